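---
title: "Normalization for joint inter- and intrasample RNA-seq analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization for joint inter- and intrasample RNA-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(getmm)
```

## Why two corrections at once

A gene's read count is proportional to both its molar abundance and its
length, and to the sequencing depth of its library. Between-sample
normalizations (TMM, RLE) remove depth and composition effects but leave
length in, because length cancels when the *same* gene is compared across
samples. Within-sample analyses — signature scores, correlation of a gene
panel against a centroid or against qPCR measurements of the same sample
— compare *different* genes, where a 10-fold length difference masquerades
as a 10-fold expression difference. TPM removes length but trusts the
total library as the scaling denominator, so a handful of extremely
abundant transcripts in one sample deflates every other gene in it.

GeTMM runs the TMM machinery on the length-corrected matrix: RPK
(count / length in kb) replaces the count, total RPK replaces the library
size, and the estimated factor rescales the per-million denominator:

$$\mathrm{GeTMM}_{gs} = \frac{RPK_{gs}}{\bigl(\sum_g RPK_{gs}\bigr) f_s}
  \times 10^6 .$$

Within a sample this is a single monotone rescaling of RPK, so
within-sample ranks are those of RPK; between samples the factor $f_s$
supplies the same robustness TMM gives to counts. When all factors are 1
(e.g. identical RPK profiles) GeTMM equals TPM elementwise, a reduction
the test suite asserts at 1e-9.

## The TMM estimator

Given a matrix of nonnegative values (counts or RPK) with column sums
$N_k$, the reference sample is the one whose 75th percentile of
column-scaled values is closest to the mean of those percentiles; ties
take the first index in column order. For sample $k$ against reference
$r$, genes positive in both columns contribute

$$M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r},\qquad
  A_g = \tfrac12\log_2\Bigl(\frac{y_{gk}}{N_k}\frac{y_{gr}}{N_r}\Bigr),
  \qquad
  v_g = \frac{N_k-y_{gk}}{N_k\,y_{gk}} + \frac{N_r-y_{gr}}{N_r\,y_{gr}}.$$

Genes ranked in the top or bottom `logratio_trim` fraction of $M$
(default 0.30) or `abs_trim` fraction of $A$ (default 0.05) are dropped
— average ranks, so tied values share their fate — and the factor is the
inverse-variance-weighted mean $2^{\sum M_g/v_g \,/\, \sum 1/v_g}$ over
the survivors (`weighted = FALSE` gives the plain mean). Factors are
rescaled to geometric mean 1, which fixes the overall scale the pairwise
ratios leave free. The defaults are the documented defaults of the
estimator's reference implementation (edgeR); the test suite checks exact
agreement with `edgeR::calcNormFactors` and with an independently coded
brute-force oracle on a seeded grid of small matrices.

Degenerate cases are resolved by convention, not error: if the doubly
trimmed set is empty, or every surviving $|M_g| < 10^{-6}$, the factor is
1 (this also makes two identical — or purely depth-scaled — columns come
out neutral exactly). Genes with a zero in either column are excluded
from M/A/variance computation, since their log-ratio is undefined.

One subtlety worth stating: uniformly rescaling one sample's counts
leaves $M$, $A$ and hence the trim set unchanged, so the *unweighted*
factor — and every normalized value — is exactly depth-invariant. The
precision weights, however, depend on the library sizes themselves, so
the weighted default is only approximately depth-invariant (as is
edgeR's). The exactness tests therefore run with `weighted = FALSE`; the
weighted estimator is kept as the default because its lower variance is
the point of precision weighting.

## RLE, and why it refuses fractions

The RLE size factor of a sample is the median over genes of the ratio of
its count to the gene's across-sample geometric mean, computed in log
space over the genes positive in every sample. If no gene is positive
everywhere the estimator has an empty reference set and stops with an
error rather than guessing. The estimator is defined on integer read
counts; length-corrected fractional RPK values are rejected with an
explicit error instead of being silently accepted, so the
counts-vs-length-corrected distinction stays visible at the interface.
RLE output is factor-divided counts (no per-million scaling) unless
`rle_per_million = TRUE`, mirroring how its factors are conventionally
applied to the counts themselves.

## Gene lengths from annotation

`gene_lengths_from_gtf()` treats GTF coordinates as 1-based and
end-inclusive (length = end − start + 1). The default
`unique_exon_sum` mode deduplicates exon records by their `exon_id`
within each gene and sums the deduplicated lengths: an exon shared by
many transcripts counts once. Overlapping exons with *distinct* IDs are
double-counted under this rule; `merged_union` mode (interval union per
gene, strand-agnostic) is offered for users who prefer a
never-double-counted length, and the tests pin
`unique_exon_sum >= merged_union` per gene. Records lacking `exon_id`
fall back to deduplication by (seqname, start, end, strand), keeping
non-GENCODE dialects usable. Genes present in the count matrix but
absent from the annotation are an error by default (`missing_genes =
"drop"` opts into silent removal) — dropping data should be a visible
decision.

## The log2 / missing-value policy

Normalized values of 0 carry no information about magnitude on the log
scale, so `log2_with_missing()` maps exact zeros to `NA` and everything
else to log2. All downstream statistics (Z-normalization, RMSE,
correlations, group tests) pairwise-delete missing values and report the
number of usable pairs where it matters, rather than imputing.

## Evaluation statistics

All standard deviations and variances use the n−1 denominator — the
pooled-variance SNR formula
$V_p = [(n_1{-}1)V_1 + (n_2{-}1)V_2]/(n_1+n_2-2)$ is built from n−1
variances, and the same convention is applied uniformly to
Z-normalization and Bland-Altman limits. Bland-Altman limits of
agreement use the 1.96 normal multiplier; when all paired differences
are numerically identical the t-test is undefined and the p-value is
reported as 1 (zero bias) or the smallest positive double with a warning
(nonzero bias) rather than failing mid-pipeline. The two-group test is
the pooled-variance Student's t-test by default with Welch behind a
flag; Mann-Whitney is the non-parametric alternative. FDR adjustment is
Benjamini-Hochberg step-up via `stats::p.adjust`, computed over the
testable genes only. Correlation p-values are not computed — method
comparisons here are between coefficient distributions, not against a
zero-correlation null.

## The recurrence score

The seven-gene score is an affine combination with fixed, published
coefficients: stromal panel mean × 0.1263, cell-cycle panel mean ×
−0.3158, GADD45B × 0.3406, then `RS = 44.16 * (Rsu + 0.30)` clipped at
zero. No upper cap is applied. The default input is the log2
expression matrix, because the qPCR comparator scale (delta-delta Cq) is
logarithmic; `--linear` / passing linear values is available and the
genes are used as-is, without per-gene rescaling to a fixed range —
that choice (raw normalized values, not 0–15 rescaled ones) is the one
open point in the published description, and it is surfaced here rather
than hidden. Gene symbols are matched case-insensitively after stripping
trailing version suffixes; an explicit `id_map` overrides matching.
A low-expressing normalization that drags the panel genes down pushes
`rs_raw` below zero and inflates the zero-clipped fraction — the tests
assert the corresponding monotonicity (raising GADD45B never increases
the clipped fraction).

## What the simulator emulates — and what it does not

`simulate_counts()` draws gene lengths log-uniformly over 0.2–20 kb
(recreating the length-driven spread of per-gene counts), per-gene
concentrations log-normally (meanlog 1, sdlog 1.5, spanning the several
orders of magnitude typical of bulk expression), and counts
negative-binomially with mean proportional to concentration × length ×
library size and edgeR-style variance $\mu + \phi\mu^2$. The dispersion
default is $\phi = 0.4$, the common-dispersion value conventional for
human tumor cohorts without replicates; library sizes default to
6 million reads. Composition bias multiplies a gene fraction by a fold
change in chosen samples *before* renormalizing sampling probabilities,
so the biased sample keeps its nominal depth while every unperturbed
gene loses a predictable share — exactly the failure mode TMM-type
factors exist to absorb. The default scenario (1000 genes × 50 samples)
is the one under which the package's recovery properties are asserted:
length-corrected methods track true concentrations within samples
(median per-sample Spearman strictly above the uncorrected methods) and
TMM/RLE/GeTMM recover a composition-biased sample's relative scale
within 5% while TPM does not.

The generator is one seeded RNG stream consumed in a fixed order, which
makes output bit-identical for a fixed configuration (the seed is part
of the configuration) — a per-cell counter-based scheme was considered
and rejected as complexity without an invariant it would add.

It does not emulate: isoform structure or effective (fragment-corrected)
lengths, RNA degradation gradients, GC or mappability bias, batch
structure, or correlated gene modules. Passing tests on these
simulations therefore demonstrate correctness of the estimators under
the stated generative model, not robustness to every artifact of real
cohorts.

## Problem sizes and tolerances

The test suite runs at desk scale by design: oracle grids up to 8 genes
× 4 samples (where brute force is exact), cross-checks at 40–60 genes,
simulation properties at 1000–10 000 genes and 2–50 samples. Algebraic
identities are asserted at 1e-9 (relative), text round-trips at 1e-12,
sampling-based properties at 3 simulation standard deviations or at the
5% scale-recovery bound stated above. Matrix I/O serializes doubles at
17 significant digits, which round-trips IEEE doubles exactly.

## Limitations

GeTMM shares TMM's assumptions: most genes not differentially expressed,
and a meaningful common reference sample. Gene-level lengths are a
single number per gene; isoform switching between samples violates the
correction silently. The recurrence-score coefficients are fixed
published constants — the calculator validates inputs, not the clinical
transportability of the score. The CLI is a thin wrapper over the
functions; it streams diagnostics to stderr and data to files, and makes
no attempt at parallelism.
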