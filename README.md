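# getmm

Normalization of bulk RNA-seq gene-level count matrices for analyses that
compare expression **between samples** (differential expression) and
**within a sample** (signature scores, correlation-based classifiers) from
one and the same normalized data set.

## The problem and the method

Raw read counts confound molar abundance with gene length: at equal
expression a 2 kb gene collects roughly twice the reads of a 1 kb gene.
The standard between-sample normalizations — TMM (trimmed mean of
M-values, used by edgeR) and RLE (median-of-ratios, used by DESeq2) —
deliberately ignore gene length, which is fine for per-gene tests across
samples but breaks any analysis that ranks or correlates *different genes
within one sample*. TPM corrects for length but has no protection against
composition bias (a few dominant transcripts deflating everything else in
that library).

**GeTMM** combines the two corrections. With raw count
$RC_{gs}$ and gene length $L_g$ in kb:

$$RPK_{gs} = \frac{RC_{gs}}{L_g}, \qquad
  \mathrm{GeTMM}_{gs} = \frac{RPK_{gs}}
  {\left(\sum_g RPK_{gs}\right)\cdot f_s} \times 10^6,$$

where $f_s$ is the TMM normalization factor estimated **on the RPK
matrix**, i.e. the total RPK of a sample replaces its total read count as
the library size. The TMM factor is the inverse-variance-weighted mean of
per-gene log2 ratios against a reference sample after trimming the
extreme 30% of log-ratios (M) and 5% of average abundances (A) on each
side, rescaled so factors have geometric mean 1. When every factor is 1,
GeTMM reduces exactly to TPM.

The package also provides, around that core:

* `read_count_matrix()` / `write_expression_matrix()` — tab-delimited I/O
  with a literal `NA` missing-value sentinel;
* `gene_lengths_from_gtf()` — gene lengths from GENCODE-style GTF, either
  by summing exons with a unique `exon_id` per gene (default) or by
  merged-interval union;
* `tpm()`, `tmm_factors()`, `rle_factors()`, `scaled_expression()`,
  `log2_with_missing()` — the comparator methods and transforms;
* evaluation statistics: `z_normalize()`, `rmse()`, `snr()`,
  `correlate_per_gene()`, `correlate_per_sample()`, `bland_altman()`,
  `two_group_tests()`, `bh_fdr()`;
* `recurrence_score()` — the seven-gene prognostic score
  `RS = 44.16 * (Rsu + 0.30)` with
  `Rsu = 0.1263*mean(BGN,FAP,INHBA) - 0.3158*mean(MKI67,MYC,MYBL2) +
  0.3406*GADD45B`, clipped at zero;
* `simulate_counts()` / `make_fixture()` — a negative-binomial simulator
  with known per-gene concentrations, lengths and per-sample scales;
* a command-line front end (`getmm_cli()`, installed as `exec/getmm`) with
  subcommands `normalize`, `genelengths`, `compare`, `detest`, `rscore`,
  `simulate`.

## Worked example

```r
library(getmm)
p  <- make_fixture("tiny", dir = tempfile(), seed = 20)  # 8 genes x 4 samples
cm <- read_count_matrix(p$counts)
lens <- gene_lengths_from_gtf(p$gtf)
g <- getmm(cm, lens)
attr(g, "norm_factors")
#> TMM normalization factors for 4 samples
#> sample001 sample002 sample003 sample004
#>    1.0631    1.2570    0.7364    1.0162
round(unclass(g)[1:3, ], 1)
#>          sample001 sample002 sample003 sample004
#> gene0001   34919.1  156901.2   89147.7   91461.6
#> gene0002  341859.0  242852.0  710704.5  209507.0
#> gene0003    1383.6    2309.1    2338.5    3031.0
colSums(g)            # 1e6 / factor per sample
#> 940604.6 795532.7 1358001.4 984090.1
colSums(tpm(cm, lens))  # TPM columns sum to exactly one million
#> 1e+06 1e+06 1e+06 1e+06
```

The factors say sample003's library is dominated by relatively fewer,
more highly expressed RPK units (factor 0.74 < 1 inflates its values
back up); GeTMM column sums equal `1e6 / factor`, whereas TPM forces
every column to exactly one million. Within each sample GeTMM is a
monotone rescaling of RPK, so per-sample rank correlations against TPM
are 1 (`correlate_per_sample(g, tpm(cm, lens))`).

The same normalization from the shell:

```sh
Rscript inst/exec/getmm normalize --method getmm \
    --counts counts.tsv --gtf genes.gtf --log2 --out getmm_log2.tsv
```

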