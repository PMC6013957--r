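Package: getmm
Title: Gene Length Corrected TMM Normalization for RNA-Seq Count Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Normalization of gene-level RNA-seq read-count matrices for
    joint inter- and intrasample analysis. Implements GeTMM (gene length
    corrected trimmed mean of M-values), alongside the comparator methods
    TMM, RLE (median-of-ratios) and TPM, gene-length derivation from GTF
    annotation, the evaluation statistics used to compare normalizations
    (Z-normalized RMSE, signal-to-noise ratio, per-gene and per-sample
    correlation, Bland-Altman agreement, two-group tests with
    Benjamini-Hochberg FDR), a seven-gene recurrence-score calculator,
    and a negative-binomial count simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    DESeq2,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
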