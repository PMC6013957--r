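#' Z-normalize an expression matrix per gene
#'
#' Subtracts from every value the mean expression of its gene and divides by
#' the gene's standard deviation (n-1 denominator), so each gene row has
#' mean 0 and sd 1. Missing values are excluded from the moments and stay
#' missing. Genes with zero variance (or fewer than 2 non-missing values)
#' are set to all-missing with a warning.
#'
#' @param m Numeric gene x sample matrix (any scale).
#' @return Matrix of the same shape, rows standardized.
#' @export
z_normalize <- function(m) {
  values <- unclass(m)
  mu <- rowMeans(values, na.rm = TRUE)
  sd_ <- apply(values, 1L, stats::sd, na.rm = TRUE)
  n_ok <- rowSums(!is.na(values))
  degenerate <- n_ok < 2L | is.na(sd_) | sd_ == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) with zero variance or < 2 values ",
            "set to all-missing", call. = FALSE)
  }
  out <- (values - mu) / sd_
  out[degenerate, ] <- NA_real_
  out
}

#' Root mean square error over complete pairs
#'
#' \code{sqrt(mean((a - b)^2))} after pairwise deletion of entries missing
#' in either vector. Intended for Z-normalized expression vectors, where it
#' measures disagreement in units of per-gene standard deviations.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    stop("RMSE undefined: no complete pairs", call. = FALSE)
  }
  sqrt(mean((a[ok] - b[ok])^2))
}

#' Signal-to-noise ratio with pooled variance
#'
#' \code{(mean(x1) - mean(x2)) / sqrt(Vp)} where the pooled variance is
#' \code{Vp = ((n1-1) V1 + (n2-1) V2) / (n1 + n2 - 2)} and V1, V2 are the
#' two groups' sample variances (n-1 denominator).
#'
#' @param x1,x2 Numeric vectors, each with at least 2 non-missing values.
#' @return Scalar; antisymmetric in its arguments.
#' @examples
#' snr(c(1, 2, 3), c(4, 5, 6))  # -3
#' @export
snr <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]
  x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) {
    stop("both groups need at least 2 values", call. = FALSE)
  }
  vp <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  if (vp == 0) {
    stop("SNR undefined: pooled variance is zero", call. = FALSE)
  }
  (mean(x1) - mean(x2)) / sqrt(vp)
}

#' Per-gene correlation between two expression matrices
#'
#' Correlates each shared gene's expression across shared samples between a
#' matrix (e.g. normalized RNA-seq) and a reference (e.g. RT-qPCR levels):
#' the intersample design, one coefficient per gene. Missing entries are
#' pairwise-deleted; Spearman uses average ranks for ties. Genes with fewer
#' than 3 complete pairs get an NA coefficient.
#'
#' @param rnaseq,reference Numeric matrices with gene rownames and sample
#'   colnames; gene and sample sets must overlap.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return Data frame with columns \code{gene_id}, \code{coefficient},
#'   \code{n_pairs}.
#' @export
correlate_per_gene <- function(rnaseq, reference,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  genes <- intersect(rownames(rnaseq), rownames(reference))
  samples <- intersect(colnames(rnaseq), colnames(reference))
  if (!length(genes) || !length(samples)) {
    stop("matrices share no genes or no samples", call. = FALSE)
  }
  a <- unclass(rnaseq)[genes, samples, drop = FALSE]
  b <- unclass(reference)[genes, samples, drop = FALSE]
  res <- lapply(seq_along(genes), function(i) {
    .cor_complete(a[i, ], b[i, ], method)
  })
  data.frame(gene_id = genes,
             coefficient = vapply(res, `[[`, numeric(1), "r"),
             n_pairs = vapply(res, `[[`, integer(1), "n"))
}

#' Per-sample Spearman correlation between two expression matrices
#'
#' Correlates the expression of the shared genes within each shared sample:
#' the intrasample design, one coefficient per sample. This is the analysis
#' where gene-length correction matters — without it, long genes rank high
#' regardless of molar abundance. Rank-based, so invariant to any monotone
#' per-sample rescaling.
#'
#' @inheritParams correlate_per_gene
#' @param method Correlation type, default \code{"spearman"}.
#' @return Data frame with columns \code{sample_id}, \code{coefficient},
#'   \code{n_pairs}.
#' @export
correlate_per_sample <- function(rnaseq, reference,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  genes <- intersect(rownames(rnaseq), rownames(reference))
  samples <- intersect(colnames(rnaseq), colnames(reference))
  if (!length(genes) || !length(samples)) {
    stop("matrices share no genes or no samples", call. = FALSE)
  }
  a <- unclass(rnaseq)[genes, samples, drop = FALSE]
  b <- unclass(reference)[genes, samples, drop = FALSE]
  res <- lapply(seq_along(samples), function(j) {
    .cor_complete(a[, j], b[, j], method)
  })
  data.frame(sample_id = samples,
             coefficient = vapply(res, `[[`, numeric(1), "r"),
             n_pairs = vapply(res, `[[`, integer(1), "n"))
}

.cor_complete <- function(x, y, method) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) {
    return(list(r = NA_real_, n = as.integer(n)))
  }
  list(r = stats::cor(x[ok], y[ok], method = method), n = as.integer(n))
}

#' Bland-Altman agreement between paired measurements
#'
#' For paired values (e.g. per-gene correlation coefficients obtained in a
#' high-quality and a low-quality sample group) computes the differences
#' \code{d = c_high - c_low}, their mean (the bias), the 95% limits of
#' agreement \code{bias +/- 1.96 sd(d)} and a one-sample t-test of d
#' against 0.
#'
#' @param c_high,c_low Paired numeric vectors, length >= 2 after pairwise
#'   deletion of missing values.
#' @return List with \code{bias}, \code{limits} (lower, upper), \code{p},
#'   \code{n}.
#' @export
bland_altman <- function(c_high, c_low) {
  if (length(c_high) != length(c_low)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(c_high) & !is.na(c_low)
  d <- c_high[ok] - c_low[ok]
  if (length(d) < 2L) {
    stop("need at least 2 complete pairs", call. = FALSE)
  }
  bias <- mean(d)
  s <- stats::sd(d)
  limits <- c(lower = bias - 1.96 * s, upper = bias + 1.96 * s)
  # t.test rejects essentially-constant data; treat that case explicitly
  if (s <= 10 * .Machine$double.eps * max(1, abs(bias))) {
    p <- if (abs(bias) <= 10 * .Machine$double.eps) 1 else
      .Machine$double.xmin
    if (p < 1) {
      warning("all differences identical and nonzero; p reported as ",
              "smallest positive double", call. = FALSE)
    }
  } else {
    p <- stats::t.test(d, mu = 0)$p.value
  }
  list(bias = bias, limits = limits, p = p, n = length(d))
}

#' Per-gene two-group tests with BH-FDR
#'
#' Runs a two-sided Student's t-test (pooled variance by default, matching
#' the classic formulation; Welch via \code{welch = TRUE}) or Mann-Whitney
#' U test per gene between two labeled sample groups, then attaches
#' Benjamini-Hochberg adjusted FDR values. Genes with fewer than 2
#' non-missing values in either group are flagged untestable (NA statistic
#' and p).
#'
#' @param m Numeric gene x sample matrix.
#' @param labels Named vector/factor mapping sample IDs to two groups.
#' @param test \code{"t_test"} or \code{"mann_whitney"}.
#' @param welch Use Welch's unequal-variance t-test instead of pooled.
#' @return Data frame: \code{gene_id}, \code{statistic}, \code{p_value},
#'   \code{fdr}, \code{testable}. FDRs are computed over testable genes.
#' @export
two_group_tests <- function(m, labels, test = c("t_test", "mann_whitney"),
                            welch = FALSE) {
  test <- match.arg(test)
  if (is.null(names(labels))) {
    stop("labels must be named by sample ID", call. = FALSE)
  }
  unknown <- setdiff(names(labels), colnames(m))
  if (length(unknown)) {
    stop("labeled sample(s) absent from matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2L) {
    stop("labels must define exactly 2 groups", call. = FALSE)
  }
  g1 <- names(labels)[labels == levels(labels)[1L]]
  g2 <- names(labels)[labels == levels(labels)[2L]]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  values <- unclass(m)
  res <- t(vapply(seq_len(nrow(values)), function(i) {
    x1 <- values[i, g1]; x2 <- values[i, g2]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2L || length(x2) < 2L) {
      return(c(NA_real_, NA_real_))
    }
    if (test == "t_test") {
      if (stats::var(x1) == 0 && stats::var(x2) == 0) {
        return(c(NA_real_, NA_real_))
      }
      ht <- stats::t.test(x1, x2, var.equal = !welch)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x1, x2))
    }
    c(unname(ht$statistic), ht$p.value)
  }, numeric(2)))
  testable <- !is.na(res[, 2L])
  fdr <- rep(NA_real_, nrow(values))
  fdr[testable] <- bh_fdr(res[testable, 2L])
  data.frame(gene_id = rownames(values),
             statistic = res[, 1L],
             p_value = res[, 2L],
             fdr = fdr,
             testable = testable)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment \code{p * n / rank} with cumulative-minimum
#' monotonicity enforcement, capped at 1; order-preserving with the input.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NA", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
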