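#' Reads per kilobase
#'
#' Divides each gene's raw read count by its length in kilobases. RPK is the
#' length-corrected unit both TPM and GeTMM start from: at equal molar
#' expression a 2 kb gene collects about twice the reads of a 1 kb gene, and
#' dividing by length removes that within-sample bias.
#'
#' @param counts Nonnegative gene x sample count matrix with dimnames.
#' @param lengths Named vector of gene lengths in bp (see
#'   \code{\link{gene_lengths_from_gtf}}).
#' @param missing_genes What to do with count-matrix genes absent from
#'   \code{lengths}: \code{"error"} (default) or \code{"drop"}.
#' @return \code{expr_matrix} of RPK values (method \code{"RPK"}, linear).
#' @examples
#' cm <- matrix(c(10L, 10L, 0L, 4L), 2, 2,
#'              dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' rpk(cm, c(g1 = 1000, g2 = 2000))
#' @export
rpk <- function(counts, lengths, missing_genes = c("error", "drop")) {
  .check_count_matrix(counts, min_samples = 1L, min_genes = 1L)
  al <- .match_lengths(counts, lengths, missing_genes)
  values <- al$counts / (al$lengths / 1000)
  expression_matrix(values, method = "RPK", scale = "linear")
}

#' Transcripts per million
#'
#' RPK scaled so that every sample column sums to one million: the total RPK
#' of a sample is taken as its library size, divided by 1e6, and used as the
#' per-sample scaling factor. TPM corrects for gene length but applies no
#' between-sample correction, so a few very highly expressed genes can
#' deflate every other gene's TPM in that sample (composition bias).
#'
#' @inheritParams rpk
#' @return \code{expr_matrix} of TPM values; each column sums to 1e6.
#' @export
tpm <- function(counts, lengths, missing_genes = c("error", "drop")) {
  r <- rpk(counts, lengths, missing_genes)
  totals <- colSums(r)
  if (any(totals <= 0)) {
    stop("degenerate sample (all-zero counts): ",
         paste(colnames(r)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  values <- sweep(unclass(r), 2L, totals / 1e6, "/")
  expression_matrix(values, method = "TPM", scale = "linear")
}

#' Trimmed mean of M-values normalization factors
#'
#' Estimates one multiplicative normalization factor per sample from a
#' doubly trimmed, precision-weighted mean of per-gene log2 expression
#' ratios (M-values) against a reference sample, assuming most genes are not
#' differentially expressed. Genes with extreme M (candidate DE genes) or
#' extreme A (very high/low abundance) are excluded before averaging, which
#' makes the factor robust to a handful of dominant transcripts.
#'
#' The input may be raw counts or any nonnegative expression measure such as
#' RPK; column sums are used as library sizes. Unless \code{ref_sample} is
#' given, the reference is the sample whose 75th percentile of
#' library-size-scaled values is closest to the mean of those percentiles
#' (ties broken by first index). Per non-reference sample, over genes
#' positive in both columns:
#' \deqn{M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r}, \quad
#'       A_g = \tfrac12 \log_2\left(\frac{y_{gk}}{N_k}\cdot
#'             \frac{y_{gr}}{N_r}\right)}

#' with asymptotic (binomial delta-method) M-value variances
#' \eqn{v_g = (N_k-y_{gk})/(N_k y_{gk}) + (N_r-y_{gr})/(N_r y_{gr})}.
#' Genes in the upper/lower \code{logratio_trim} fraction of M and
#' \code{abs_trim} fraction of A are discarded; the factor is the
#' inverse-variance-weighted mean
#' \eqn{2^{\sum (M_g/v_g) / \sum (1/v_g)}} over the survivors. Factors are
#' rescaled so their geometric mean is exactly 1.
#'
#' If the doubly trimmed set is empty, or the surviving \eqn{|M_g|} are all
#' below 1e-6, the sample's factor is set to 1 (degenerate-case convention).
#'
#' @param m Nonnegative numeric matrix (counts or RPK) with dimnames; at
#'   least two samples, every column with a positive sum.
#' @param ref_sample Optional sample ID to use as reference.
#' @param logratio_trim Two-sided trim fraction on M, default 0.30.
#' @param abs_trim Two-sided trim fraction on A, default 0.05.
#' @param weighted Use precision weights (default) or a plain mean.
#' @return Object of class \code{norm_factors}: list with \code{factors}
#'   (named, geometric mean 1), \code{library_sizes} (column sums),
#'   \code{method = "TMM"} and \code{ref_sample}.
#' @references Robinson MD, Oshlack A (2010). A scaling normalization method
#'   for differential expression analysis of RNA-seq data. Genome Biology
#'   11:R25.
#' @export
tmm_factors <- function(m, ref_sample = NULL, logratio_trim = 0.30,
                        abs_trim = 0.05, weighted = TRUE) {
  .check_count_matrix(m, min_samples = 2L, min_genes = 1L)
  lib <- colSums(m)
  if (any(lib <= 0)) {
    stop("degenerate sample (zero column sum): ",
         paste(colnames(m)[lib <= 0], collapse = ", "), call. = FALSE)
  }
  samples <- colnames(m)
  if (is.null(ref_sample)) {
    q75 <- apply(sweep(m, 2L, lib, "/"), 2L, stats::quantile, probs = 0.75)
    ref_idx <- which.min(abs(q75 - mean(q75)))
  } else {
    ref_idx <- match(ref_sample, samples)
    if (is.na(ref_idx)) {
      stop("ref_sample '", ref_sample, "' not found", call. = FALSE)
    }
  }
  yr <- m[, ref_idx]
  nr <- lib[ref_idx]
  f <- vapply(seq_along(samples), function(k) {
    if (k == ref_idx) return(1)
    .tmm_pair_factor(m[, k], yr, lib[k], nr, logratio_trim, abs_trim,
                     weighted)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = stats::setNames(f, samples),
                 library_sizes = stats::setNames(lib, samples),
                 method = "TMM",
                 ref_sample = samples[ref_idx]),
            class = "norm_factors")
}

# one sample vs reference: doubly trimmed weighted mean of M-values
.tmm_pair_factor <- function(yk, yr, nk, nr, logratio_trim, abs_trim,
                             weighted) {
  pos <- yk > 0 & yr > 0
  yk <- yk[pos]; yr <- yr[pos]
  if (!length(yk)) return(1)
  m_val <- log2((yk / nk) / (yr / nr))
  a_val <- 0.5 * log2((yk / nk) * (yr / nr))
  w <- (nk - yk) / (nk * yk) + (nr - yr) / (nr * yr)
  n <- length(m_val)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m_val); ra <- rank(a_val)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  if (max(abs(m_val[keep])) < 1e-6) return(1)
  if (weighted) {
    2^(sum(m_val[keep] / w[keep]) / sum(1 / w[keep]))
  } else {
    2^mean(m_val[keep])
  }
}

#' Relative log expression (median-of-ratios) size factors
#'
#' For each gene with strictly positive counts in every sample, the
#' geometric mean across samples defines a pseudo-reference; a sample's size
#' factor is the median over those genes of the ratio of its count to the
#' pseudo-reference. Computed in log space. Assumes most genes are not
#' differentially expressed.
#'
#' Fractional input is refused: this estimator operates on integer read
#' counts, and length-corrected fractional values (RPK) are not a valid
#' input for it.
#'
#' @param counts Nonnegative integer gene x sample matrix with dimnames.
#' @return \code{norm_factors} with \code{method = "RLE"}; factors are the
#'   size factors themselves (not rescaled to geometric mean 1).
#' @export
rle_factors <- function(counts) {
  .check_count_matrix(counts)
  if (any(counts != round(counts))) {
    stop("RLE requires integer read counts; fractional values ",
         "(e.g. length-corrected RPK) are not accepted", call. = FALSE)
  }
  logc <- log(counts)
  all_pos <- apply(counts > 0, 1L, all)
  if (!any(all_pos)) {
    stop("RLE size factors cannot be estimated: no gene has strictly ",
         "positive counts in every sample", call. = FALSE)
  }
  log_geomean <- rowMeans(logc[all_pos, , drop = FALSE])
  f <- apply(logc[all_pos, , drop = FALSE], 2L, function(col) {
    exp(stats::median(col - log_geomean))
  })
  structure(list(factors = f,
                 library_sizes = colSums(counts),
                 method = "RLE",
                 ref_sample = NA_character_),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("%s normalization factors for %d samples\n", x$method,
              length(x$factors)))
  print(round(x$factors, 4))
  invisible(x)
}

#' Apply normalization factors to an expression matrix
#'
#' TMM-style factors rescale the library size: each value is divided by
#' (library size x factor) and multiplied by \code{per} (counts per million
#' by default). RLE-style factors divide the counts of each sample directly
#' and \code{per} is ignored unless \code{rle_per_million = TRUE}.
#'
#' @param m Numeric gene x sample matrix with dimnames.
#' @param factors \code{norm_factors} covering every sample of \code{m}.
#' @param per Scale constant for the TMM path, default 1e6.
#' @param rle_per_million Also scale the RLE path to \code{per} per sample;
#'   off by default (factor-divided counts, the conventional RLE output).
#' @return \code{expr_matrix} tagged with the factors' method.
#' @export
scaled_expression <- function(m, factors, per = 1e6,
                              rle_per_million = FALSE) {
  stopifnot(inherits(factors, "norm_factors"))
  missing_s <- setdiff(colnames(m), names(factors$factors))
  if (length(missing_s)) {
    stop("no factor for sample(s): ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  }
  f <- factors$factors[colnames(m)]
  if (factors$method == "RLE" && !rle_per_million) {
    values <- sweep(unclass(m), 2L, f, "/")
  } else {
    lib <- factors$library_sizes[colnames(m)]
    values <- sweep(unclass(m), 2L, lib * f / per, "/")
  }
  expression_matrix(values,
                    method = if (factors$method == "RLE") "RLE" else "TMM",
                    scale = "linear")
}

#' Gene length corrected TMM (GeTMM) normalization
#'
#' Computes RPK (count / length in kb) for every gene, then runs TMM factor
#' estimation on the RPK matrix itself, substituting the total RPK of a
#' sample for its library size, and scales to one million: the output value
#' is \code{RPK[g,s] / (sum(RPK[,s]) * factor_s) * 1e6}. The gene-length
#' correction makes values comparable between genes within a sample, while
#' the TMM factor keeps them comparable between samples even under
#' composition bias. When all TMM factors are 1 the result equals TPM
#' exactly.
#'
#' @inheritParams rpk
#' @param logratio_trim,abs_trim,weighted Passed to
#'   \code{\link{tmm_factors}}.
#' @return \code{expr_matrix} with method \code{"GeTMM"}; the TMM factors
#'   are attached as attribute \code{"norm_factors"}.
#' @examples
#' cm <- matrix(c(10L, 20L, 5L, 10L), 2, 2,
#'              dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' getmm(cm, c(g1 = 500, g2 = 2000))
#' @export
getmm <- function(counts, lengths, missing_genes = c("error", "drop"),
                  logratio_trim = 0.30, abs_trim = 0.05, weighted = TRUE) {
  r <- rpk(counts, lengths, missing_genes)
  nf <- tmm_factors(unclass(r), logratio_trim = logratio_trim,
                    abs_trim = abs_trim, weighted = weighted)
  out <- scaled_expression(unclass(r), nf, per = 1e6)
  out <- expression_matrix(unclass(out), method = "GeTMM",
                           scale = "linear")
  attr(out, "norm_factors") <- nf
  out
}

#' log2 transform with zeros set to missing
#'
#' Transforms a linear-scale expression matrix to log2, mapping exact zeros
#' (genes with 0 read counts) to \code{NA} rather than \code{-Inf}, so that
#' downstream statistics can pairwise-delete them.
#'
#' @param m Linear-scale \code{expr_matrix} (or nonnegative matrix).
#' @return \code{expr_matrix} on the log2 scale, same method tag.
#' @export
log2_with_missing <- function(m) {
  if (expr_scale(m) == "log2") {
    stop("matrix is already on the log2 scale", call. = FALSE)
  }
  if (any(m < 0, na.rm = TRUE)) {
    stop("negative values cannot be log2-transformed", call. = FALSE)
  }
  values <- unclass(m)
  values[values == 0] <- NA_real_
  values <- log2(values)
  expression_matrix(values, method = expr_method(m), scale = "log2")
}

#' Export normalization factors as a two-column table
#'
#' @param factors \code{norm_factors}.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_norm_factors <- function(factors, path) {
  stopifnot(inherits(factors, "norm_factors"))
  df <- data.frame(sample_id = names(factors$factors),
                   factor = unname(factors$factors))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
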