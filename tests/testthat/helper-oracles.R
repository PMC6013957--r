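# Independent oracles, deliberately coded with explicit loops and manual
# rank arithmetic so they share nothing with the package's vectorized
# implementations.

# average rank of each element, computed by counting
.manual_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    below <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- below + (1 + ties) / 2
  }
  r
}

# brute-force TMM: reference choice, M/A/variance per gene, double trim,
# inverse-variance-weighted mean, geometric-mean rescale
oracle_tmm_factors <- function(m, logratio_trim = 0.30, abs_trim = 0.05,
                               weighted = TRUE) {
  lib <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) lib[j] <- sum(m[, j])
  q75 <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    q75[j] <- unname(quantile(m[, j] / lib[j], probs = 0.75))
  }
  ref <- which.min(abs(q75 - mean(q75)))[1]
  fac <- numeric(ncol(m))
  for (k in seq_len(ncol(m))) {
    if (k == ref) {
      fac[k] <- 1
      next
    }
    M <- c(); A <- c(); V <- c()
    for (g in seq_len(nrow(m))) {
      yk <- m[g, k]; yr <- m[g, ref]
      if (yk > 0 && yr > 0) {
        pk <- yk / lib[k]; pr <- yr / lib[ref]
        M <- c(M, log2(pk / pr))
        A <- c(A, 0.5 * log2(pk * pr))
        V <- c(V, (lib[k] - yk) / (lib[k] * yk) +
                 (lib[ref] - yr) / (lib[ref] * yr))
      }
    }
    n <- length(M)
    if (n == 0) {
      fac[k] <- 1
      next
    }
    rm_ <- .manual_ranks(M)
    ra <- .manual_ranks(A)
    lo_m <- floor(n * logratio_trim) + 1
    lo_a <- floor(n * abs_trim) + 1
    keep <- rm_ >= lo_m & rm_ <= n + 1 - lo_m &
      ra >= lo_a & ra <= n + 1 - lo_a
    if (!any(keep)) {
      fac[k] <- 1
      next
    }
    if (max(abs(M[keep])) < 1e-6) {
      fac[k] <- 1
      next
    }
    if (weighted) {
      num <- 0; den <- 0
      for (i in which(keep)) {
        num <- num + M[i] / V[i]
        den <- den + 1 / V[i]
      }
      fac[k] <- 2^(num / den)
    } else {
      fac[k] <- 2^mean(M[keep])
    }
  }
  gm <- exp(sum(log(fac)) / length(fac))
  setNames(fac / gm, colnames(m))
}

# brute-force interval union length: mark covered bases one by one
oracle_union_length <- function(starts, ends) {
  covered <- logical(max(ends))
  for (i in seq_along(starts)) {
    covered[starts[i]:ends[i]] <- TRUE
  }
  sum(covered)
}

# small deterministic count matrix used across tests
toy_counts <- function(seed = 42, n_genes = 8, n_samples = 4,
                       mu = 200, size = 2) {
  set.seed(seed)
  matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
         nrow = n_genes, ncol = n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

toy_lengths <- function(counts, seed = 43, range = c(300, 8000)) {
  set.seed(seed)
  setNames(sample(range[1]:range[2], nrow(counts)), rownames(counts))
}

# minimal GENCODE-style GTF writer for hand-built exon sets
write_test_gtf <- function(path, records) {
  lines <- vapply(records, function(r) {
    attrs <- sprintf('gene_id "%s";', r$gene)
    if (!is.null(r$exon_id)) {
      attrs <- paste0(attrs, sprintf(' exon_id "%s";', r$exon_id))
    }
    if (!is.null(r$transcript_id)) {
      attrs <- paste0(attrs, sprintf(' transcript_id "%s";',
                                     r$transcript_id))
    }
    sprintf("chr1\ttest\texon\t%d\t%d\t.\t+\t.\t%s", r$start, r$end,
            attrs)
  }, character(1))
  writeLines(lines, path)
  path
}

panel_matrix <- function(values, sample_id = "s1") {
  genes <- c("BGN", "FAP", "INHBA", "MKI67", "MYC", "MYBL2", "GADD45B")
  matrix(values, nrow = 7, ncol = length(sample_id),
         dimnames = list(genes, sample_id))
}
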