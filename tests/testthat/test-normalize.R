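test_that("rpk divides counts by length in kilobases", {
  cm <- matrix(c(10L, 10L, 0L, 3L), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  r <- rpk(cm, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(r["g1", "s1"]), 10)  # 1 kb identity
  expect_equal(unname(r["g2", "s1"]), 5)
  expect_equal(unname(r["g1", "s2"]), 0)
  expect_identical(expr_method(r), "RPK")

  expect_error(rpk(cm, c(g1 = 1000)), "g2")
  dropped <- rpk(cm, c(g1 = 1000), missing_genes = "drop")
  expect_identical(rownames(dropped), "g1")
})

test_that("tpm columns sum to one million and are depth-invariant", {
  cm <- toy_counts()
  lens <- toy_lengths(cm)
  t1 <- tpm(cm, lens)
  expect_equal(unname(colSums(t1)), rep(1e6, ncol(cm)),
               tolerance = 1e-9)
  # hand example: equal RPK split
  cm2 <- matrix(c(10L, 20L), 2, 1,
                dimnames = list(c("g1", "g2"), "s1"))
  t2 <- tpm(cm2, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(t2[, 1]), c(5e5, 5e5))
  # point mass
  cm3 <- matrix(c(7L, 0L), 2, 1,
                dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(tpm(cm3, c(g1 = 500, g2 = 500))[, 1]), c(1e6, 0))
  # uniform rescaling of one sample's counts changes nothing
  cm4 <- cm
  cm4[, 2] <- cm4[, 2] * 3L
  expect_equal(unclass(tpm(cm4, lens)), unclass(t1), tolerance = 1e-12)
  # all-zero sample
  cm5 <- cm
  cm5[, 1] <- 0L
  expect_error(tpm(cm5, lens), "degenerate")
})

test_that("TMM factors are neutral for identical or purely rescaled columns", {
  cm <- toy_counts()
  same <- cbind(s1 = cm[, 1], s2 = cm[, 1])
  expect_equal(unname(tmm_factors(same)$factors), c(1, 1))
  scaled <- cbind(s1 = cm[, 1], s2 = 3L * cm[, 1])
  expect_equal(unname(tmm_factors(scaled)$factors), c(1, 1))
})

test_that("TMM factors match the brute-force oracle on a seeded grid", {
  set.seed(301)
  vals <- c(0, 1, 5, 10, 100, 1000)
  n_checked <- 0
  for (i in 1:60) {
    ng <- sample(3:8, 1)
    ns <- sample(2:4, 1)
    m <- matrix(sample(vals, ng * ns, replace = TRUE), ng, ns,
                dimnames = list(paste0("g", 1:ng), paste0("s", 1:ns)))
    if (any(colSums(m) == 0)) next
    expect_equal(tmm_factors(m)$factors, oracle_tmm_factors(m),
                 tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 30)
  # the spec'd shape: one sample dominated by a single gene
  m <- matrix(c(100, 90, 80, 120, 60, 70,
                110, 85, 75, 130, 55, 65,
                5000, 80, 85, 110, 60, 75), 6, 3,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  expect_equal(tmm_factors(m)$factors, oracle_tmm_factors(m),
               tolerance = 1e-9)
})

test_that("TMM agrees with edgeR and keeps geometric mean 1", {
  for (seed in c(5, 17, 99)) {
    m <- toy_counts(seed = seed, n_genes = 50, n_samples = 6)
    nf <- tmm_factors(m)
    expect_equal(exp(mean(log(nf$factors))), 1, tolerance = 1e-9)
    expect_equal(unname(nf$factors),
                 unname(edgeR::calcNormFactors(m, method = "TMM")),
                 tolerance = 1e-9)
  }
  # permuting samples permutes factors identically
  m <- toy_counts(seed = 5, n_genes = 50, n_samples = 6)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(tmm_factors(m[, perm])$factors,
               tmm_factors(m)$factors[perm], tolerance = 1e-12)
  expect_error(tmm_factors(m[, 1, drop = FALSE]), "2")
})

test_that("RLE size factors follow the median-of-ratios closed form", {
  cm <- toy_counts() + 1L  # all positive
  same <- cbind(s1 = cm[, 1], s2 = cm[, 1])
  expect_equal(unname(rle_factors(same)$factors), c(1, 1))
  # column 2 = c * column 1: factors proportional to (1, c)
  for (cc in c(2L, 5L)) {
    scaled <- cbind(s1 = cm[, 1], s2 = cc * cm[, 1])
    f <- rle_factors(scaled)$factors
    expect_equal(unname(f[2] / f[1]), cc, tolerance = 1e-9)
  }
  # agreement with the DESeq2 estimator
  expect_equal(unname(rle_factors(cm)$factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(cm)),
               tolerance = 1e-9)
  # every gene has a zero somewhere -> impossible
  bad <- matrix(c(0L, 5L, 5L, 0L), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(rle_factors(bad), "no gene")
  # fractional input refused (integer-count estimator)
  frac <- matrix(c(1.5, 2, 3, 4), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(rle_factors(frac), "integer")
})

test_that("scaled_expression applies TMM and RLE factors as defined", {
  cm <- toy_counts()
  neutral <- structure(list(
    factors = setNames(rep(1, 4), colnames(cm)),
    library_sizes = colSums(cm), method = "TMM",
    ref_sample = "s1"), class = "norm_factors")
  cpm_ <- scaled_expression(cm, neutral)
  expect_equal(unclass(cpm_),
               sweep(cm, 2, colSums(cm) / 1e6, "/"),
               tolerance = 1e-12, ignore_attr = TRUE)
  # TMM path: column sum = per / factor
  nf <- tmm_factors(cm)
  sc <- scaled_expression(cm, nf)
  expect_equal(unname(colSums(sc)), unname(1e6 / nf$factors),
               tolerance = 1e-9)
  # RLE path: factor 2 halves a sample
  rf <- structure(list(
    factors = setNames(c(1, 2, 1, 1), colnames(cm)),
    library_sizes = colSums(cm), method = "RLE",
    ref_sample = NA_character_), class = "norm_factors")
  halved <- scaled_expression(cm, rf)
  expect_equal(unname(halved[, 2]), unname(cm[, 2] / 2))
  expect_error(scaled_expression(cm[, 1:3][, c(1, 2, 3)],
                                 structure(list(factors = c(s9 = 1),
                                                library_sizes = c(s9 = 1),
                                                method = "TMM",
                                                ref_sample = "s9"),
                                           class = "norm_factors")),
               "no factor")
})

test_that("GeTMM equals TPM when TMM factors are neutral", {
  cm <- toy_counts()
  lens <- toy_lengths(cm)
  # two samples with identical RPK columns -> factors 1 by symmetry
  cm2 <- cbind(s1 = cm[, 1], s2 = cm[, 1])
  g <- getmm(cm2, lens)
  t_ <- tpm(cm2, lens)
  expect_equal(unclass(g), unclass(t_), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(attr(g, "norm_factors")$factors), c(1, 1))
})

test_that("GeTMM column sums equal 1e6 / factor and preserve within-sample ranks", {
  cm <- toy_counts(seed = 9, n_genes = 40, n_samples = 5)
  lens <- toy_lengths(cm)
  g <- getmm(cm, lens)
  f <- attr(g, "norm_factors")$factors
  expect_equal(unname(colSums(g)), unname(1e6 / f), tolerance = 1e-9)
  r <- unclass(rpk(cm, lens))
  for (j in seq_len(ncol(g))) {
    expect_identical(order(g[, j]), order(r[, j]))
  }
  # depth invariance is exact for the unweighted trimmed mean (the
  # precision weights of the default estimator depend on library size)
  cm2 <- cm
  cm2[, 3] <- cm2[, 3] * 4L
  expect_equal(unclass(getmm(cm2, lens, weighted = FALSE)),
               unclass(getmm(cm, lens, weighted = FALSE)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("GeTMM matches the edgeR recipe (RPK into calcNormFactors + cpm)", {
  cm <- toy_counts(seed = 23, n_genes = 60, n_samples = 6)
  lens <- toy_lengths(cm)
  g <- getmm(cm, lens)
  y <- edgeR::DGEList(counts = unclass(rpk(cm, lens)))
  y <- edgeR::calcNormFactors(y, method = "TMM")
  ref <- edgeR::cpm(y)
  expect_equal(unclass(g), unclass(ref), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("GeTMM resists composition bias where TPM does not", {
  set.seed(77)
  ng <- 400
  base <- rlnorm(ng, 4, 1)
  lens <- setNames(sample(300:20000, ng), paste0("g", 1:ng))
  conc <- cbind(s1 = base, s2 = base)
  hit <- sample(ng, 0.05 * ng)
  conc[hit, "s2"] <- conc[hit, "s2"] * 20
  w <- conc * (lens / 1000)
  counts <- matrix(as.integer(round(sweep(w, 2, 2e6 / colSums(w), "*"))),
                   ng, 2, dimnames = list(names(lens), c("s1", "s2")))
  keep <- setdiff(seq_len(ng), hit)
  g <- getmm(counts, lens)
  t_ <- tpm(counts, lens)
  ratio_g <- median(g[keep, "s2"] / g[keep, "s1"], na.rm = TRUE)
  ratio_t <- median(t_[keep, "s2"] / t_[keep, "s1"], na.rm = TRUE)
  expect_lt(abs(ratio_g - 1), 0.02)
  expect_gt(abs(ratio_t - 1), 0.2)
})

test_that("log2 transform maps zeros to missing and powers of two exactly", {
  m <- expression_matrix(
    matrix(c(8, 0, 1, 0.5), 2, 2,
           dimnames = list(c("g1", "g2"), c("s1", "s2"))),
    method = "TPM", scale = "linear")
  lg <- log2_with_missing(m)
  expect_equal(unname(lg["g1", "s1"]), 3)
  expect_true(is.na(lg["g2", "s1"]))
  expect_equal(unname(lg["g1", "s2"]), 0)
  expect_equal(unname(lg["g2", "s2"]), -1)
  expect_identical(expr_scale(lg), "log2")
  expect_error(log2_with_missing(lg), "already")
})
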