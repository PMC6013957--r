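#' Configuration for the synthetic count generator
#'
#' Collects the parameters of the generative model behind
#' \code{\link{simulate_counts}}. Defaults describe a mid-sized bulk
#' RNA-seq cohort: 1000 genes with lengths log-uniform between 0.2 and
#' 20 kb, 50 samples with library sizes around 6 million reads, log-normal
#' true concentrations spanning several orders of magnitude, and
#' negative-binomial counts with common dispersion 0.4 (variance
#' mu + 0.4 mu^2).
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param length_range Gene-length range in bp; lengths are drawn
#'   log-uniformly over it.
#' @param concentration_meanlog,concentration_sdlog Log-normal law of the
#'   per-gene true concentrations (arbitrary units).
#' @param library_sizes Per-sample expected total read counts; a scalar is
#'   recycled.
#' @param dispersion NB dispersion phi (variance mu + phi mu^2); values
#'   below 1e-8 fall back to Poisson sampling.
#' @param composition_bias List \code{(fraction, fold, samples)}: that
#'   fraction of genes is multiplied by \code{fold} in the given sample
#'   indices before sampling probabilities are renormalized — the classic
#'   few-dominant-transcripts scenario.
#' @param de_genes List \code{(fraction, log2fc)}: that fraction of genes
#'   gets the fold-change \code{2^log2fc} in group-2 samples (second half
#'   of the cohort).
#' @param seed Integer seed; together with the config it determines the
#'   output bit-exactly.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 1000L,
                       n_samples = 50L,
                       length_range = c(200, 20000),
                       concentration_meanlog = 1,
                       concentration_sdlog = 1.5,
                       library_sizes = 6e6,
                       dispersion = 0.4,
                       composition_bias = list(fraction = 0, fold = 1,
                                               samples = integer(0)),
                       de_genes = list(fraction = 0, log2fc = 0),
                       seed = 1L) {
  stopifnot(n_genes >= 2L, n_samples >= 2L,
            length(length_range) == 2L, all(length_range >= 1),
            length_range[1] <= length_range[2],
            dispersion >= 0,
            composition_bias$fraction >= 0,
            composition_bias$fraction <= 1,
            de_genes$fraction >= 0, de_genes$fraction <= 1)
  if (any(library_sizes <= 0)) {
    stop("library sizes must be positive", call. = FALSE)
  }
  library_sizes <- rep_len(library_sizes, n_samples)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 length_range = length_range,
                 concentration_meanlog = concentration_meanlog,
                 concentration_sdlog = concentration_sdlog,
                 library_sizes = library_sizes,
                 dispersion = dispersion,
                 composition_bias = composition_bias,
                 de_genes = de_genes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a count matrix with known ground truth
#'
#' Draws gene lengths log-uniformly, per-gene true concentrations
#' log-normally, and counts negative-binomially with expected value
#' proportional to concentration x length x library size: the read count a
#' gene collects grows with both its molar abundance and its length, which
#' is exactly the confounding that length-corrected normalization removes.
#' Composition-bias genes are multiplied by their fold-change in the
#' affected samples (and DE genes in group-2 samples) before the sampling
#' probabilities are renormalized, so affected samples keep their nominal
#' library size while every unperturbed gene's share of it shrinks.
#'
#' Output is bit-identical across runs for a fixed config (the seed is part
#' of the config).
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{counts} (integer matrix, genes x samples),
#'   \code{lengths} (named bp vector) and \code{truth} (list:
#'   \code{concentration} matrix in arbitrary units, \code{lengths},
#'   \code{true_scale} per sample — the expected count per unit of
#'   concentration x length, \code{group} labels, \code{bias_genes},
#'   \code{de_gene_ids}).
#' @export
simulate_counts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  ns <- cfg$n_samples
  gene_ids <- sprintf("gene%04d", seq_len(ng))
  sample_ids <- sprintf("sample%03d", seq_len(ns))
  lens <- round(exp(stats::runif(ng, log(cfg$length_range[1]),
                                 log(cfg$length_range[2]))))
  lens <- pmax(lens, 1)
  names(lens) <- gene_ids
  base_conc <- stats::rlnorm(ng, cfg$concentration_meanlog,
                             cfg$concentration_sdlog)
  conc <- matrix(base_conc, nrow = ng, ncol = ns,
                 dimnames = list(gene_ids, sample_ids))
  group <- stats::setNames(rep(c(1L, 2L), c(ceiling(ns / 2), floor(ns / 2))),
                           sample_ids)
  de_ids <- character(0)
  if (cfg$de_genes$fraction > 0 && cfg$de_genes$log2fc != 0) {
    n_de <- round(cfg$de_genes$fraction * ng)
    de_idx <- sample.int(ng, n_de)
    de_ids <- gene_ids[de_idx]
    conc[de_idx, group == 2L] <- conc[de_idx, group == 2L] *
      2^cfg$de_genes$log2fc
  }
  bias_ids <- character(0)
  cb <- cfg$composition_bias
  if (cb$fraction > 0 && cb$fold != 1 && length(cb$samples)) {
    n_bias <- round(cb$fraction * ng)
    bias_idx <- sample.int(ng, n_bias)
    bias_ids <- gene_ids[bias_idx]
    conc[bias_idx, cb$samples] <- conc[bias_idx, cb$samples] * cb$fold
  }
  w <- conc * (lens / 1000)
  totals <- colSums(w)
  mu <- sweep(w, 2L, cfg$library_sizes / totals, "*")
  counts <- if (cfg$dispersion < 1e-8) {
    stats::rpois(ng * ns, lambda = mu)
  } else {
    stats::rnbinom(ng * ns, mu = mu, size = 1 / cfg$dispersion)
  }
  counts <- matrix(as.integer(counts), nrow = ng, ncol = ns,
                   dimnames = list(gene_ids, sample_ids))
  truth <- list(concentration = conc,
                lengths = lens,
                true_scale = stats::setNames(cfg$library_sizes / totals,
                                             sample_ids),
                group = group,
                bias_genes = bias_ids,
                de_gene_ids = de_ids)
  list(counts = counts, lengths = lens, truth = truth)
}

#' Write a single-exon-per-gene GTF for simulated genes
#'
#' Emits one gene and one exon record per gene on a synthetic contig, with
#' GENCODE-style attributes (\code{gene_id}, \code{exon_id}); exon width
#' equals the gene length, so \code{\link{gene_lengths_from_gtf}} recovers
#' the input exactly in both modes.
#'
#' @param lengths Named bp vector.
#' @param path Output GTF path.
#' @return Invisibly, the path.
#' @export
write_simulated_gtf <- function(lengths, path) {
  start <- cumsum(c(1, utils::head(unname(lengths), -1L) + 1000))
  end <- start + unname(lengths) - 1
  gene_attr <- sprintf('gene_id "%s";', names(lengths))
  exon_attr <- sprintf('gene_id "%s"; exon_id "%s.e1";',
                       names(lengths), names(lengths))
  lines <- c(
    sprintf("chrS\tsim\tgene\t%d\t%d\t.\t+\t.\t%s", start, end, gene_attr),
    sprintf("chrS\tsim\texon\t%d\t%d\t.\t+\t.\t%s", start, end, exon_attr))
  ord <- order(rep(seq_along(lengths), 2L))
  writeLines(lines[ord], path)
  invisible(path)
}

#' Materialize a named test fixture on disk
#'
#' Writes a seeded count matrix (\code{counts.tsv}), matching annotation
#' (\code{genes.gtf}), gene lengths (\code{lengths.tsv}) and two-group
#' sample labels (\code{labels.tsv}) into a directory.
#'
#' Available fixtures: \code{tiny} (8 genes x 4 samples, hand-checkable),
#' \code{composition} (20 samples, 5% of genes 20-fold up in the last
#' sample), \code{intrasample} (200 genes x 20 samples with a 100-fold
#' length range, for length-bias demonstrations), \code{rs_panel} (the 7
#' recurrence-score genes plus background genes, 12 samples).
#'
#' @param name Fixture name.
#' @param dir Output directory, created if needed.
#' @param seed Integer seed.
#' @return Invisibly, a named list of the written file paths.
#' @export
make_fixture <- function(name = c("tiny", "composition", "intrasample",
                                  "rs_panel"),
                         dir = tempfile("fixture_"), seed = 20L) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop("unknown fixture '", name[1L], "'; valid names: tiny, ",
         "composition, intrasample, rs_panel", call. = FALSE)
  })
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- switch(name,
    tiny = sim_config(n_genes = 8L, n_samples = 4L,
                      length_range = c(500, 5000),
                      library_sizes = 5e4, seed = seed),
    composition = sim_config(n_genes = 500L, n_samples = 20L,
                             library_sizes = 1e6,
                             composition_bias = list(fraction = 0.05,
                                                     fold = 20,
                                                     samples = 20L),
                             seed = seed),
    intrasample = sim_config(n_genes = 200L, n_samples = 20L,
                             length_range = c(200, 20000),
                             library_sizes = 1e6, seed = seed),
    rs_panel = sim_config(n_genes = 50L, n_samples = 12L,
                          library_sizes = 2e5, seed = seed))
  sim <- simulate_counts(cfg)
  counts <- sim$counts
  lens <- sim$lengths
  if (name == "rs_panel") {
    panel <- recurrence_panel()
    panel_genes <- c(panel$stromal, panel$cell_cycle, panel$single)
    rownames(counts)[seq_along(panel_genes)] <- panel_genes
    names(lens)[seq_along(panel_genes)] <- panel_genes
  }
  paths <- list(counts = file.path(dir, "counts.tsv"),
                gtf = file.path(dir, "genes.gtf"),
                lengths = file.path(dir, "lengths.tsv"),
                labels = file.path(dir, "labels.tsv"))
  write_expression_matrix(counts, paths$counts)
  write_simulated_gtf(lens, paths$gtf)
  utils::write.table(data.frame(gene_id = names(lens),
                                length = unname(lens)),
                     paths$lengths, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(sim$truth$group),
                                group = unname(sim$truth$group)),
                     paths$labels, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
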