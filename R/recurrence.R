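#' The seven-gene recurrence-score panel
#'
#' Defines the gene panels and fixed coefficients of the colon-cancer
#' recurrence score: a stromal panel (BGN, FAP, INHBA, coefficient 0.1263
#' on the panel average), a cell-cycle panel (MKI67, MYC, MYBL2,
#' coefficient -0.3158) and the single gene GADD45B (coefficient 0.3406).
#' The unscaled score Rsu is mapped to the reported score as
#' \code{RS = 44.16 * (Rsu + 0.30)}, with negative scores set to zero.
#'
#' @param stromal,cell_cycle Character vectors of 3 gene symbols each.
#' @param single Single gene symbol.
#' @param coef_stromal,coef_cell_cycle,coef_single Panel coefficients.
#' @param scale,offset Affine map from Rsu to the raw score.
#' @return List of class \code{recurrence_panel}.
#' @export
recurrence_panel <- function(stromal = c("BGN", "FAP", "INHBA"),
                             cell_cycle = c("MKI67", "MYC", "MYBL2"),
                             single = "GADD45B",
                             coef_stromal = 0.1263,
                             coef_cell_cycle = -0.3158,
                             coef_single = 0.3406,
                             scale = 44.16,
                             offset = 0.30) {
  genes <- c(stromal, cell_cycle, single)
  if (anyDuplicated(toupper(genes))) {
    stop("panel genes must be distinct", call. = FALSE)
  }
  structure(list(stromal = stromal, cell_cycle = cell_cycle,
                 single = single, coef_stromal = coef_stromal,
                 coef_cell_cycle = coef_cell_cycle,
                 coef_single = coef_single, scale = scale,
                 offset = offset),
            class = "recurrence_panel")
}

# match panel symbols against matrix rownames, case-insensitively and
# ignoring trailing version suffixes (e.g. ENSG....4 / MYC.2)
.match_panel_gene <- function(symbol, gene_ids, id_map = NULL) {
  if (!is.null(id_map) && symbol %in% names(id_map)) {
    idx <- match(id_map[[symbol]], gene_ids)
    return(if (is.na(idx)) NA_integer_ else idx)
  }
  stripped <- toupper(sub("\\.[0-9]+$", "", gene_ids))
  hits <- which(stripped == toupper(symbol))
  if (length(hits) == 0L) NA_integer_ else hits[[1L]]
}

#' Compute the seven-gene recurrence score per sample
#'
#' For each sample the unscaled score is
#' \code{Rsu = 0.1263 * mean(stromal) - 0.3158 * mean(cell cycle) +
#' 0.3406 * GADD45B}, the raw score is \code{44.16 * (Rsu + 0.30)}, and the
#' reported score clips the raw score at zero. The default input is a
#' log2-scale normalized expression matrix (the RT-qPCR comparator,
#' delta-delta Cq, is also logarithmic); linear input is accepted and used
#' as-is.
#'
#' Samples in which any panel gene is missing (NA) are flagged unscorable
#' rather than scored; a panel gene absent from the matrix altogether is an
#' error naming the gene.
#'
#' @param m Numeric gene x sample matrix of normalized expression.
#' @param panel A \code{\link{recurrence_panel}}.
#' @param id_map Optional named character vector mapping panel symbols to
#'   matrix row IDs, overriding symbol matching.
#' @return Data frame: \code{sample_id}, \code{rsu}, \code{rs_raw},
#'   \code{rs} (clipped at 0), \code{scorable}.
#' @examples
#' m <- matrix(0, 7, 1, dimnames = list(
#'   c("BGN", "FAP", "INHBA", "MKI67", "MYC", "MYBL2", "GADD45B"), "s1"))
#' recurrence_score(m)  # rs = 44.16 * 0.30
#' @export
recurrence_score <- function(m, panel = recurrence_panel(),
                             id_map = NULL) {
  stopifnot(inherits(panel, "recurrence_panel"))
  gene_ids <- rownames(m)
  all_genes <- c(panel$stromal, panel$cell_cycle, panel$single)
  idx <- vapply(all_genes, .match_panel_gene, integer(1),
                gene_ids = gene_ids, id_map = id_map)
  if (anyNA(idx)) {
    stop("panel gene(s) absent from matrix: ",
         paste(all_genes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  values <- unclass(m)[idx, , drop = FALSE]
  ns <- length(panel$stromal)
  ncc <- length(panel$cell_cycle)
  stromal <- colMeans(values[seq_len(ns), , drop = FALSE])
  cc <- colMeans(values[ns + seq_len(ncc), , drop = FALSE])
  single <- values[ns + ncc + 1L, ]
  rsu <- panel$coef_stromal * stromal + panel$coef_cell_cycle * cc +
    panel$coef_single * single
  rs_raw <- panel$scale * (rsu + panel$offset)
  scorable <- !is.na(rsu)
  data.frame(sample_id = colnames(m),
             rsu = rsu,
             rs_raw = rs_raw,
             rs = pmax(rs_raw, 0),
             scorable = scorable,
             row.names = NULL)
}
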