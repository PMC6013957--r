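#' Read a gene x sample count matrix from delimited text
#'
#' Parses a text file whose first row is a sample header, first column holds
#' gene identifiers and whose body holds raw (nonnegative, integer) read
#' counts, as produced by merging per-sample counters into a single table.
#'
#' @param path Path to the file.
#' @param delimiter Field separator, default tab.
#' @return An integer matrix with gene IDs as rownames and sample IDs as
#'   colnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t5\t0", "g2\t2\t7"), f)
#' read_count_matrix(f)
#' @export
read_count_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    stop("count matrix file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) {
    stop("parse error at line 1: file is empty, expected a sample header",
         call. = FALSE)
  }
  header <- strsplit(lines[[1L]], delimiter, fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("parse error at line 1: header must contain a gene-ID column ",
         "followed by at least one sample ID", call. = FALSE)
  }
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  n_genes <- length(lines) - 1L
  counts <- matrix(0L, nrow = n_genes, ncol = length(sample_ids))
  gene_ids <- character(n_genes)
  for (i in seq_len(n_genes)) {
    fields <- strsplit(lines[[i + 1L]], delimiter, fixed = TRUE)[[1L]]
    if (length(fields) != length(header)) {
      stop("parse error at line ", i + 1L, ": expected ", length(header),
           " fields, found ", length(fields), call. = FALSE)
    }
    gene_ids[i] <- fields[[1L]]
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    bad <- which(!is.finite(vals))
    if (length(bad)) {
      stop("validation error at row ", i, " (gene '", gene_ids[i],
           "'), column '", sample_ids[bad[1L]], "': non-numeric value '",
           fields[-1L][bad[1L]], "'", call. = FALSE)
    }
    neg <- which(vals < 0)
    if (length(neg)) {
      stop("validation error at row ", i, " (gene '", gene_ids[i],
           "'), column '", sample_ids[neg[1L]], "': negative count ",
           vals[neg[1L]], call. = FALSE)
    }
    nonint <- which(vals != round(vals))
    if (length(nonint)) {
      stop("validation error at row ", i, " (gene '", gene_ids[i],
           "'), column '", sample_ids[nonint[1L]],
           "': non-integer count ", vals[nonint[1L]], call. = FALSE)
    }
    counts[i, ] <- as.integer(round(vals))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ID: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  counts
}

#' Derive gene lengths from a GTF annotation
#'
#' Computes one length in base pairs per gene from the exon records of a GTF
#' file (1-based, end-inclusive coordinates; GENCODE-style
#' \code{key "value"} attributes).
#'
#' Two definitions are offered. \code{"unique_exon_sum"} (the default)
#' deduplicates exon records by their \code{exon_id} attribute within each
#' gene and sums the lengths of the deduplicated exons; an exon shared by
#' several transcripts therefore counts once, but overlapping exons with
#' distinct IDs are double-counted. \code{"merged_union"} merges overlapping
#' exon intervals per gene (strand-agnostic) and sums the merged lengths, so
#' no base is ever counted twice. For every gene
#' \code{unique_exon_sum >= merged_union}.
#'
#' Exon records missing the \code{exon_id} attribute are deduplicated by
#' their (seqname, start, end, strand) tuple instead, which keeps
#' non-GENCODE GTF dialects usable.
#'
#' @param path Path to a GTF file.
#' @param id_attribute Attribute naming the gene, default \code{"gene_id"}.
#' @param exon_id_attribute Attribute naming the exon, default
#'   \code{"exon_id"}.
#' @param mode \code{"unique_exon_sum"} or \code{"merged_union"}.
#' @return Named integer vector: gene ID -> length in bp. Genes with no exon
#'   record are absent.
#' @export
gene_lengths_from_gtf <- function(path,
                                  id_attribute = "gene_id",
                                  exon_id_attribute = "exon_id",
                                  mode = c("unique_exon_sum",
                                           "merged_union")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    stop("GTF file not found: ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  meta <- S4Vectors::mcols(gr)
  if (!id_attribute %in% colnames(meta)) {
    stop("no exon record carries the '", id_attribute, "' attribute",
         call. = FALSE)
  }
  gene <- as.character(meta[[id_attribute]])
  missing_gene <- is.na(gene) | !nzchar(gene)
  if (any(missing_gene)) {
    warning(sum(missing_gene), " exon record(s) lacked '", id_attribute,
            "' and were skipped", call. = FALSE)
    gr <- gr[!missing_gene]
    gene <- gene[!missing_gene]
  }
  if (length(gr) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  if (mode == "merged_union") {
    grl <- GenomicRanges::split(gr, gene)
    lens <- sum(IRanges::width(GenomicRanges::reduce(grl,
                                                     ignore.strand = TRUE)))
    return(stats::setNames(as.integer(lens), names(lens)))
  }
  meta <- S4Vectors::mcols(gr)
  if (exon_id_attribute %in% colnames(meta)) {
    exon_key <- as.character(meta[[exon_id_attribute]])
  } else {
    exon_key <- rep(NA_character_, length(gr))
  }
  coord_key <- paste(as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr), GenomicRanges::end(gr),
                     as.character(GenomicRanges::strand(gr)), sep = ":")
  no_id <- is.na(exon_key) | !nzchar(exon_key)
  exon_key[no_id] <- paste0("coord:", coord_key[no_id])
  keep <- !duplicated(paste(gene, exon_key, sep = "\r"))
  widths <- GenomicRanges::width(gr)[keep]
  lens <- tapply(widths, gene[keep], sum)
  out <- stats::setNames(as.integer(lens), names(lens))
  out[order(names(out))]
}

#' Construct a tagged expression matrix
#'
#' Wraps a numeric gene x sample matrix with the name of the method that
#' produced it and its scale. Linear-scale values must be nonnegative (or
#' NA); log2-scale matrices may hold NA only where the linear value was 0.
#'
#' @param values Numeric matrix with gene rownames and sample colnames.
#' @param method One of \code{"TPM"}, \code{"TMM"}, \code{"RLE"},
#'   \code{"GeTMM"}, \code{"RPK"}, \code{"raw"}.
#' @param scale \code{"linear"} or \code{"log2"}.
#' @return The matrix with class \code{"expr_matrix"} and attributes
#'   \code{method} and \code{scale}.
#' @export
expression_matrix <- function(values,
                              method = c("raw", "TPM", "TMM", "RLE",
                                         "GeTMM", "RPK"),
                              scale = c("linear", "log2")) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("gene and sample identifiers must be unique", call. = FALSE)
  }
  if (scale == "linear" && any(values < 0, na.rm = TRUE)) {
    stop("linear-scale expression values must be nonnegative",
         call. = FALSE)
  }
  structure(values, class = c("expr_matrix", class(values)),
            method = method, scale = scale)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples [%s, %s]\n",
              nrow(x), ncol(x), attr(x, "method"), attr(x, "scale")))
  print(utils::head(unclass(x), 6L))
  invisible(x)
}

#' Expression-matrix metadata accessors
#'
#' @param m An \code{expr_matrix} (plain matrices report \code{"raw"} /
#'   \code{"linear"}).
#' @return A character scalar.
#' @export
expr_method <- function(m) {
  v <- attr(m, "method")
  if (is.null(v)) "raw" else v
}

#' @rdname expr_method
#' @export
expr_scale <- function(m) {
  v <- attr(m, "scale")
  if (is.null(v)) "linear" else v
}

#' Write an expression matrix to tab-delimited text
#'
#' Missing values are serialized as the literal token \code{"NA"}. The file
#' round-trips through \code{\link{read_expression_matrix}} with values
#' preserved to full double precision.
#'
#' @param m Numeric matrix (or \code{expr_matrix}) with dimnames.
#' @param path Output path.
#' @param id_column Header name of the gene-ID column.
#' @return Invisibly, the path.
#' @export
write_expression_matrix <- function(m, path, id_column = "gene_id") {
  if (is.null(colnames(m))) {
    stop("matrix must carry sample colnames", call. = FALSE)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(m)), collapse = "\t"), con)
  if (nrow(m) > 0L) {
    body <- apply(m, 1L, function(v) {
      paste(ifelse(is.na(v), "NA", formatC(v, digits = 17, format = "g")),
            collapse = "\t")
    })
    writeLines(paste(rownames(m), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read an expression matrix written by \code{write_expression_matrix}
#'
#' @param path Path to the file.
#' @param delimiter Field separator.
#' @return Numeric matrix with gene rownames and sample colnames; the
#'   \code{"NA"} sentinel becomes \code{NA}.
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[[1L]], delimiter, fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  n <- length(lines) - 1L
  out <- matrix(NA_real_, nrow = n, ncol = length(sample_ids))
  ids <- character(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[[i + 1L]], delimiter, fixed = TRUE)[[1L]]
    ids[i] <- fields[[1L]]
    v <- fields[-1L]
    v[v == "NA"] <- NA_character_
    out[i, ] <- as.numeric(v)
  }
  dimnames(out) <- list(ids, sample_ids)
  out
}

# shared input validation for the cross-sample normalizers
.check_count_matrix <- function(counts, min_samples = 2L, min_genes = 2L) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene IDs in count matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample IDs in count matrix", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  if (ncol(counts) < min_samples || nrow(counts) < min_genes) {
    stop("need at least ", min_genes, " genes and ", min_samples,
         " samples", call. = FALSE)
  }
  invisible(counts)
}

# align a length table to a count matrix; error or drop unknown genes
.match_lengths <- function(counts, lengths, missing_genes = c("error",
                                                              "drop")) {
  missing_genes <- match.arg(missing_genes)
  if (is.null(names(lengths))) {
    stop("lengths must be a named vector (gene ID -> bp)", call. = FALSE)
  }
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop("all gene lengths must be >= 1 bp", call. = FALSE)
  }
  absent <- setdiff(rownames(counts), names(lengths))
  if (length(absent)) {
    if (missing_genes == "error") {
      stop("no length for gene(s): ",
           paste(utils::head(absent, 10L), collapse = ", "),
           if (length(absent) > 10L) sprintf(" (and %d more)",
                                             length(absent) - 10L) else "",
           call. = FALSE)
    }
    counts <- counts[setdiff(rownames(counts), absent), , drop = FALSE]
  }
  list(counts = counts, lengths = lengths[rownames(counts)])
}
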