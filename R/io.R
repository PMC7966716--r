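## File input/output and core containers.
##
## Count matrices are plain numeric matrices, genes in rows, with unique
## character dimnames.  All joins downstream are by identifier, never by
## position.

.validate_counts <- function(values, gene_ids, column_ids, what = "count matrix") {
  if (!is.matrix(values)) abort(sprintf("%s: expected a matrix", what))
  if (length(gene_ids) != nrow(values)) {
    abort(sprintf("%s: %d gene ids but %d rows", what, length(gene_ids), nrow(values)))
  }
  if (length(column_ids) != ncol(values)) {
    abort(sprintf("%s: %d column ids but %d columns", what, length(column_ids), ncol(values)))
  }
  if (anyDuplicated(gene_ids)) {
    abort(sprintf("%s: duplicated gene ids (e.g. '%s')", what,
                  gene_ids[duplicated(gene_ids)][1]))
  }
  if (anyDuplicated(column_ids)) {
    abort(sprintf("%s: duplicated column ids (e.g. '%s')", what,
                  column_ids[duplicated(column_ids)][1]))
  }
  if (anyNA(values)) abort(sprintf("%s: missing values are not allowed", what))
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("%s: negative entry at gene '%s', column '%s'",
                  what, gene_ids[bad[1]], column_ids[bad[2]]))
  }
  if (max(abs(values - round(values))) > 1e-8) {
    bad <- which(abs(values - round(values)) > 1e-8, arr.ind = TRUE)[1, ]
    abort(sprintf("%s: non-integer entry at gene '%s', column '%s'",
                  what, gene_ids[bad[1]], column_ids[bad[2]]))
  }
  dimnames(values) <- list(gene_ids, column_ids)
  values
}

.guess_format <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  if (grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "tsv"
}

.read_id_file <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  vapply(strsplit(ids, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Read a gene-by-column count matrix
#'
#' Reads raw counts either from a dense TSV (gene identifiers in the first
#' column, column identifiers in the header) or from a MatrixMarket
#' coordinate file with `genes.tsv` / `barcodes.tsv`-style sidecar files
#' (one identifier per line; only the first tab-separated field is used).
#' The result is validated: entries must be non-negative integers and
#' identifiers must be unique.
#'
#' @param path Path to the matrix file.
#' @param format `"tsv"`, `"mtx"`, or `"auto"` (decide from the extension).
#' @param genes_file,columns_file Sidecar paths for the MTX format; default
#'   to `genes.tsv` and `barcodes.tsv` next to `path`.
#' @return A numeric matrix of counts with gene and column ids as dimnames,
#'   row and column order preserved from the file.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx"),
                        genes_file = NULL, columns_file = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  format <- .guess_format(path, format)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) abort(sprintf("parse error in %s: need a gene id column plus data", path))
    gene_ids <- as.character(df[[1]])
    for (j in seq(2, ncol(df))) {
      if (!is.numeric(df[[j]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
        abort(sprintf("parse error in %s: non-numeric value in column '%s', line %d",
                      path, names(df)[j], bad + 1L))
      }
    }
    values <- as.matrix(df[, -1, drop = FALSE])
    .validate_counts(values, gene_ids, colnames(values), what = path)
  } else {
    dir <- dirname(path)
    if (is.null(genes_file)) genes_file <- file.path(dir, "genes.tsv")
    if (is.null(columns_file)) columns_file <- file.path(dir, "barcodes.tsv")
    for (f in c(genes_file, columns_file)) {
      if (!file.exists(f)) abort(sprintf("MTX sidecar file not found: %s", f))
    }
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- .read_id_file(genes_file)
    column_ids <- .read_id_file(columns_file)
    .validate_counts(m, gene_ids, column_ids, what = path)
  }
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: dense TSV or MatrixMarket plus id sidecars.
#'
#' @inheritParams read_counts
#' @param counts Validated count matrix (genes x columns, named dims).
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path, format = c("auto", "tsv", "mtx"),
                         genes_file = NULL, columns_file = NULL) {
  counts <- .validate_counts(counts, rownames(counts), colnames(counts))
  format <- .guess_format(path, format)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dir <- dirname(path)
    if (is.null(genes_file)) genes_file <- file.path(dir, "genes.tsv")
    if (is.null(columns_file)) columns_file <- file.path(dir, "barcodes.tsv")
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), path)
    writeLines(rownames(counts), genes_file)
    writeLines(colnames(counts), columns_file)
  }
  invisible(path)
}

#' Log2 counts-per-million transform
#'
#' Normalizes each column to counts-per-million and returns
#' `log2(pseudocount + CPM)`, the expression scale used for marker testing,
#' centroid construction and all correlations.
#'
#' @param counts Count matrix, genes x columns.
#' @param pseudocount Value added inside the log; 1 by default so that zero
#'   counts map to 0.
#' @return Numeric matrix of the same shape and dimnames.
#' @export
to_log_cpm <- function(counts, pseudocount = 1) {
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    abort(sprintf("column(s) with zero total count: %s",
                  paste(colnames(counts)[totals <= 0], collapse = ", ")))
  }
  log2(pseudocount + sweep(counts, 2, totals, "/") * 1e6)
}

#' Read a column annotation table
#'
#' Expects a TSV with columns `column_id`, `group` (cell type of reference
#' cells, or the enriched cell type of test samples) and optionally
#' `condition`.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `column_id`, `group`, `condition`.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("column_id", "group") %in% names(ann))) {
    abort("annotation file must have columns 'column_id' and 'group'")
  }
  if (!"condition" %in% names(ann)) ann$condition <- NA_character_
  if (anyDuplicated(ann$column_id)) {
    abort(sprintf("duplicated column_id in annotations (e.g. '%s')",
                  ann$column_id[duplicated(ann$column_id)][1]))
  }
  dplyr::select(ann, "column_id", "group", "condition")
}

#' Write a result table as TSV
#'
#' Serializes marker sets, contamination profiles, DE results and similar
#' tabular results with a deterministic column order and full floating-point
#' precision.  List columns (e.g. retained bootstrap draws) are dropped with
#' a note; use the in-memory object to access them.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x)
  is_list <- vapply(x, is.list, logical(1))
  if (any(is_list)) {
    x <- x[, !is_list, drop = FALSE]
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
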