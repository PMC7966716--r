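## Reference products from annotated single-cell data: cell-type marker
## genes, cluster centroids, expected (biological-baseline) correlations.

.check_reference <- function(counts, annotations, min_cells = 3L) {
  missing <- setdiff(colnames(counts), annotations$column_id)
  if (length(missing)) {
    abort(sprintf("%d reference column(s) lack an annotation (e.g. '%s')",
                  length(missing), missing[1]))
  }
  ann <- annotations[match(colnames(counts), annotations$column_id), ]
  sizes <- table(ann$group)
  if (length(sizes) < 2) abort("reference must contain at least 2 cell types")
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    abort(sprintf("cell type(s) with fewer than %d cells: %s",
                  min_cells, paste(small, collapse = ", ")))
  }
  ann
}

#' Per-gene detection fraction
#'
#' Fraction of the selected columns in which a gene has a nonzero count.
#'
#' @param counts Count matrix, genes x columns.
#' @param columns Optional character vector of column ids (or integer/logical
#'   index) selecting the population; defaults to all columns.
#' @return A tibble with columns `gene_id` and `detection`.
#' @export
detection_fraction <- function(counts, columns = NULL) {
  if (is.null(columns)) columns <- seq_len(ncol(counts))
  sub <- counts[, columns, drop = FALSE]
  if (ncol(sub) == 0) abort("empty column subset")
  tibble(gene_id = rownames(counts), detection = unname(rowMeans(sub > 0)))
}

## Vectorized two-part (hurdle) statistics for all genes at once.
## expr: genes x cells log2(1+CPM) matrix; in_cols: logical over cells.
## Detection part: binomial likelihood-ratio test (1 df).
## Continuous part: Gaussian likelihood-ratio test on detected cells (1 df).
.hurdle_stats <- function(expr, in_cols) {
  x1 <- expr[, in_cols, drop = FALSE]
  x2 <- expr[, !in_cols, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 1 || n2 < 1) abort("both groups must be non-empty")

  d1 <- x1 > 0
  d2 <- x2 > 0
  k1 <- rowSums(d1); k2 <- rowSums(d2)
  p1 <- k1 / n1; p2 <- k2 / n2
  p0 <- (k1 + k2) / (n1 + n2)

  binll <- function(k, n, p) {
    out <- numeric(length(k))
    pos <- k > 0
    out[pos] <- out[pos] + k[pos] * log(p[pos])
    z <- (n - k) > 0
    out[z] <- out[z] + (n - k[z]) * log1p(-p[z])
    out
  }
  det_active <- p0 > 0 & p0 < 1
  stat_det <- 2 * (binll(k1, n1, p1) + binll(k2, n2, p2) -
                     binll(k1, n1, p0) - binll(k2, n2, p0))
  stat_det[!det_active] <- 0
  stat_det <- pmax(stat_det, 0)

  s1 <- rowSums(x1 * d1); ss1 <- rowSums(x1^2 * d1)
  s2 <- rowSums(x2 * d2); ss2 <- rowSums(x2^2 * d2)
  cont_active <- k1 >= 2 & k2 >= 2
  rss1 <- pmax(ss1 - s1^2 / pmax(k1, 1), 0) + pmax(ss2 - s2^2 / pmax(k2, 1), 0)
  nn <- k1 + k2
  rss0 <- pmax(ss1 + ss2 - (s1 + s2)^2 / pmax(nn, 1), 0)
  eps <- 1e-10
  stat_cont <- nn * log((rss0 + eps) / (rss1 + eps))
  stat_cont <- pmax(stat_cont, 0)
  ## both groups constant and identical on the continuous part: no signal
  stat_cont[!cont_active] <- 0
  cont_active <- cont_active & (rss0 > eps | rss1 > eps)

  df <- as.integer(det_active) + as.integer(cont_active)
  stat <- stat_det * det_active + stat_cont * cont_active
  p_value <- ifelse(df > 0, pchisq(stat, df, lower.tail = FALSE), 1)

  tibble(
    gene_id = rownames(expr),
    p_value = p_value,
    statistic = stat,
    df = df,
    log2_fold_change = rowMeans(x1) - rowMeans(x2),
    detection_diff = p1 - p2,
    degenerate = df == 0L
  )
}

#' Two-part (hurdle) expression test
#'
#' Compares a target and a background population of cells on the
#' log2(1+CPM) scale with a two-part likelihood-ratio test: a binomial LRT
#' on the detection rate (1 df) plus a Gaussian LRT on expression among
#' detected cells (1 df), summed as a chi-square statistic with summed
#' degrees of freedom.  When one part carries no information (e.g. a gene
#' never or always detected, or too few detected cells) only the other part
#' contributes; when both are degenerate the p-value is 1 and the result is
#' flagged.
#'
#' @param expr_in,expr_out Numeric vectors of per-cell log2(1+CPM) values
#'   for the target group and the rest (at least 3 cells each).
#' @return A one-row tibble with `p_value`, `statistic`, `df`,
#'   `log2_fold_change` (difference of group means), `detection_diff`
#'   (difference of detection fractions) and `degenerate`.
#' @export
hurdle_test <- function(expr_in, expr_out) {
  if (length(expr_in) < 3 || length(expr_out) < 3) {
    abort("both groups need at least 3 cells")
  }
  expr <- matrix(c(expr_in, expr_out), nrow = 1,
                 dimnames = list("gene", NULL))
  in_cols <- c(rep(TRUE, length(expr_in)), rep(FALSE, length(expr_out)))
  res <- .hurdle_stats(expr, in_cols)
  res$gene_id <- NULL
  res[] <- lapply(res, unname)
  res
}

#' Select cell-type marker genes
#'
#' One-vs-rest hurdle testing per cell type with Benjamini-Hochberg
#' correction across genes within each comparison.  A gene is retained as a
#' marker when it is higher in the target type with a detection-fraction
#' difference of at least `min_det_diff`, a log2 fold change of at least
#' `min_log2fc`, and an FDR of at most `max_fdr`.  Genes passing for several
#' types are assigned only to the type with the largest detection
#' difference (ties broken by fold change, then by type name), so markers
#' are mutually exclusive across types.
#'
#' @param counts Reference count matrix (genes x cells).
#' @param annotations Tibble with `column_id` and `group` (cell type) for
#'   every cell; every type needs at least 3 cells.
#' @param min_det_diff Minimum detection-fraction difference (default 0.40).
#' @param min_log2fc Minimum log2 fold change (default 1, i.e. two-fold).
#' @param max_fdr Maximum BH-adjusted p-value (default 0.01).
#' @return A tibble of class `sct_markers` with columns `cell_type`,
#'   `gene_id`, `log2_fold_change`, `detection_diff`, `p_value`, `q_value`.
#' @export
select_markers <- function(counts, annotations, min_det_diff = 0.40,
                           min_log2fc = 1.0, max_fdr = 0.01) {
  ann <- .check_reference(counts, annotations)
  expr <- to_log_cpm(counts)
  types <- sort(unique(ann$group))
  all_stats <- purrr::map_dfr(types, function(ty) {
    st <- .hurdle_stats(expr, ann$group == ty)
    st$q_value <- p.adjust(st$p_value, method = "BH")
    st$cell_type <- ty
    st
  })
  kept <- dplyr::filter(
    all_stats,
    .data$detection_diff >= min_det_diff,
    .data$log2_fold_change >= min_log2fc,
    .data$q_value <= max_fdr
  )
  ## enforce marker exclusivity across types
  kept <- kept |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(.data$detection_diff),
                   dplyr::desc(.data$log2_fold_change),
                   .data$cell_type, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  empty <- setdiff(types, kept$cell_type)
  if (length(empty)) {
    warn(sprintf("no markers survived thresholds for type(s): %s",
                 paste(empty, collapse = ", ")))
  }
  out <- kept |>
    dplyr::arrange(.data$cell_type, .data$q_value,
                   dplyr::desc(.data$detection_diff)) |>
    dplyr::select("cell_type", "gene_id", "log2_fold_change",
                  "detection_diff", "p_value", "q_value")
  class(out) <- c("sct_markers", class(out))
  out
}

#' Truncated interquartile mean
#'
#' Mean of the values remaining after dropping the lowest and highest
#' `trim` fraction: values are sorted and `floor(trim * n)` are removed
#' from each end.
#'
#' @param values Non-empty numeric vector.
#' @param trim Fraction to drop at each end, in `[0, 0.5)`; default 0.25.
#' @return The truncated mean.
#' @export
truncated_iqr_mean <- function(values, trim = 0.25) {
  if (length(values) == 0) abort("empty input")
  if (trim < 0 || trim >= 0.5) abort("trim must be in [0, 0.5)")
  n <- length(values)
  k <- floor(trim * n)
  s <- sort(values)
  mean(s[seq(k + 1L, n - k)])
}

.row_trunc_means <- function(mat, trim) {
  n <- ncol(mat)
  k <- floor(trim * n)
  if (k == 0) return(rowMeans(mat))
  idx <- seq(k + 1L, n - k)
  apply(mat, 1L, function(v) mean(sort.int(v, method = "quick")[idx]))
}

#' Cluster centroids
#'
#' Collapses a reference into per-type centroids: for every gene, the
#' truncated interquartile mean (lowest and highest `trim` fraction of
#' cells excluded) of the per-cell log2(1+CPM) values.  Types with fewer
#' than 4 cells fall back to the plain mean with a warning.
#'
#' @inheritParams select_markers
#' @param trim Fraction trimmed at each end (default 0.25).
#' @return A numeric matrix (genes x cell types) of class `sct_centroids`.
#' @export
compute_centroids <- function(counts, annotations, trim = 0.25) {
  ann <- .check_reference(counts, annotations)
  expr <- to_log_cpm(counts)
  types <- sort(unique(ann$group))
  cent <- vapply(types, function(ty) {
    cols <- ann$group == ty
    if (sum(cols) < 4) {
      warn(sprintf("type '%s' has fewer than 4 cells; using the plain mean", ty))
      rowMeans(expr[, cols, drop = FALSE])
    } else {
      .row_trunc_means(expr[, cols, drop = FALSE], trim)
    }
  }, numeric(nrow(expr)))
  dimnames(cent) <- list(rownames(counts), types)
  structure(cent, trim = trim, class = c("sct_centroids", class(cent)))
}

#' Expected cell-type-to-centroid correlations
#'
#' Estimates the biological baseline similarity between cell types: a
#' random subsample of reference cells of each (annotated) true type is
#' correlated, on marker genes, against every type centroid; the table
#' entry is the mean per-cell Pearson correlation.  These expectations are
#' the denominators that turn raw test-sample correlations into scaled
#' contamination coefficients.
#'
#' @inheritParams select_markers
#' @param markers Marker table (needs `cell_type`, `gene_id`), e.g. from
#'   [select_markers()].
#' @param centroids Centroid matrix from [compute_centroids()].
#' @param n_cells_per_type Cells sampled per true type (default 100; all
#'   cells with a warning when a type is smaller).
#' @param seed Optional integer seed for the subsample.
#' @return A tibble of class `sct_expected` with columns `true_type`,
#'   `reference_type`, `expected_r`, `n_cells_used`.
#' @export
expected_correlations <- function(counts, annotations, markers, centroids,
                                  n_cells_per_type = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_cells_per_type < 1) abort("n_cells_per_type must be >= 1")
  ann <- .check_reference(counts, annotations)
  mg <- intersect(unique(markers$gene_id),
                  intersect(rownames(counts), rownames(centroids)))
  if (length(mg) < 3) abort("fewer than 3 marker genes shared with the reference")
  types <- sort(unique(ann$group))
  expr <- to_log_cpm(counts)
  purrr::map_dfr(types, function(ty) {
    cells <- which(ann$group == ty)
    if (length(cells) < n_cells_per_type) {
      warn(sprintf("type '%s' has %d cells (< %d); using all of them",
                   ty, length(cells), n_cells_per_type))
      take <- cells
    } else {
      take <- cells[sample.int(length(cells), n_cells_per_type)]
    }
    r <- cor(expr[mg, take, drop = FALSE], centroids[mg, , drop = FALSE])
    tibble(
      true_type = ty,
      reference_type = colnames(centroids),
      expected_r = unname(colMeans(r, na.rm = TRUE)),
      n_cells_used = length(take)
    )
  }) |>
    (\(x) { class(x) <- c("sct_expected", class(x)); x })()
}
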