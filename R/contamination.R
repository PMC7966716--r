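## Scoring test samples against reference centroids: bootstrap Pearson
## correlations on marker genes and scaled contamination coefficients.

.cor_to_centroids <- function(x, cent) {
  ## x: named numeric vector (marker log2(1+CPM)); cent: markers x types
  drop(suppressWarnings(cor(x, cent)))
}

#' Marker-space correlation of one sample to every reference type
#'
#' Pearson correlation of a sample's log2(1+CPM) values, restricted to a
#' marker-gene subset, against each centroid column on the same genes.
#'
#' @param sample_expr Named numeric vector of log2(1+CPM) values for one
#'   sample (names are gene ids).
#' @param centroids Centroid matrix (genes x types), e.g. from
#'   [compute_centroids()].
#' @param marker_genes Character vector of marker gene ids; at least 3 must
#'   be present in both the sample and the centroids.
#' @return A tibble with columns `reference_type` and `r`.  Types whose
#'   centroid (or the sample) has zero variance on the subset get `NA` with
#'   a warning.
#' @export
marker_correlation <- function(sample_expr, centroids, marker_genes) {
  genes <- intersect(marker_genes, intersect(names(sample_expr), rownames(centroids)))
  if (length(genes) < 3) {
    abort("need at least 3 marker genes present in both sample and centroids")
  }
  r <- .cor_to_centroids(sample_expr[genes], centroids[genes, , drop = FALSE])
  if (anyNA(r)) {
    warn(sprintf("zero-variance vector: correlation undefined for type(s) %s",
                 paste(colnames(centroids)[is.na(r)], collapse = ", ")))
  }
  tibble(reference_type = colnames(centroids), r = unname(r))
}

.prep_marker_draw <- function(sample_expr, centroids, markers,
                              subsample_fraction) {
  markers <- dplyr::distinct(markers, .data$cell_type, .data$gene_id)
  present <- markers$gene_id %in% intersect(names(sample_expr), rownames(centroids))
  if (any(!present)) {
    markers <- markers[present, , drop = FALSE]
  }
  if (nrow(markers) == 0) abort("no marker genes shared with sample and centroids")
  split_idx <- split(markers$gene_id, markers$cell_type)
  m_total <- nrow(markers)
  k <- length(split_idx)
  n_per_type <- max(1L, floor(subsample_fraction * m_total / k))
  short <- names(split_idx)[lengths(split_idx) < n_per_type]
  if (length(short)) {
    warn(sprintf("type(s) with fewer than %d markers, using all of them: %s",
                 n_per_type, paste(short, collapse = ", ")))
  }
  list(split_idx = split_idx, n_per_type = n_per_type)
}

#' Bootstrap marker-subsample correlations for one sample
#'
#' Repeatedly draws a random subset of the marker genes -- an equal number
#' per cell type, `floor(subsample_fraction * M / K)` for `M` total markers
#' over `K` types, capped at each type's marker count -- and correlates the
#' sample against every centroid on the pooled draw.  The consensus
#' correlation is the mean over iterations; the 2.5%/97.5% quantiles of the
#' draws give a per-sample confidence interval, and the full set of draws
#' is retained.
#'
#' @inheritParams marker_correlation
#' @param markers Marker table with `cell_type` and `gene_id` columns.
#' @param subsample_fraction Fraction of the total marker set used per
#'   iteration (default 0.6).
#' @param n_iter Number of bootstrap iterations (default 10000).
#' @param seed Optional integer seed.
#' @return A tibble with one row per reference type: `reference_type`,
#'   `consensus_r`, `ci_low`, `ci_high`, `n_iter` and a list column
#'   `bootstrap_r` holding the per-iteration correlations.
#' @export
bootstrap_correlations <- function(sample_expr, centroids, markers,
                                   subsample_fraction = 0.6, n_iter = 10000L,
                                   seed = NULL) {
  if (n_iter < 1) abort("n_iter must be >= 1")
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    abort("subsample_fraction must be in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  prep <- .prep_marker_draw(sample_expr, centroids, markers, subsample_fraction)
  all_genes <- unlist(prep$split_idx, use.names = FALSE)
  x <- sample_expr[all_genes]
  cent <- centroids[all_genes, , drop = FALSE]
  ## per-type positions within the pooled vector
  pos <- split(seq_along(all_genes), rep(names(prep$split_idx), lengths(prep$split_idx)))
  npt <- prep$n_per_type
  boot <- matrix(NA_real_, nrow = n_iter, ncol = ncol(cent),
                 dimnames = list(NULL, colnames(cent)))
  for (it in seq_len(n_iter)) {
    idx <- unlist(lapply(pos, function(ix) {
      if (length(ix) <= npt) ix else ix[sample.int(length(ix), npt)]
    }), use.names = FALSE)
    boot[it, ] <- .cor_to_centroids(x[idx], cent[idx, , drop = FALSE])
  }
  tibble(
    reference_type = colnames(cent),
    consensus_r = unname(colMeans(boot, na.rm = TRUE)),
    ci_low = unname(apply(boot, 2, quantile, probs = 0.025, na.rm = TRUE, names = FALSE)),
    ci_high = unname(apply(boot, 2, quantile, probs = 0.975, na.rm = TRUE, names = FALSE)),
    n_iter = as.integer(n_iter),
    bootstrap_r = lapply(seq_len(ncol(boot)), function(j) boot[, j])
  )
}

#' Scale consensus correlations by expected correlations
#'
#' Divides each sample-to-type consensus correlation by the expected
#' correlation of a pure cell of the sample's labeled type to that
#' reference type.  A scaled coefficient near 1 means the sample behaves
#' like a pure cell of its labeled type; values above 1 indicate off-target
#' contamination.  Pairings whose expected correlation is at or below 0.05
#' give an unstable denominator and are reported as `NA` with a warning.
#'
#' @param profiles Tibble with columns `labeled_type`, `reference_type`,
#'   `consensus_r` (and optionally more), e.g. the output of
#'   [estimate_contamination()] before scaling.
#' @param expected Expected-correlation table from
#'   [expected_correlations()].
#' @return `profiles` with columns `expected_r` and `scaled_coefficient`
#'   added.
#' @export
scale_coefficients <- function(profiles, expected) {
  missing <- setdiff(unique(profiles$labeled_type), unique(expected$true_type))
  if (length(missing)) {
    abort(sprintf("expected-correlation table has no row for labeled type(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- profiles |>
    dplyr::left_join(
      dplyr::select(as_tibble(expected), labeled_type = "true_type",
                    "reference_type", "expected_r"),
      by = c("labeled_type", "reference_type")
    ) |>
    dplyr::mutate(
      scaled_coefficient = dplyr::if_else(
        !is.na(.data$expected_r) & .data$expected_r > 0.05,
        .data$consensus_r / .data$expected_r,
        NA_real_
      )
    )
  n_bad <- sum(!is.na(out$consensus_r) & is.na(out$scaled_coefficient))
  if (n_bad > 0) {
    warn(sprintf("%d pairing(s) with expected correlation <= 0.05: coefficient set to NA",
                 n_bad))
  }
  class(out) <- unique(c("sct_contamination", class(out)))
  out
}

#' Estimate contamination profiles for a set of samples
#'
#' End-to-end per-sample scoring: log2(1+CPM) transform, bootstrap
#' marker-subsample correlations against the reference centroids, and
#' scaling by the expected correlations of the sample's labeled (enriched)
#' cell type.
#'
#' @param counts Test count matrix (genes x samples).
#' @param annotations Tibble with `column_id` and `group` (the enriched
#'   cell type of each sample).
#' @param centroids Centroid matrix from [compute_centroids()].
#' @param markers Marker table (`cell_type`, `gene_id`).
#' @param expected Expected-correlation table from
#'   [expected_correlations()].
#' @inheritParams bootstrap_correlations
#' @return A tibble of class `sct_contamination`, one row per sample x
#'   reference type, with `sample_id`, `labeled_type`, `reference_type`,
#'   `consensus_r`, `ci_low`, `ci_high`, `expected_r`,
#'   `scaled_coefficient` and the `bootstrap_r` list column.
#' @export
estimate_contamination <- function(counts, annotations, centroids, markers,
                                   expected, subsample_fraction = 0.6,
                                   n_iter = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  missing <- setdiff(colnames(counts), annotations$column_id)
  if (length(missing)) {
    abort(sprintf("unannotated sample(s): %s", paste(missing, collapse = ", ")))
  }
  ann <- annotations[match(colnames(counts), annotations$column_id), ]
  expr <- to_log_cpm(counts)
  res <- purrr::map_dfr(seq_len(ncol(expr)), function(j) {
    prof <- bootstrap_correlations(expr[, j], centroids, markers,
                                   subsample_fraction = subsample_fraction,
                                   n_iter = n_iter, seed = NULL)
    prof$sample_id <- colnames(expr)[j]
    prof$labeled_type <- ann$group[j]
    prof
  })
  res <- dplyr::relocate(res, "sample_id", "labeled_type", "reference_type")
  scale_coefficients(res, expected)
}

#' Rank off-target cell types and extract DE covariates
#'
#' Ranks the reference types other than the labeled type by their mean
#' scaled contamination coefficient across samples and returns the top `k`
#' together with the per-sample coefficient vectors -- the covariates used
#' for contamination-corrected differential expression.
#'
#' @param profiles An `sct_contamination` tibble whose samples all share
#'   one labeled type.
#' @param k Number of off-target types to keep (default 4); all available
#'   types with a warning when fewer exist.
#' @return A list of class `sct_offtarget` with `types` (tibble
#'   `reference_type`, `mean_scaled`, ranked) and `covariates` (tibble with
#'   `sample_id` and one column per selected type).
#' @export
rank_off_target <- function(profiles, k = 4L) {
  if (nrow(profiles) == 0) abort("no contamination profiles supplied")
  if (length(unique(profiles$labeled_type)) != 1) {
    abort("all profiles must share the same labeled type")
  }
  off <- dplyr::filter(as_tibble(profiles),
                       .data$reference_type != .data$labeled_type)
  ranking <- off |>
    dplyr::group_by(.data$reference_type) |>
    dplyr::summarise(mean_scaled = mean(.data$scaled_coefficient, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_scaled))
  if (nrow(ranking) < k) {
    warn(sprintf("only %d off-target type(s) available (k = %d)", nrow(ranking), k))
    k <- nrow(ranking)
  }
  top <- head(ranking, k)
  covariates <- off |>
    dplyr::filter(.data$reference_type %in% top$reference_type) |>
    dplyr::select("sample_id", "reference_type", "scaled_coefficient") |>
    tidyr::pivot_wider(names_from = "reference_type",
                       values_from = "scaled_coefficient") |>
    dplyr::select(dplyr::all_of(c("sample_id", top$reference_type)))
  structure(list(types = top, covariates = covariates), class = "sct_offtarget")
}
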