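## Differential expression with and without contamination covariates,
## per-gene AIC model comparison, and evaluation against simulation truth.

#' Pre-filter genes by per-condition zero counts
#'
#' Removes a gene when, in at least one condition, the number of
#' zero-count samples strictly exceeds half the samples of that condition.
#' Zeros in exactly half of the samples do not trigger removal.
#'
#' @param counts Count matrix, genes x samples.
#' @param condition Character/factor vector of per-sample conditions
#'   (aligned with the matrix columns), with at least 2 samples each.
#' @return The filtered count matrix, with attribute `n_removed`.
#' @export
prefilter_genes <- function(counts, condition) {
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) {
    abort("condition labels must match the matrix columns")
  }
  tab <- table(condition)
  if (any(tab < 2)) abort("need at least 2 samples per condition")
  drop <- rep(FALSE, nrow(counts))
  for (cond in names(tab)) {
    sub <- counts[, condition == cond, drop = FALSE]
    drop <- drop | rowSums(sub == 0) > ncol(sub) / 2
  }
  if (all(drop)) {
    abort("pre-filter removed every gene; review the zero-count threshold")
  }
  out <- counts[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

.prepare_covariates <- function(covariates, sample_ids) {
  if (is.null(covariates)) return(NULL)
  if (inherits(covariates, "sct_offtarget")) covariates <- covariates$covariates
  covariates <- as.data.frame(covariates)
  if (!"sample_id" %in% names(covariates)) {
    abort("covariates must contain a 'sample_id' column")
  }
  idx <- match(sample_ids, covariates$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("covariates missing for sample(s): %s",
                  paste(sample_ids[is.na(idx)], collapse = ", ")))
  }
  cv <- as.matrix(covariates[idx, setdiff(names(covariates), "sample_id"),
                             drop = FALSE])
  storage.mode(cv) <- "double"
  if (anyNA(cv)) abort("covariates contain missing values")
  ## drop zero-variance covariates
  sds <- apply(cv, 2, sd)
  if (any(sds < 1e-12)) {
    warn(sprintf("dropping zero-variance covariate(s): %s",
                 paste(colnames(cv)[sds < 1e-12], collapse = ", ")))
    cv <- cv[, sds >= 1e-12, drop = FALSE]
  }
  if (ncol(cv) == 0) return(NULL)
  ## mean-center, then prune near-collinear columns greedily, keeping the
  ## earlier (higher-ranked) one
  cv <- scale(cv, center = TRUE, scale = FALSE)
  keep <- logical(ncol(cv))
  for (j in seq_len(ncol(cv))) {
    kept <- which(keep)
    r <- if (length(kept)) suppressWarnings(abs(cor(cv[, j], cv[, kept, drop = FALSE]))) else 0
    if (length(r) && any(r > 0.95, na.rm = TRUE)) {
      warn(sprintf("dropping covariate '%s': |r| > 0.95 with a higher-ranked covariate",
                   colnames(cv)[j]))
    } else {
      keep[j] <- TRUE
    }
  }
  cv[, keep, drop = FALSE]
}

#' Differential expression with optional contamination covariates
#'
#' Pre-filters genes, computes median-of-ratios size factors, fits a
#' per-gene negative-binomial GLM of counts on condition (plus any
#' covariates, e.g. the top off-target scaled contamination coefficients
#' from [rank_off_target()]), applies Benjamini-Hochberg correction across
#' the retained genes and calls differentially expressed genes at
#' `q < fdr`.  Covariates are mean-centered; zero-variance or
#' near-collinear (|r| > 0.95) covariates are dropped with a warning.
#'
#' @param counts Count matrix (genes x samples).
#' @param annotations Tibble with `column_id` and `condition` for every
#'   sample; exactly two conditions.  When a `control`/`ctrl` level is
#'   present it is used as the reference level, otherwise the first level
#'   alphabetically.
#' @param covariates Optional: an `sct_offtarget` object or a data frame
#'   with `sample_id` plus numeric columns.
#' @param fdr FDR threshold for calling DEGs (default 0.1).
#' @param prefilter Apply [prefilter_genes()] first (default `TRUE`).
#' @return A tibble of class `sct_de` with one row per retained gene:
#'   `gene_id`, `log2_fc`, `wald_p`, `q_value`, `aic`, `converged`,
#'   `called`.  Attributes: `model_spec`, `n_genes_prefiltered`,
#'   `size_factors`, `condition_levels`, `fdr`.
#' @export
run_de <- function(counts, annotations, covariates = NULL, fdr = 0.1,
                   prefilter = TRUE) {
  idx <- match(colnames(counts), annotations$column_id)
  if (anyNA(idx)) {
    abort(sprintf("unannotated sample(s): %s",
                  paste(colnames(counts)[is.na(idx)], collapse = ", ")))
  }
  cond <- as.character(annotations$condition[idx])
  levels <- sort(unique(cond))
  if (length(levels) != 2) abort("exactly two conditions are required")
  ref <- if (any(tolower(levels) %in% c("control", "ctrl"))) {
    levels[tolower(levels) %in% c("control", "ctrl")][1]
  } else {
    levels[1]
  }
  alt <- setdiff(levels, ref)
  if (prefilter) counts <- prefilter_genes(counts, cond)
  sf <- size_factors_mor(counts)
  cv <- .prepare_covariates(covariates, colnames(counts))
  design <- cbind(condition = as.numeric(cond == alt), cv)
  fits <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    fit_nb_glm(counts[i, ], design, size_factors = sf)
  })
  out <- tibble(
    gene_id = rownames(counts),
    log2_fc = fits$coefficient,
    wald_p = fits$wald_p,
    q_value = p.adjust(fits$wald_p, method = "BH"),
    aic = fits$aic,
    converged = fits$converged
  )
  out$called <- out$q_value < fdr
  attr(out, "model_spec") <- c("condition", colnames(cv))
  attr(out, "n_genes_prefiltered") <- nrow(counts)
  attr(out, "size_factors") <- sf
  attr(out, "condition_levels") <- c(reference = ref, alternative = alt)
  attr(out, "fdr") <- fdr
  class(out) <- c("sct_de", class(out))
  out
}

#' Per-gene AIC comparison of two DE models
#'
#' Fraction of genes, over the shared converged gene set, whose AIC is
#' strictly smaller in the covariate model; ties count as not preferring
#' the covariate model.
#'
#' @param fit_with,fit_without `sct_de` results for the covariate and the
#'   minimal model.
#' @return The fraction of genes preferring the covariate model, with
#'   attribute `n_genes`.
#' @export
compare_models_aic <- function(fit_with, fit_without) {
  shared <- intersect(fit_with$gene_id[fit_with$converged],
                      fit_without$gene_id[fit_without$converged])
  if (length(shared) == 0) abort("no shared converged genes between the two fits")
  a_with <- fit_with$aic[match(shared, fit_with$gene_id)]
  a_without <- fit_without$aic[match(shared, fit_without$gene_id)]
  structure(mean(a_with < a_without), n_genes = length(shared))
}

.auroc <- function(p, is_de) {
  n1 <- sum(is_de)
  n0 <- sum(!is_de)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  ## ties receive half credit through midranks
  (sum(r[!is_de]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}

#' Evaluate DE calls against simulation truth
#'
#' Computes the false-positive fraction (false discoveries among called
#' DEGs), the false-negative fraction (missed genes among truly DE genes)
#' and the AUROC of the p-value ranking (probability that a random truly
#' DE gene has a smaller p-value than a random non-DE gene, ties counting
#' one half) over all genes in `result`.
#'
#' @param result An `sct_de` tibble.
#' @param truth Tibble with `gene_id` and logical `is_de` covering every
#'   gene in `result` (e.g. the `gene_truth` of a simulation).
#' @param fdr Call threshold on `q_value` (default 0.1).
#' @return A one-row tibble of class `sct_eval`: `fpf`, `fnf`, `auroc`,
#'   `n_called`, `n_true_de`, `n_genes`.  `fpf` is `NA` when nothing is
#'   called; `fnf` is `NA` when no gene is truly DE.
#' @export
evaluate_calls <- function(result, truth, fdr = 0.1) {
  idx <- match(result$gene_id, truth$gene_id)
  if (anyNA(idx)) {
    abort(sprintf("truth lacks %d gene(s) present in the DE result", sum(is.na(idx))))
  }
  is_de <- as.logical(truth$is_de[idx])
  called <- result$q_value < fdr
  tp <- sum(called & is_de)
  fp <- sum(called & !is_de)
  fn <- sum(!called & is_de)
  out <- tibble(
    fpf = if (tp + fp == 0) NA_real_ else fp / (fp + tp),
    fnf = if (tp + fn == 0) NA_real_ else fn / (fn + tp),
    auroc = .auroc(result$wald_p, is_de),
    n_called = tp + fp,
    n_true_de = tp + fn,
    n_genes = length(is_de)
  )
  class(out) <- c("sct_eval", class(out))
  out
}

#' Minimum hypergeometric overlap p-value of two rankings
#'
#' Slides a threshold `t = step, 2 step, ...` down two rankings of the same
#' gene universe and, at each threshold, computes the upper-tail
#' hypergeometric probability of the observed overlap between the two
#' top-`t` lists; returns the minimum over thresholds.
#'
#' @param ranked_a,ranked_b Character vectors ranking the same gene set
#'   (best first).
#' @param step Threshold increment, in `[1, universe size]`.
#' @return The minimum hypergeometric p-value, with attribute `thresholds`
#'   (a tibble of threshold, overlap and p-value).
#' @export
min_hypergeometric_overlap <- function(ranked_a, ranked_b, step = 100L) {
  if (length(ranked_a) != length(ranked_b) ||
      !setequal(ranked_a, ranked_b)) {
    abort("the two rankings must cover the same gene universe")
  }
  n <- length(ranked_a)
  if (step <= 0 || step > n) abort("step must be in [1, universe size]")
  ts <- seq(step, n, by = step)
  res <- purrr::map_dfr(ts, function(t) {
    k <- length(intersect(ranked_a[seq_len(t)], ranked_b[seq_len(t)]))
    tibble(threshold = t, overlap = k,
           p = phyper(k - 1, t, n - t, t, lower.tail = FALSE))
  })
  structure(min(res$p), thresholds = res)
}
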