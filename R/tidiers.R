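## broom-style tidy()/glance() methods for the package's result objects.

#' Tidy a contamination-profile table
#'
#' Returns the per-sample, per-reference-type coefficients as a plain
#' tibble, dropping the bootstrap draw list column.
#'
#' @param x An `sct_contamination` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sct_contamination
#' @export
tidy.sct_contamination <- function(x, ...) {
  out <- as_tibble(x)
  out$bootstrap_r <- NULL
  class(out) <- setdiff(class(out), "sct_contamination")
  out
}

#' Summarize a contamination-profile table
#'
#' One row per labeled type x reference type with the mean consensus
#' correlation and mean scaled coefficient across samples.
#'
#' @inheritParams tidy.sct_contamination
#' @return A tibble.
#' @method glance sct_contamination
#' @export
glance.sct_contamination <- function(x, ...) {
  as_tibble(x) |>
    dplyr::group_by(.data$labeled_type, .data$reference_type) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_consensus_r = mean(.data$consensus_r, na.rm = TRUE),
      mean_scaled = mean(.data$scaled_coefficient, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Tidy a differential-expression result
#'
#' @param x An `sct_de` object.
#' @param ... Unused.
#' @return The per-gene result tibble without the `sct_de` class.
#' @method tidy sct_de
#' @export
tidy.sct_de <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "sct_de")
  out
}

#' Summarize a differential-expression result
#'
#' @inheritParams tidy.sct_de
#' @return A one-row tibble with the model specification, gene counts and
#'   number of calls.
#' @method glance sct_de
#' @export
glance.sct_de <- function(x, ...) {
  tibble(
    model = paste(attr(x, "model_spec"), collapse = " + "),
    n_genes = nrow(x),
    n_converged = sum(x$converged),
    n_called = sum(x$called),
    fdr = attr(x, "fdr")
  )
}

#' Tidy an off-target ranking
#'
#' @param x An `sct_offtarget` object from [rank_off_target()].
#' @param ... Unused.
#' @return The ranked types tibble.
#' @method tidy sct_offtarget
#' @export
tidy.sct_offtarget <- function(x, ...) x$types

#' @export
print.sct_offtarget <- function(x, ...) {
  cat(sprintf("Top %d off-target cell type(s) by mean scaled coefficient:\n",
              nrow(x$types)))
  print(x$types)
  invisible(x)
}
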