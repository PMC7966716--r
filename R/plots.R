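## ggplot2 displays for the package's result objects.

#' Plot contamination profiles
#'
#' Boxplots of scaled contamination coefficients per reference cell type,
#' faceted by the samples' labeled (enriched) type, with the purity
#' expectation of 1.0 marked.  Values near 1 mean a sample behaves like a
#' pure cell of its labeled type; larger values indicate off-target
#' contamination.
#'
#' @param object An `sct_contamination` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sct_contamination
#' @export
autoplot.sct_contamination <- function(object, ...) {
  df <- tidy.sct_contamination(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference_type,
                                   y = .data$scaled_coefficient)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~labeled_type) +
    ggplot2::labs(x = "reference cell type",
                  y = "scaled contamination coefficient") +
    ggplot2::theme_bw()
}

#' Volcano plot of a differential-expression result
#'
#' @param object An `sct_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sct_de
#' @export
autoplot.sct_de <- function(object, ...) {
  df <- tidy.sct_de(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(pmax(.data$wald_p, 1e-300)),
                                   colour = .data$called)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 Wald p",
                  colour = sprintf("q < %.2g", attr(object, "fdr") %||% 0.1)) +
    ggplot2::theme_bw()
}

#' Heatmap of expected cell-type correlations
#'
#' Tile plot of the expected correlation of single cells of each true type
#' to every reference centroid; rows should be dominated by their diagonal
#' entry in clean references.
#'
#' @param object An `sct_expected` tibble from [expected_correlations()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sct_expected
#' @export
autoplot.sct_expected <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$reference_type, y = .data$true_type,
                               fill = .data$expected_r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$expected_r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = "reference centroid", y = "true cell type",
                  fill = "expected r") +
    ggplot2::theme_minimal()
}
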