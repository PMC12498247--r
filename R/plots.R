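#' Plot an equidistant conformer selection
#'
#' Feature value against conformer energy, with selected conformers
#' highlighted and the equidistant target values as horizontal lines.
#'
#' @param object A `conformer_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conformer_selection <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$energy, y = .data$value)) +
    ggplot2::geom_hline(yintercept = object$targets, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected,
                                     shape = .data$is_lowest_energy),
                        size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey65",
                                            `TRUE` = "#D55E00")) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(x = "relative energy (kcal/mol)",
                  y = object$selection_feature,
                  colour = "selected", shape = "lowest energy") +
    ggplot2::theme_minimal()
}

#' Plot observed against predicted values of a model report
#'
#' @param object A `model_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted,
                               colour = .data$split)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "observed (kcal/mol)", y = "predicted (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot range coverage of a conformer selection
#'
#' Bar chart of the per-feature `range_fraction` from [coverage_metrics()].
#'
#' @param coverage Tibble from [coverage_metrics()].
#' @return A ggplot.
#' @export
plot_coverage <- function(coverage) {
  stopifnot(all(c("feature", "range_fraction") %in% names(coverage)))
  ggplot2::ggplot(coverage,
                  ggplot2::aes(x = stats::reorder(.data$feature,
                                                  .data$range_fraction),
                               y = .data$range_fraction)) +
    ggplot2::geom_col(fill = "#0072B2") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of full-ensemble range covered") +
    ggplot2::theme_minimal()
}

#' Plot permutation feature importances
#'
#' @param importance Tibble from [permutation_importance()].
#' @param top Show only the `top` most important features.
#' @return A ggplot.
#' @export
plot_importance <- function(importance, top = 15) {
  stopifnot(all(c("feature", "importance") %in% names(importance)))
  d <- head(dplyr::arrange(importance, dplyr::desc(.data$importance)), top)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$feature,
                                                     .data$importance),
                                  y = .data$importance)) +
    ggplot2::geom_col(fill = "#009E73") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "RMSE increase on permutation (kcal/mol)") +
    ggplot2::theme_minimal()
}
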