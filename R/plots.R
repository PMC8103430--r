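#' Bar chart of mean hours (or adventure level) per place by role
#'
#' Visualises a [describe_by_place()] summary: one bar per place per
#' informant role, for either the mean annual hours or the mean adventure
#' rating.
#'
#' @param descriptives Output of [describe_by_place()].
#' @param what `"hours"` or `"adventure"`.
#' @return A ggplot object.
#' @export
plot_place_means <- function(descriptives, what = c("hours", "adventure")) {
  what <- match.arg(what)
  ycol <- if (what == "hours") "mean_hours" else "mean_adventure"
  ylab <- if (what == "hours") "Mean annual hours of play" else
    "Mean adventure level (1-5)"
  ggplot2::ggplot(descriptives,
                  ggplot2::aes(x = .data$place, y = .data[[ycol]],
                               fill = .data$role)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = ylab, fill = "Informant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot an agreement table
#'
#' Concordance estimates with confidence intervals, one row per metric,
#' optionally faceted by analysis when several `cps_agreement` tables are
#' bound together.
#'
#' @param object A `cps_agreement` tibble (from [cross_informant()] or
#'   [test_retest()], possibly row-bound).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cps_agreement <- function(object, ...) {
  p <- ggplot2::ggplot(
    object[object$estimable, , drop = FALSE],
    ggplot2::aes(x = .data$ccc,
                 y = factor(.data$metric, levels = rev(cps_metric_names())))) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.65), linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Concordance correlation coefficient", y = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(object$analysis)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$analysis))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
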