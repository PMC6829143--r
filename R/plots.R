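# ggplot2 helpers for the main result types.

#' @export
autoplot.cnv_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::coord_equal()
}

#' Feature-importance profile by flank offset
#'
#' Importance of each statistic as a function of the sub-window offset from
#' the focal sub-window (offset 0), the diagnostic view of what the
#' classifier actually uses.
#'
#' @param model A fitted `cnv_classifier`.
#' @param target `"class"` or `"copy_number"`.
#' @return A ggplot object.
#' @export
plot_feature_importances <- function(model, target = "class") {
  imp <- feature_importances(model, target)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$offset, y = .data$importance,
                                    fill = .data$statistic)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Sub-window offset from focal window",
                  y = "Importance (mean decrease in impurity)",
                  fill = "Statistic")
}

#' @export
autoplot.cnv_classifier <- function(object, ...) {
  plot_feature_importances(object, ...)
}

#' Standardized coverage track with window calls
#'
#' @param stats A [window_stats()] tibble.
#' @param calls Optional window or interval calls with `cnv_class` or
#'   `cnv_type` to highlight.
#' @return A ggplot object.
#' @export
plot_coverage_track <- function(stats, calls = NULL) {
  p <- ggplot2::ggplot(stats, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                           y = .data$std_median)) +
    ggplot2::geom_step(colour = "black") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "Position (bp)", y = "Standardized median coverage")
  if (!is.null(calls) && nrow(calls) > 0) {
    cls <- calls$cnv_type %||% calls$cnv_class
    shade <- calls[cls != "normal", ]
    shade$what <- cls[cls != "normal"]
    if (nrow(shade) > 0) {
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf, fill = .data$what),
        alpha = 0.25, inherit.aes = FALSE) +
        ggplot2::scale_fill_manual(
          values = c(duplication = "firebrick", deletion = "steelblue"),
          name = NULL)
    }
  }
  p
}
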