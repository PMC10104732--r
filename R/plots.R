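#' Plot the threshold-scan objective curve
#'
#' @param object A `threshold_result`.
#' @param ... Unused.
#' @return A ggplot: `G(t)` over the scanned thresholds with the optimum
#'   marked.
#' @export
autoplot.threshold_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$t, y = .data$G)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$t_star, linetype = 2, colour = "firebrick") +
    ggplot2::labs(
      x = "threshold t (intensity)", y = "within-class scatter G(t)",
      title = sprintf("Clustering-threshold objective (t* = %g)", object$t_star)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the pressure field of a flow solution
#'
#' @param object A `flow_solution`.
#' @param ... Unused.
#' @return A ggplot of pressure (mmHg, left) and lumen radius (mm) along
#'   the vessel.
#' @export
autoplot.flow_solution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pressure_mmhg), colour = "firebrick") +
    ggplot2::labs(
      x = "arclength s (mm)", y = "pressure (mmHg)",
      title = sprintf("Steady flow solution (Q = %.3g mL/s)", attr(object, "q_ml_s"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot FFR against stenosis severity
#'
#' @param object An `ffr_sweep` from [ffr_vs_severity()].
#' @param ... Unused.
#' @return A ggplot of FFR over severity with the 0.80 ischemia cutoff.
#' @export
autoplot.ffr_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$d, y = .data$ffr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2, colour = "grey40") +
    ggplot2::labs(
      x = "stenosis severity d (fractional diameter reduction)",
      y = "FFR", title = "FFR vs stenosis severity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot ROC curve with the chance diagonal.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}
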