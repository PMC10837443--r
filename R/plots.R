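# ggplot2 autoplot methods for the evaluation outputs.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for stacksurv results
#'
#' `autoplot()` methods return ggplot objects: ROC curve with the chance
#' diagonal, Kaplan-Meier step curve, calibration scatter against the
#' identity line, and the cut-point scan profile.
#'
#' @param object A stacksurv result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.td_roc <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Time-dependent ROC at t = %g (AUC = %.3f)",
                      object$eval_time, object$auc)
    ) +
    ggplot2::coord_equal()
}

#' @rdname autoplot.td_roc
#' @export
autoplot.km_curve <- function(object, ...) {
  fit <- object$fit
  df <- tibble::tibble(time = c(0, fit$time), survival = c(1, fit$surv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  title = "Kaplan-Meier estimate")
}

#' @rdname autoplot.td_roc
#' @export
autoplot.calibration_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$predicted,
                                       y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(
      x = "Predicted survival", y = "Observed (KM) survival",
      title = sprintf("Calibration at t = %g", attr(object, "eval_time"))
    )
}

#' @rdname autoplot.td_roc
#' @export
autoplot.cutpoint_result <- function(object, ...) {
  ggplot2::ggplot(object$candidates,
                  ggplot2::aes(x = .data$cutpoint, y = abs(.data$z))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutpoint, linetype = "dashed") +
    ggplot2::labs(x = "Candidate cut-point",
                  y = "|standardized log-rank statistic|",
                  title = sprintf("Maximally selected cut-point = %.4g",
                                  object$cutpoint))
}

#' @importFrom rlang .data
NULL
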