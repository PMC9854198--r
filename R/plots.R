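# ggplot2 displays for the main result types.

#' Plot a time-dependent ROC curve
#'
#' @param object a `time_roc`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot time_roc
#' @export
autoplot.time_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("Time-dependent ROC at %g months (AUC = %.2f)",
                      object$horizon, object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the Weibull reference risk curve
#'
#' Reference curve through the four optimal thresholds, optionally with a
#' personalized curve overlaid and the below-reference region shaded.
#'
#' @param object a `reference_risk_curve`.
#' @param curve optional tibble (`time`, `surv`) of one patient's
#'   personalized curve.
#' @param window months shown.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot reference_risk_curve
#' @export
autoplot.reference_risk_curve <- function(object, curve = NULL,
                                          window = c(0, 24), ...) {
  tt <- seq(window[1], window[2], by = 0.25)
  df <- tibble::tibble(time = tt, surv = ref_survival(object, tt))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(data = object$anchors,
                        ggplot2::aes(x = .data$horizon, y = .data$threshold),
                        shape = 4, size = 3, colour = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Months", y = "Progression-free probability",
                  title = sprintf("Reference risk curve (k = %.2f, λ = %.1f)",
                                  object$shape, object$scale)) +
    ggplot2::theme_minimal()
  if (!is.null(curve)) {
    cv <- dplyr::filter(curve, .data$time >= window[1],
                        .data$time <= window[2])
    p <- p + ggplot2::geom_line(data = cv, colour = "steelblue")
  }
  p
}

#' Plot personalized survival curves
#'
#' Spaghetti plot of predicted PFS curves, coloured by group (e.g. good vs
#' poor control).
#'
#' @param curves tibble from [predict_survival_curve()]; one curve per
#'   `.row`/`patient_id`.
#' @param group optional per-patient grouping vector (recycled by curve).
#' @return a ggplot.
#' @export
plot_survival_curves <- function(curves, group = NULL) {
  key <- if ("patient_id" %in% names(curves)) "patient_id" else ".row"
  df <- curves
  if (!is.null(group)) {
    ids <- unique(df[[key]])
    df$group <- factor(group[match(df[[key]], ids)])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                        group = .data[[key]]))
  p <- if (is.null(group)) {
    p + ggplot2::geom_line(alpha = 0.4)
  } else {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$group), alpha = 0.5)
  }
  p + ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Months", y = "Progression-free probability") +
    ggplot2::theme_minimal()
}

#' Plot a DeepSurv training log
#'
#' @param object a `deepsurv_model`.
#' @param ... unused.
#' @return a ggplot of training and validation loss by epoch.
#' @method autoplot deepsurv_model
#' @export
autoplot.deepsurv_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(x = "Epoch", y = "Negative log partial likelihood") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
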