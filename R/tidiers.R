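# broom-style tidiers for the package's fitted objects.

#' @describeIn deepsurv_train tidy method: per-epoch training log.
#' @param x a `deepsurv_model`.
#' @param ... unused.
#' @method tidy deepsurv_model
#' @export
tidy.deepsurv_model <- function(x, ...) x$log

#' @describeIn deepsurv_train glance method: one-row model summary.
#' @method glance deepsurv_model
#' @export
glance.deepsurv_model <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train, n_events = x$n_events,
    n_features = length(x$scaler$center),
    n_hidden_layers = x$hp$n_hidden_layers,
    nodes_per_layer = x$hp$nodes_per_layer,
    n_params = length(.ds_flatten(x$params)),
    best_epoch = x$best_epoch,
    best_val_loss = min(x$log$val_loss, na.rm = TRUE))
}

#' @describeIn time_dependent_roc tidy method: ROC staircase points.
#' @param x a `time_roc`.
#' @param ... unused.
#' @method tidy time_roc
#' @export
tidy.time_roc <- function(x, ...) x$points

#' @describeIn time_dependent_roc glance method: one-row ROC summary.
#' @method glance time_roc
#' @export
glance.time_roc <- function(x, ...) {
  tibble::tibble(horizon = x$horizon, auc = x$auc, threshold = x$threshold,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n_cases = x$n_cases, n_controls = x$n_controls)
}

#' @describeIn fit_weibull_reference tidy method: anchors with fit residuals.
#' @param x a `reference_risk_curve`.
#' @param ... unused.
#' @method tidy reference_risk_curve
#' @export
tidy.reference_risk_curve <- function(x, ...) x$anchors

#' @describeIn fit_weibull_reference glance method: fitted parameters.
#' @method glance reference_risk_curve
#' @export
glance.reference_risk_curve <- function(x, ...) {
  tibble::tibble(shape = x$shape, scale = x$scale,
                 median_months = x$scale * log(2)^(1 / x$shape))
}

#' @describeIn sequential_forward_select tidy method: selection trace.
#' @param x a `selected_panel`.
#' @param ... unused.
#' @method tidy selected_panel
#' @export
tidy.selected_panel <- function(x, ...) x$trace

#' @describeIn bootstrap_compare tidy method: paired tests per metric/horizon.
#' @param x a `bootstrap_comparison`.
#' @param ... unused.
#' @method tidy bootstrap_comparison
#' @export
tidy.bootstrap_comparison <- function(x, ...) x$tests
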