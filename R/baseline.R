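# Breslow baseline hazard and personalized survival curves.

#' Breslow baseline survival estimator
#'
#' Cumulative baseline hazard
#' `H0(t) = sum_{event times t_k <= t} d_k / sum_{j in R(t_k)} exp(h_j)` and
#' `S0 = exp(-H0)`, a right-continuous step function with `S0(0) = 1`. With
#' all `h = 0` this reduces to the Nelson-Aalen-based survival estimate.
#'
#' @param h per-patient log relative hazards on the training set.
#' @param time,event training outcome.
#' @return tibble: `time` (distinct event times, ascending), `h0`
#'   (cumulative baseline hazard), `s0` (baseline survival).
#' @export
breslow_baseline <- function(h, time, event) {
  if (sum(event) < 1) stop("no events: baseline undefined", call. = FALSE)
  eh <- exp(h - max(h))
  scale_back <- exp(max(h))
  ut <- sort(unique(time[event == 1]))
  inc <- vapply(ut, function(tk) {
    dk <- sum(event == 1 & time == tk)
    dk / (sum(eh[time >= tk]) * scale_back)
  }, numeric(1))
  h0 <- cumsum(inc)
  tibble::tibble(time = ut, h0 = h0, s0 = exp(-h0))
}

# step interpolation of s0 at arbitrary times (right-continuous, s0(0)=1)
.s0_at <- function(baseline, times) {
  idx <- findInterval(times, baseline$time)
  c(1, baseline$s0)[idx + 1]
}

#' Personalized survival curves
#'
#' `S(t | x) = S0(t)^exp(h(x))` evaluated on a time grid by step
#' interpolation of the Breslow baseline.
#'
#' @param model a `deepsurv_model` (with its stored baseline), or any object
#'   with a `baseline` tibble as produced by [breslow_baseline()].
#' @param newdata features to predict for (ignored when `h` is given).
#' @param h optional precomputed log relative hazards.
#' @param times evaluation grid in months.
#' @return tibble: `.row` (patient row), `time`, `surv`.
#' @export
predict_survival_curve <- function(model, newdata = NULL, h = NULL,
                                   times = seq(0, 30, by = 1)) {
  if (is.null(model$baseline)) {
    stop("model has no baseline survival; train first", call. = FALSE)
  }
  if (is.null(h)) {
    if (is.null(newdata)) stop("need `newdata` or `h`", call. = FALSE)
    h <- predict(model, newdata, type = "lp")
  }
  s0 <- .s0_at(model$baseline, times)
  tidyr::expand_grid(.row = seq_along(h), time = times) |>
    dplyr::mutate(surv = s0[match(.data$time, times)]^exp(h[.data$.row]))
}
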