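# Weibull reference risk curve and risk-of-progression period classification.

#' Fit the Weibull reference risk curve
#'
#' Fits `S_ref(t) = exp(-(t/lambda)^k)` through the horizon-specific optimal
#' survival-probability thresholds by least squares on the complementary
#' log-log linearisation `log(-log S*) = k log t - k log lambda`, which is
#' exact whenever the anchors are Weibull-consistent.
#'
#' @param anchors tibble/data frame with columns `horizon` (months, strictly
#'   increasing, > 0) and `threshold` (optimal S* in (0, 1)), typically the
#'   Youden thresholds of [time_dependent_roc()] at 3, 12, 18 and 24 months.
#' @return object of class `reference_risk_curve`: `shape` k, `scale` lambda,
#'   `anchors` (with fitted values and residuals on the cloglog scale).
#' @export
fit_weibull_reference <- function(anchors) {
  stopifnot(all(c("horizon", "threshold") %in% names(anchors)))
  t0 <- anchors$horizon; s0 <- anchors$threshold
  if (any(diff(t0) <= 0) || any(t0 <= 0)) {
    stop("horizons must be positive and strictly increasing", call. = FALSE)
  }
  if (any(s0 <= 0 | s0 >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  y <- log(-log(s0))
  x <- log(t0)
  fit <- lm(y ~ x)
  k <- unname(coef(fit)[2])
  if (!is.finite(k) || k <= 0) {
    stop(sprintf(
      paste0("anchors imply a non-decreasing survival curve ",
             "(fitted shape %.4g <= 0); thresholds: %s"),
      k, paste(signif(s0, 4), collapse = ", ")), call. = FALSE)
  }
  lambda <- exp(-unname(coef(fit)[1]) / k)
  out <- structure(list(shape = k, scale = lambda,
                        anchors = tibble::tibble(
                          horizon = t0, threshold = s0,
                          fitted = exp(-(t0 / lambda)^k),
                          residual = y - unname(stats::fitted(fit)))),
                   class = "reference_risk_curve")
  out
}

#' Evaluate a reference risk curve
#' @param ref a `reference_risk_curve`.
#' @param times months.
#' @return `S_ref(times)`.
#' @export
ref_survival <- function(ref, times) {
  stopifnot(inherits(ref, "reference_risk_curve"))
  exp(-(times / ref$scale)^ref$shape)
}

#' @export
print.reference_risk_curve <- function(x, ...) {
  cat(sprintf("<reference_risk_curve> shape k = %.3f, scale lambda = %.2f months\n",
              x$shape, x$scale))
  invisible(x)
}

#' Signed area between a personalized curve and the reference
#'
#' Trapezoidal signed area of `S_patient - S_ref` over the observation
#' window on a 0.5-month grid. Sub-intervals where the personalized curve
#' falls below the reference are located by linear interpolation between
#' grid points; a negative area flags a high risk of progression in that
#' interval.
#'
#' @param surv tibble with `time`, `surv` (one patient's curve) or a numeric
#'   vector on `grid`.
#' @param ref a `reference_risk_curve`.
#' @param window observation window in months.
#' @param step grid step (months).
#' @return list: `area`, `negative_intervals` (tibble start/end),
#'   `earliest_crossing` (NA when never below).
#' @export
risk_area <- function(surv, ref, window = c(0, 24), step = 0.5) {
  grid <- seq(window[1], window[2], by = step)
  if (is.data.frame(surv)) {
    if (max(surv$time) < window[2] || min(surv$time) > window[1]) {
      stop("window extends beyond the patient curve support", call. = FALSE)
    }
    sp <- approx(surv$time, surv$surv, xout = grid, rule = 2)$y
  } else {
    if (length(surv) != length(grid)) {
      stop("numeric `surv` must match the evaluation grid", call. = FALSE)
    }
    sp <- surv
  }
  sr <- ref_survival(ref, grid)
  d <- sp - sr
  area <- sum(diff(grid) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)

  # negative sub-intervals by sign change on the linear interpolant
  below <- d < 0
  cross_at <- function(i) {
    # root of the linear interpolant between grid[i] and grid[i+1]
    grid[i] + (0 - d[i]) * (grid[i + 1] - grid[i]) / (d[i + 1] - d[i])
  }
  ints <- list()
  i <- 1
  while (i <= length(grid)) {
    if (below[i]) {
      start <- if (i == 1) grid[1] else cross_at(i - 1)
      j <- i
      while (j < length(grid) && below[j + 1]) j <- j + 1
      end <- if (j == length(grid)) grid[length(grid)] else cross_at(j)
      ints[[length(ints) + 1]] <- tibble::tibble(start = start, end = end)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  negs <- if (length(ints)) dplyr::bind_rows(ints) else
    tibble::tibble(start = numeric(0), end = numeric(0))
  list(area = area, negative_intervals = negs,
       earliest_crossing = if (nrow(negs)) negs$start[1] else NA_real_)
}

#' Classify the risk-of-progression period
#'
#' The category is the interval of the checkpoint partition containing the
#' earliest time at which the personalized curve falls below the reference:
#' never below on the window gives ">24 months", below from t = 0 gives
#' "<3 months".
#'
#' @param earliest_crossing earliest below-reference time (NA = never).
#' @param checkpoints partition boundaries (months).
#' @return factor level among `<3 months`, `3-12 months`, `12-18 months`,
#'   `18-24 months`, `>24 months`.
#' @export
classify_risk_period <- function(earliest_crossing,
                                 checkpoints = c(3, 12, 18, 24)) {
  labels <- c(paste0("<", checkpoints[1], " months"),
              paste0(utils::head(checkpoints, -1), "-",
                     utils::tail(checkpoints, -1), " months"),
              paste0(">", checkpoints[length(checkpoints)], " months"))
  pick <- function(tc) {
    if (is.na(tc)) return(labels[length(labels)])
    labels[findInterval(tc, checkpoints) + 1]
  }
  factor(vapply(earliest_crossing, pick, character(1)), levels = labels)
}

#' Per-patient risk-of-progression report
#'
#' Applies [risk_area()] and [classify_risk_period()] to each patient's
#' personalized curve.
#'
#' @param curves tibble from [predict_survival_curve()] (`.row`, `time`,
#'   `surv`), optionally with `patient_id`.
#' @param ref a `reference_risk_curve`.
#' @param window,step see [risk_area()].
#' @param checkpoints see [classify_risk_period()].
#' @return tibble: `patient_id` (or `.row`), `area`, `earliest_crossing`,
#'   `risk_period`.
#' @export
risk_period_report <- function(curves, ref, window = c(0, 24), step = 0.5,
                               checkpoints = c(3, 12, 18, 24)) {
  key <- if ("patient_id" %in% names(curves)) "patient_id" else ".row"
  curves |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::group_modify(function(df, g) {
      ra <- risk_area(df[, c("time", "surv")], ref, window, step)
      tibble::tibble(area = ra$area,
                     earliest_crossing = ra$earliest_crossing)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(risk_period = classify_risk_period(.data$earliest_crossing,
                                                     checkpoints))
}
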