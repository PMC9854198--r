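# Model evaluation: Harrell C-index, time-dependent ROC at fixed horizons,
# log-rank comparison, and paired bootstrap model comparison.

#' Harrell concordance index
#'
#' Fraction of comparable patient pairs ordered correctly by the risk score.
#' A pair is comparable when the earlier time is an observed event; tied risk
#' scores count 1/2; pairs tied on an event time are not comparable.
#'
#' @param risk higher = higher predicted risk (earlier progression).
#' @param time,event outcome.
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    cmp <- which(time > time[i] | (time == time[i] & event == 0))
    if (!length(cmp)) next
    den <- den + length(cmp)
    num <- num + sum(risk[i] > risk[cmp]) + 0.5 * sum(risk[i] == risk[cmp])
  }
  if (den == 0) stop("no comparable pairs", call. = FALSE)
  num / den
}

#' Time-dependent ROC at a fixed horizon
#'
#' Cumulative/dynamic definition: cases progressed by the horizon
#' (`time <= t`, event observed), controls progression-free past it
#' (`time > t`); patients censored before the horizon are excluded. The
#' marker is the predicted survival probability at the horizon, low values
#' classifying "progressed". AUC by trapezoid over the ROC staircase; the
#' optimal threshold S* maximises Youden's `sensitivity + specificity - 1`.
#'
#' @param marker predicted `S(horizon)` per patient (low = high risk).
#' @param time,event outcome.
#' @param horizon months.
#' @return object of class `time_roc`: list with `horizon`, `auc`,
#'   `threshold` (S*), `sensitivity`, `specificity`, `points` tibble
#'   (fpr, tpr, threshold), `n_cases`, `n_controls`.
#' @export
time_dependent_roc <- function(marker, time, event, horizon) {
  case <- time <= horizon & event == 1
  ctrl <- time > horizon
  use <- case | ctrl
  if (sum(case) == 0 || sum(ctrl) == 0) {
    stop(sprintf("no cases or no controls at %g months", horizon),
         call. = FALSE)
  }
  m <- marker[use]; y <- case[use]
  # classify positive when marker <= c
  cuts <- sort(unique(m))
  tpr <- vapply(cuts, function(cc) mean(m[y] <= cc), numeric(1))
  fpr <- vapply(cuts, function(cc) mean(m[!y] <= cc), numeric(1))
  pts <- tibble::tibble(threshold = c(-Inf, cuts), fpr = c(0, fpr),
                        tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  youden <- pts$tpr - pts$fpr
  best <- which.max(youden[-1]) + 1   # skip the -Inf row
  structure(list(horizon = horizon, auc = auc,
                 threshold = pts$threshold[best],
                 sensitivity = pts$tpr[best],
                 specificity = 1 - pts$fpr[best],
                 points = pts,
                 n_cases = sum(case), n_controls = sum(ctrl)),
            class = "time_roc")
}

#' @export
print.time_roc <- function(x, ...) {
  cat(sprintf(
    "<time_roc> %g months: AUC %.3f, S* = %.3f (sens %.2f, spec %.2f; %d cases / %d controls)\n",
    x$horizon, x$auc, x$threshold, x$sensitivity, x$specificity,
    x$n_cases, x$n_controls))
  invisible(x)
}

#' Two-sample log-rank test
#'
#' Standard log-rank test of observed outcomes between two groups (e.g. good
#' vs poor tumour control, or a predicted-risk median split). If neither
#' group has any event the test is undefined and p = 1 is returned with a
#' warning.
#'
#' @param time,event outcome.
#' @param group two-level grouping vector.
#' @return tibble: `statistic` (chi-squared, 1 df), `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("need exactly two non-empty groups", call. = FALSE)
  }
  if (sum(event) == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(tibble::tibble(statistic = 0, p_value = 1))
  }
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group)
  tibble::tibble(statistic = unname(sd0$chisq),
                 p_value = unname(pchisq(sd0$chisq, df = 1,
                                         lower.tail = FALSE)))
}

#' Paired bootstrap comparison of two models
#'
#' Resamples the test set with replacement `B` times (the same replicate
#' indices for both models), computes AUC, sensitivity and specificity of the
#' horizon-specific ROC for each model on each replicate, and compares models
#' per metric and horizon by a paired t-test. Replicates lacking cases or
#' controls at some horizon are redrawn (counted in `n_redrawn`).
#'
#' @param markersA,markersB matrices (`n x length(horizons)`) of predicted
#'   `S(horizon)` per patient for each model.
#' @param time,event test-set outcome.
#' @param horizons evaluation horizons (months).
#' @param B number of bootstrap replicates (>= 2).
#' @param seed resampling seed.
#' @return object of class `bootstrap_comparison`: `summary` tibble (model,
#'   horizon, metric, mean, sd), `tests` tibble (horizon, metric, t, p_value,
#'   mean_diff), `B`, `n_redrawn`.
#' @export
bootstrap_compare <- function(markersA, markersB, time, event,
                              horizons = c(3, 12, 18, 24), B = 1000,
                              seed = 1) {
  if (B < 2) stop("need B >= 2 bootstrap replicates", call. = FALSE)
  markersA <- as.matrix(markersA); markersB <- as.matrix(markersB)
  n <- length(time)
  stopifnot(nrow(markersA) == n, nrow(markersB) == n,
            ncol(markersA) == length(horizons),
            ncol(markersB) == length(horizons))
  ok_idx <- function(idx) {
    all(vapply(horizons, function(h0) {
      sum(time[idx] <= h0 & event[idx] == 1) > 0 && sum(time[idx] > h0) > 0
    }, logical(1)))
  }
  if (!ok_idx(seq_len(n))) {
    stop("some horizon has no cases or no controls in the full test set",
         call. = FALSE)
  }
  metrics <- c("auc", "sensitivity", "specificity")
  resA <- array(NA_real_, c(B, length(horizons), 3))
  resB <- array(NA_real_, c(B, length(horizons), 3))
  n_redrawn <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      tries <- 0L
      while (!ok_idx(idx)) {
        idx <- sample.int(n, n, replace = TRUE)
        n_redrawn <- n_redrawn + 1L
        tries <- tries + 1L
        if (tries > 1000) {
          stop("could not draw a valid bootstrap replicate", call. = FALSE)
        }
      }
      for (j in seq_along(horizons)) {
        ra <- time_dependent_roc(markersA[idx, j], time[idx], event[idx],
                                 horizons[j])
        rb <- time_dependent_roc(markersB[idx, j], time[idx], event[idx],
                                 horizons[j])
        resA[b, j, ] <- c(ra$auc, ra$sensitivity, ra$specificity)
        resB[b, j, ] <- c(rb$auc, rb$sensitivity, rb$specificity)
      }
    }
  })
  summ <- list(); tests <- list()
  for (j in seq_along(horizons)) {
    for (k in 1:3) {
      a <- resA[, j, k]; b2 <- resB[, j, k]
      summ[[length(summ) + 1]] <- tibble::tibble(
        model = c("A", "B"), horizon = horizons[j], metric = metrics[k],
        mean = c(mean(a), mean(b2)), sd = c(sd(a), sd(b2)))
      tt <- if (isTRUE(all.equal(a, b2))) {
        list(statistic = 0, p.value = 1)
      } else {
        t.test(a, b2, paired = TRUE)
      }
      tests[[length(tests) + 1]] <- tibble::tibble(
        horizon = horizons[j], metric = metrics[k],
        t = unname(tt$statistic), p_value = unname(tt$p.value),
        mean_diff = mean(a) - mean(b2))
    }
  }
  structure(list(summary = dplyr::bind_rows(summ),
                 tests = dplyr::bind_rows(tests),
                 replicates = list(A = resA, B = resB),
                 horizons = horizons, B = B, n_redrawn = n_redrawn),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf("<bootstrap_comparison> B = %d (%d redrawn)\n", x$B,
              x$n_redrawn))
  print(x$tests)
  invisible(x)
}
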