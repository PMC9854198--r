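# Two-step feature selection: univariate screens at p < 0.1 followed by
# sequential forward selection with a cross-validated Cox concordance scorer.

#' Univariate Cox screen of one feature
#'
#' Fits a single-covariate proportional-hazards model (Breslow ties) on the
#' standardized feature and keeps it when the Wald p-value is below `alpha`.
#'
#' @param x numeric feature vector.
#' @param time,event survival outcome (PFS months, progression indicator).
#' @param alpha retention threshold (default 0.1).
#' @param name feature name carried into the result.
#' @return one-row tibble: `feature`, `statistic` (Wald z), `p_value`,
#'   `kept`, `degenerate`.
#' @export
cox_screen <- function(x, time, event, alpha = 0.1, name = "x") {
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) {
    return(tibble::tibble(feature = name, statistic = 0, p_value = 1,
                          kept = FALSE, degenerate = TRUE))
  }
  z <- (x - mean(x)) / s
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ z, ties = "breslow"),
    warning = function(w) suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ z, ties = "breslow")),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(coef(fit)[1])) {
    return(tibble::tibble(feature = name, statistic = 0, p_value = 1,
                          kept = FALSE, degenerate = TRUE))
  }
  sm <- summary(fit)
  zval <- sm$coefficients[1, "z"]
  p <- sm$coefficients[1, "Pr(>|z|)"]
  tibble::tibble(feature = name, statistic = unname(zval),
                 p_value = unname(p), kept = is.finite(p) && p < alpha,
                 degenerate = FALSE)
}

#' Screen a table of radiomic features
#'
#' Applies [cox_screen()] to every numeric column.
#'
#' @param features tibble of features (a `patient_id` column is ignored).
#' @param outcomes tibble with `pfs_months` and `event`, aligned by row.
#' @param alpha retention threshold.
#' @return tibble with one row per feature.
#' @export
screen_radiomic <- function(features, outcomes, alpha = 0.1) {
  cols <- setdiff(names(features), "patient_id")
  purrr::map_dfr(cols, function(nm) {
    cox_screen(features[[nm]], outcomes$pfs_months, outcomes$event,
               alpha = alpha, name = nm)
  })
}

#' Chi-squared screen of one categorical clinical feature
#'
#' Dichotomises patients at the (training) median PFS into good control
#' (PFS above the median) and poor control (progression before the median);
#' patients censored before the median are excluded. Keeps the feature when
#' the Pearson chi-squared test (no continuity correction) of the
#' category-by-group table has p below `alpha`.
#'
#' @param x factor (or character) clinical feature.
#' @param time,event survival outcome.
#' @param alpha retention threshold.
#' @param median_pfs dichotomisation point; defaults to `median(time)`.
#' @param name feature name.
#' @return one-row tibble as in [cox_screen()].
#' @export
chisq_screen <- function(x, time, event, alpha = 0.1,
                         median_pfs = median(time), name = "x") {
  x <- factor(x)
  grp <- ifelse(time > median_pfs, "good",
                ifelse(event == 1, "poor", NA_character_))
  ok <- !is.na(grp)
  tab <- table(droplevels(x[ok]), grp[ok])
  if (nrow(tab) < 2 || ncol(tab) < 2 ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(feature = name, statistic = 0, p_value = 1,
                          kept = FALSE, degenerate = TRUE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(feature = name, statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value),
                 kept = is.finite(ct$p.value) && ct$p.value < alpha,
                 degenerate = FALSE)
}

#' Screen the clinical covariate table
#'
#' Applies [chisq_screen()] to every non-id column.
#'
#' @inheritParams screen_radiomic
#' @param median_pfs dichotomisation point (training median PFS).
#' @return tibble with one row per clinical feature.
#' @export
screen_clinical <- function(features, outcomes, alpha = 0.1,
                            median_pfs = median(outcomes$pfs_months)) {
  cols <- setdiff(names(features), "patient_id")
  purrr::map_dfr(cols, function(nm) {
    chisq_screen(features[[nm]], outcomes$pfs_months, outcomes$event,
                 alpha = alpha, median_pfs = median_pfs, name = nm)
  })
}

# default SFS scorer: k-fold cross-validated Harrell C of a Cox fit
.cv_cox_scorer <- function(folds) {
  function(X, time, event, feats) {
    scores <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f
      te <- !tr
      if (sum(event[te]) == 0 || sum(event[tr]) < 2) return(NA_real_)
      df <- as.data.frame(X[, feats, drop = FALSE])
      fit <- tryCatch(suppressWarnings(survival::coxph(
        survival::Surv(time[tr], event[tr]) ~ .,
        data = df[tr, , drop = FALSE], ties = "breslow")),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      lp <- predict(fit, newdata = df[te, , drop = FALSE], type = "lp")
      tryCatch(concordance_index(lp, time[te], event[te]),
               error = function(e) NA_real_)
    }, numeric(1))
    mean(scores, na.rm = TRUE)
  }
}

#' Sequential forward selection
#'
#' Greedy wrapper selection: at each step adds the candidate feature that
#' maximises the scorer (default: 5-fold cross-validated Harrell C-index of a
#' multivariable Cox fit); stops when the improvement falls below `tol` or
#' `cap` features are selected. Fold assignment is seeded, so the search is
#' deterministic.
#'
#' @param features tibble/data frame of candidate features (screened pool).
#' @param outcomes tibble with `pfs_months`, `event` aligned by row.
#' @param cap maximum panel size.
#' @param folds number of CV folds for the default scorer.
#' @param seed fold-assignment seed.
#' @param tol minimum score improvement to continue.
#' @param scorer optional `function(X, time, event, feats)` returning a
#'   scalar score; failures on a candidate skip it with a warning.
#' @param pool label recorded on the result ("clinical" or "radiomic").
#' @return object of class `selected_panel`: list with `features` (ordered
#'   names), `trace` tibble (step, feature, score), `pool`.
#' @export
sequential_forward_select <- function(features, outcomes, cap = 5,
                                      folds = 5, seed = 1, tol = 1e-4,
                                      scorer = NULL, pool = "radiomic") {
  cols <- setdiff(names(features), "patient_id")
  if (length(cols) == 0) stop("candidate pool is empty", call. = FALSE)
  stopifnot(cap >= 1)
  X <- as.matrix(features[, cols, drop = FALSE])
  n <- nrow(X)
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  if (is.null(scorer)) scorer <- .cv_cox_scorer(fold_id)
  selected <- character(0)
  best_score <- -Inf
  trace <- list()
  repeat {
    cand <- setdiff(cols, selected)
    if (length(cand) == 0 || length(selected) >= cap) break
    step_scores <- vapply(cand, function(nm) {
      out <- tryCatch(scorer(X, outcomes$pfs_months, outcomes$event,
                             c(selected, nm)),
                      error = function(e) {
                        warning(sprintf("scorer failed for '%s': %s",
                                        nm, conditionMessage(e)),
                                call. = FALSE)
                        NA_real_
                      })
      if (is.null(out) || !is.finite(out)) NA_real_ else out
    }, numeric(1))
    if (all(is.na(step_scores))) break
    pick <- names(which.max(step_scores))
    gain <- step_scores[pick] - ifelse(is.finite(best_score), best_score, 0)
    if (length(selected) > 0 && gain < tol) break
    selected <- c(selected, pick)
    best_score <- step_scores[pick]
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(selected), feature = pick,
      score = unname(step_scores[pick]))
  }
  structure(list(features = selected,
                 trace = dplyr::bind_rows(trace),
                 pool = pool),
            class = "selected_panel")
}

#' @export
print.selected_panel <- function(x, ...) {
  cat(sprintf("<selected_panel> pool=%s, %d feature(s)\n", x$pool,
              length(x$features)))
  if (nrow(x$trace)) print(x$trace)
  invisible(x)
}
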