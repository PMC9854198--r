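# End-to-end orchestration: cohort -> features -> selection -> three models
# (clinical, radiomic, combined) -> evaluation -> risk periods.

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()] (or an existing `radsurv_cohort`).
#' @param grid_shape phantom grid (voxels per axis).
#' @param train_fraction fraction of patients in the training split.
#' @param horizons time-dependent evaluation horizons (months, increasing).
#' @param clinical_cap,radiomic_cap SFS panel caps per pool.
#' @param alpha univariate screen threshold.
#' @param cv_folds folds of the SFS scorer.
#' @param hyperparams a [deepsurv_hyperparams()] shared by the three models.
#' @param bootstrap_B bootstrap replicates for model comparison.
#' @param seeds named list of seeds: `split`, `folds`, `train`, `bootstrap`.
#' @param n_bins texture gray levels.
#' @param output_dir optional artifact directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            grid_shape = c(48, 48, 48),
                            train_fraction = 0.7,
                            horizons = c(3, 12, 18, 24),
                            clinical_cap = 5, radiomic_cap = 5,
                            alpha = 0.1, cv_folds = 5,
                            hyperparams = deepsurv_hyperparams(),
                            bootstrap_B = 1000,
                            seeds = list(split = 11L, folds = 12L,
                                         train = 13L, bootstrap = 14L),
                            n_bins = 32, output_dir = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            all(diff(horizons) > 0))
  structure(list(cohort = cohort, grid_shape = grid_shape,
                 train_fraction = train_fraction, horizons = horizons,
                 clinical_cap = clinical_cap, radiomic_cap = radiomic_cap,
                 alpha = alpha, cv_folds = cv_folds,
                 hyperparams = hyperparams, bootstrap_B = bootstrap_B,
                 seeds = seeds, n_bins = n_bins, output_dir = output_dir),
            class = "pipeline_config")
}

#' Split a cohort into training and test sets
#'
#' Seeded stratified split: strata are censored patients, events with PFS at
#' or below the event median, and events above it; within each stratum a
#' proportional number of patients (largest-remainder rounding to
#' `floor(train_fraction * n)` in total) goes to training. If any stratum has
#' fewer than 2 patients the split falls back to event-only stratification
#' with a warning.
#'
#' @param outcomes tibble with `pfs_months`, `event`.
#' @param train_fraction fraction in training (0 < f < 1).
#' @param seed RNG seed.
#' @return list with integer row indices `train` and `test`.
#' @export
split_cohort <- function(outcomes, train_fraction = 0.7, seed = 1) {
  n <- nrow(outcomes)
  if (n < 10) stop("need at least 10 patients to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly inside (0, 1)", call. = FALSE)
  }
  ev <- outcomes$event == 1
  medev <- median(outcomes$pfs_months[ev])
  strata <- ifelse(!ev, "censored",
                   ifelse(outcomes$pfs_months <= medev, "event_lo", "event_hi"))
  if (min(table(strata)) < 2) {
    warning("a stratum has fewer than 2 patients; falling back to ",
            "event-only stratification")
    strata <- ifelse(ev, "event", "censored")
  }
  target <- floor(train_fraction * n)
  tab <- table(strata)
  exact <- as.numeric(tab) * train_fraction
  base <- floor(exact)
  rem <- target - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  alloc <- setNames(as.integer(base), names(tab))
  train <- withr::with_seed(seed, {
    unlist(lapply(names(tab), function(s) {
      rows <- which(strata == s)
      sample(rows, min(alloc[[s]], length(rows)))
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Run the full pipeline
#'
#' Generates (or accepts) the synthetic cohort, extracts the 593-feature
#' table, splits into training and test sets, screens and selects features on
#' the training split only (chi-squared screen + SFS for clinical, Cox screen
#' + SFS for radiomic), trains the three DeepSurv variants (clinical,
#' radiomic, combined) with shared seeds, evaluates them on the test split
#' (C-index, time-dependent ROC, paired bootstrap comparisons, log-rank on
#' the predicted-risk median split), fits the Weibull reference risk curve
#' through the four training-set optimal thresholds of the combined model,
#' and classifies each test patient's risk-of-progression period.
#'
#' @param config a [pipeline_config()].
#' @param features optional precomputed feature table (skips extraction).
#' @param progress print stage progress.
#' @return object of class `radsurv_run`; see Details for components.
#' @details Components: `cohort`, `features`, `split`, `screens`, `panels`,
#'   `models`, `metrics` (per-variant C-index + per-horizon AUC),
#'   `bootstrap` (combined vs radiomic / clinical), `logrank`,
#'   `reference_curve`, `risk_report`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), features = NULL,
                         progress = FALSE) {
  say <- function(...) if (progress) cat(sprintf(...), "\n")
  cohort <- config$cohort
  if (inherits(cohort, "cohort_config")) {
    say("generating cohort (n = %d)", cohort$n_patients)
    cohort <- generate_cohort(cohort, grid_shape = config$grid_shape)
  }
  stopifnot(inherits(cohort, "radsurv_cohort"))
  outcomes <- cohort$outcomes

  if (is.null(features)) {
    say("extracting features for %d patients", nrow(outcomes))
    features <- extract_cohort_features(cohort, n_bins = config$n_bins,
                                        progress = progress)
  }
  feat_cols <- setdiff(names(features), "patient_id")

  sp <- split_cohort(outcomes, config$train_fraction, config$seeds$split)
  tr <- sp$train; te <- sp$test
  out_tr <- outcomes[tr, ]; out_te <- outcomes[te, ]

  # --- selection on the training split only -------------------------------
  say("screening %d radiomic features", length(feat_cols))
  rad_tr <- features[tr, feat_cols, drop = FALSE]
  scr_rad <- screen_radiomic(rad_tr, out_tr, alpha = config$alpha)
  pool_rad <- scr_rad$feature[scr_rad$kept]

  clin_enc <- encode_clinical(cohort$clinical)
  clin_cols <- setdiff(names(clin_enc), "patient_id")
  med_tr <- median(out_tr$pfs_months)
  scr_clin <- screen_clinical(cohort$clinical[tr, ], out_tr,
                              alpha = config$alpha, median_pfs = med_tr)
  pool_clin <- scr_clin$feature[scr_clin$kept]
  # map screened clinical variables to their encoded columns
  enc_map <- list(n_stage = "n_stage", m_stage = "m_stage",
                  histology = "histology",
                  total_protein = c("tp_high", "tp_low", "tp_missing"),
                  mcv = c("mcv_high", "mcv_low", "mcv_missing"),
                  smoking = "smoking")
  pool_clin_enc <- unlist(enc_map[pool_clin], use.names = FALSE)

  say("sequential forward selection")
  panel_rad <- if (length(pool_rad)) {
    sequential_forward_select(rad_tr[, pool_rad, drop = FALSE], out_tr,
                              cap = config$radiomic_cap,
                              folds = config$cv_folds,
                              seed = config$seeds$folds, pool = "radiomic")
  } else {
    structure(list(features = character(0), trace = tibble::tibble(),
                   pool = "radiomic"), class = "selected_panel")
  }
  panel_clin <- if (length(pool_clin_enc)) {
    sequential_forward_select(clin_enc[tr, pool_clin_enc, drop = FALSE],
                              out_tr, cap = config$clinical_cap,
                              folds = config$cv_folds,
                              seed = config$seeds$folds, pool = "clinical")
  } else {
    structure(list(features = character(0), trace = tibble::tibble(),
                   pool = "clinical"), class = "selected_panel")
  }

  variants <- list(
    clinical = panel_clin$features,
    radiomic = panel_rad$features,
    combined = c(panel_clin$features, panel_rad$features))
  all_X <- dplyr::bind_cols(clin_enc[clin_cols],
                            features[feat_cols])

  # --- train the three variants -------------------------------------------
  models <- list()
  for (v in names(variants)) {
    pan <- variants[[v]]
    if (!length(pan)) {
      warning(sprintf("variant '%s' has an empty panel; skipped", v))
      next
    }
    say("training %s model (%d features)", v, length(pan))
    hp <- config$hyperparams
    hp$seed <- as.integer(config$seeds$train)
    models[[v]] <- deepsurv_train(all_X[tr, pan, drop = FALSE],
                                  out_tr$pfs_months, out_tr$event, hp)
  }

  # --- evaluation on the test split ---------------------------------------
  say("evaluating on %d test patients", length(te))
  horizons <- config$horizons
  metrics <- list(); roc_tbls <- list(); surv_te <- list(); logrank <- list()
  for (v in names(models)) {
    pan <- variants[[v]]
    hte <- predict(models[[v]], all_X[te, pan, drop = FALSE])
    cidx <- concordance_index(hte, out_te$pfs_months, out_te$event)
    smat <- vapply(horizons, function(h0) {
      s0 <- .s0_at(models[[v]]$baseline, h0)
      s0^exp(hte)
    }, numeric(length(te)))
    surv_te[[v]] <- smat
    rocs <- lapply(seq_along(horizons), function(j) {
      tryCatch(time_dependent_roc(smat[, j], out_te$pfs_months, out_te$event,
                                  horizons[j]),
               error = function(e) {
                 warning(sprintf("%s model, %g months: %s", v, horizons[j],
                                 conditionMessage(e)), call. = FALSE)
                 NULL
               })
    })
    gv <- function(f) vapply(rocs, function(r) {
      if (is.null(r)) NA_real_ else r[[f]]
    }, numeric(1))
    metrics[[v]] <- tibble::tibble(
      model = v, c_index = cidx, horizon = horizons,
      auc = gv("auc"), sensitivity = gv("sensitivity"),
      specificity = gv("specificity"), threshold = gv("threshold"))
    roc_tbls[[v]] <- rocs
    grp <- ifelse(hte > median(hte), "high_risk", "low_risk")
    logrank[[v]] <- dplyr::mutate(
      tryCatch(logrank_test(out_te$pfs_months, out_te$event, grp),
               error = function(e) {
                 warning(sprintf("log-rank (%s): %s", v,
                                 conditionMessage(e)), call. = FALSE)
                 tibble::tibble(statistic = NA_real_, p_value = NA_real_)
               }),
      model = v)
  }
  metrics <- dplyr::bind_rows(metrics)

  boot <- list()
  try_boot <- function(a, b) {
    tryCatch(bootstrap_compare(surv_te[[a]], surv_te[[b]],
                               out_te$pfs_months, out_te$event, horizons,
                               B = config$bootstrap_B,
                               seed = config$seeds$bootstrap),
             error = function(e) {
               warning(sprintf("bootstrap %s vs %s: %s", a, b,
                               conditionMessage(e)), call. = FALSE)
               NULL
             })
  }
  if (all(c("combined", "radiomic") %in% names(models))) {
    boot$combined_vs_radiomic <- try_boot("combined", "radiomic")
  }
  if (all(c("combined", "clinical") %in% names(models))) {
    boot$combined_vs_clinical <- try_boot("combined", "clinical")
  }

  # --- reference risk curve and risk periods ------------------------------
  ref <- NULL; risk_report <- NULL
  refv <- if ("combined" %in% names(models)) "combined" else names(models)[1]
  if (!is.null(refv) && length(models)) {
    htr <- predict(models[[refv]], all_X[tr, variants[[refv]], drop = FALSE])
    anchors <- tibble::tibble(
      horizon = horizons,
      threshold = vapply(seq_along(horizons), function(j) {
        s0 <- .s0_at(models[[refv]]$baseline, horizons[j])
        tryCatch(time_dependent_roc(s0^exp(htr), out_tr$pfs_months,
                                    out_tr$event, horizons[j])$threshold,
                 error = function(e) NA_real_)
      }, numeric(1)))
    anchors <- anchors[is.finite(anchors$threshold), ]
    ref <- tryCatch(fit_weibull_reference(anchors), error = function(e) {
      warning("reference curve fit failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(ref)) {
      curves <- predict(models[[refv]], all_X[te, variants[[refv]], drop = FALSE],
                        type = "survival", times = seq(0, 30, by = 0.5))
      curves$patient_id <- outcomes$patient_id[te][curves$.row]
      risk_report <- risk_period_report(curves[, c("patient_id", "time", "surv")],
                                        ref, window = c(0, 24), step = 0.5)
    }
  }

  manifest <- list(
    n_patients = nrow(outcomes),
    train_fraction = config$train_fraction,
    horizons = horizons,
    seeds = config$seeds,
    cohort_seed = cohort$config$seed,
    hyperparams = unclass(config$hyperparams),
    panels = variants,
    package_version = as.character(utils::packageVersion("radsurv")))

  run <- structure(list(cohort = cohort, features = features, split = sp,
                        screens = list(radiomic = scr_rad, clinical = scr_clin),
                        panels = list(radiomic = panel_rad,
                                      clinical = panel_clin),
                        variants = variants, models = models,
                        metrics = metrics, roc = roc_tbls,
                        surv_test = surv_te,
                        bootstrap = boot, logrank = dplyr::bind_rows(logrank),
                        reference_curve = ref, risk_report = risk_report,
                        manifest = manifest),
                   class = "radsurv_run")
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' @export
print.radsurv_run <- function(x, ...) {
  cat("<radsurv_run>\n")
  print(x$metrics)
  invisible(x)
}

#' Write pipeline artifacts
#'
#' Feature table, screen results, panels, per-variant metrics, risk report
#' and the manifest, as CSV/JSON under one directory.
#'
#' @param run a `radsurv_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(run$features, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(run$screens$radiomic, file.path(dir, "screen_radiomic.csv"),
            row.names = FALSE)
  write.csv(run$screens$clinical, file.path(dir, "screen_clinical.csv"),
            row.names = FALSE)
  write.csv(run$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(run$risk_report)) {
    write.csv(run$risk_report, file.path(dir, "risk_report.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(run$variants, file.path(dir, "panels.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(run$reference_curve)) {
    jsonlite::write_json(list(shape = run$reference_curve$shape,
                              scale = run$reference_curve$scale,
                              anchors = run$reference_curve$anchors),
                         file.path(dir, "reference_curve.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
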