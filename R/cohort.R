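# Full synthetic cohort: phantom specs + clinical covariates + outcomes with
# a recorded ground-truth log, reproducible from one seed.

#' Generate a synthetic cohort
#'
#' Draws, per patient, a latent shape score (mapped to ellipsoid elongation
#' and surface lobulation, so that rounder tumours have higher compactness)
#' and a latent texture score (mapped to the Gaussian-random-field correlation
#' length, so that smoother interiors score higher on homogeneity features
#' such as GLCM IDMN), together with clinical covariates; PFS outcomes follow
#' the configured Weibull proportional-hazards model on the standardized
#' generating covariates.
#'
#' Phantom image data are returned as `phantom_spec`s (deterministic in their
#' seeds) rather than materialised arrays; [generate_phantom()] or
#' [extract_cohort_features()] realise them on demand, which keeps a
#' 270-patient cohort small in memory.
#'
#' @param cfg a [cohort_config()].
#' @param grid_shape voxels per axis for each phantom.
#' @param spacing_mm voxel size (mm).
#' @param write_dir optional directory: writes volumes/masks as NIfTI
#'   (`<id>_vol.nii.gz`, `<id>_mask.nii.gz`) and tables as CSV.
#' @return object of class `radsurv_cohort`: list with `phantoms` (list of
#'   `phantom_spec`), `clinical`, `outcomes`, `ground_truth` tibbles and the
#'   `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 12, seed = 7))
#' coh$outcomes
#' @export
generate_cohort <- function(cfg, grid_shape = c(48, 48, 48),
                            spacing_mm = c(1, 1, 1), write_dir = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_patients
  withr::with_seed(cfg$seed, {
    z_shape <- rnorm(n)      # high = round
    w_tex <- rnorm(n)        # high = long correlation length (homogeneous)
    radius <- runif(n, 6, 9)
    phantom_seeds <- sample.int(.Machine$integer.max - 1L, n)
    clin_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    surv_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  })

  lob <- 0.25 * pnorm(-z_shape)
  elong <- 1 + 0.6 * pnorm(-z_shape)
  corr <- 0.5 + 4 * pnorm(w_tex)

  phantoms <- lapply(seq_len(n), function(i) {
    phantom_spec(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 semi_axes_mm = c(radius[i] * elong[i], radius[i],
                                  radius[i] / elong[i]),
                 lobulation_amp = lob[i], texture_corr_mm = corr[i],
                 seed = phantom_seeds[i])
  })

  clinical <- generate_clinical(n, seed = clin_seed)
  enc <- encode_clinical(clinical)

  gt <- tibble::tibble(
    patient_id = clinical$patient_id,
    compactness = z_shape,
    texture = w_tex,
    n_stage = enc$n_stage,
    m_stage = enc$m_stage,
    histology = enc$histology,
    radius_mm = radius,
    lobulation_amp = lob,
    elongation_factor = elong,
    texture_corr_mm = corr
  )

  outcomes <- simulate_survival(gt, cfg, seed = surv_seed)
  gt$eta <- outcomes$eta
  gt$time_true <- outcomes$time_true
  outcomes <- outcomes[, c("patient_id", "pfs_months", "event")]

  coh <- structure(list(phantoms = phantoms, clinical = clinical,
                        outcomes = outcomes, ground_truth = gt, config = cfg),
                   class = "radsurv_cohort")
  if (!is.null(write_dir)) write_cohort(coh, write_dir)
  coh
}

#' @export
print.radsurv_cohort <- function(x, ...) {
  cat(sprintf("<radsurv_cohort> %d patients, seed %d\n",
              length(x$phantoms), x$config$seed))
  cat(sprintf("  events: %d (%.2f), median PFS %.1f months\n",
              sum(x$outcomes$event), mean(x$outcomes$event),
              median(x$outcomes$pfs_months)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Volumes and masks as compressed NIfTI, clinical/outcome/ground-truth
#' tables as CSV, under one directory.
#'
#' @param cohort a `radsurv_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$phantoms)) {
    ph <- generate_phantom(cohort$phantoms[[i]])
    id <- cohort$clinical$patient_id[i]
    sp <- voxel_spacing(ph$volume)
    RNifti::writeNifti(RNifti::asNifti(ph$volume, pixdim = sp),
                       file.path(dir, paste0(id, "_vol.nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(ph$mask, pixdim = sp),
                       file.path(dir, paste0(id, "_mask.nii.gz")))
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}
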