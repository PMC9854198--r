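# Assembly of the 593-feature radiomic panel per ROI and per cohort.

#' Names of the full radiomic feature panel
#'
#' Fixed schema: for each of the nine image sets (original + eight wavelet
#' subbands), 14 histogram + 22 GLCM + 16 GLRLM + 12 LBP features named
#' `<imageset>_<family>_<feature>`, plus 17 `shape_<feature>` geometry
#' features computed once on the original mask; 9 x 64 + 17 = 593 names.
#'
#' @return character vector of length 593.
#' @export
feature_names <- function() {
  sets <- wavelet_set_names()
  per_set <- c(paste0("histogram_", .histogram_feature_names),
               paste0("glcm_", .glcm_feature_names),
               paste0("glrlm_", .glrlm_feature_names),
               paste0("lbp_", .lbp_feature_names))
  c(as.vector(vapply(sets, function(s) paste0(s, "_", per_set),
                     character(length(per_set)))),
    paste0("shape_", .geometry_feature_names))
}

#' Extract the full feature panel from a wavelet bank
#'
#' Computes all 593 radiomic features: texture/histogram/LBP families on each
#' of the nine image sets (each discretised separately over its in-mask
#' range) and shape features once on the original mask.
#'
#' @param bank a `wavelet_bank` from [wavelet_decompose()].
#' @param mask aligned binary mask.
#' @param n_bins gray levels for texture discretisation.
#' @return named numeric vector of length 593 (attribute `degenerate` lists
#'   image sets with a collapsed gray-level range).
#' @export
extract_all <- function(bank, mask, n_bins = 32) {
  stopifnot(inherits(bank, "wavelet_bank"))
  if (!identical(dim(bank$original), dim(mask))) {
    stop("bank and mask are not aligned", call. = FALSE)
  }
  out <- numeric(0)
  degen <- character(0)
  for (set in wavelet_set_names()) {
    vol <- bank[[set]]
    vals <- tryCatch({
      q <- discretize(vol, mask, n_bins)
      hf <- histogram_features(vol, mask, n_bins)
      gf <- glcm_features(q)
      rf <- glrlm_features(q)
      lf <- lbp_features(vol, mask)
      if (isTRUE(attr(gf, "degenerate"))) degen <- c(degen, set)
      c(setNames(hf, paste0(set, "_histogram_", names(hf))),
        setNames(gf, paste0(set, "_glcm_", names(gf))),
        setNames(rf, paste0(set, "_glrlm_", names(rf))),
        setNames(lf, paste0(set, "_lbp_", names(lf))))
    }, error = function(e) {
      stop(sprintf("feature extraction failed on image set '%s': %s",
                   set, conditionMessage(e)), call. = FALSE)
    })
    out <- c(out, vals)
  }
  gm <- geometry_features(mask)
  out <- c(out, setNames(as.numeric(gm), paste0("shape_", names(gm))))
  attr(out, "degenerate") <- degen
  out
}

#' Extract features for a single volume/mask pair
#'
#' Convenience wrapper running the full preprocessing chain (resample to
#' isotropic 1 mm, Z-score normalise, wavelet decompose) before
#' [extract_all()]. Resampling is skipped when the input is already on the
#' target grid.
#'
#' @param volume intensity volume.
#' @param mask aligned binary mask.
#' @param n_bins gray levels for texture discretisation.
#' @return named numeric vector of length 593.
#' @export
extract_features <- function(volume, mask, n_bins = 32) {
  sp <- voxel_spacing(volume)
  if (max(abs(sp - 1)) > 1e-9) {
    rs <- resample_isotropic(volume, mask, 1)
    volume <- rs$volume
    mask <- rs$mask
  }
  bank <- wavelet_decompose(zscore_normalize(volume))
  extract_all(bank, mask, n_bins)
}

#' Extract the feature table for a whole cohort
#'
#' Materialises each patient's phantom, runs the preprocessing chain and
#' feature extraction, and returns the rectangular cohort feature table.
#'
#' @param cohort a `radsurv_cohort` from [generate_cohort()].
#' @param n_bins gray levels for texture discretisation.
#' @param progress print a dot every 25 patients.
#' @return tibble: `patient_id` plus 593 feature columns, no missing entries.
#' @export
extract_cohort_features <- function(cohort, n_bins = 32, progress = FALSE) {
  stopifnot(inherits(cohort, "radsurv_cohort"))
  rows <- lapply(seq_along(cohort$phantoms), function(i) {
    ph <- generate_phantom(cohort$phantoms[[i]])
    fv <- extract_features(ph$volume, ph$mask, n_bins)
    if (progress && i %% 25 == 0) cat(".")
    fv
  })
  if (progress) cat("\n")
  mat <- do.call(rbind, rows)
  dplyr::bind_cols(tibble::tibble(patient_id = cohort$clinical$patient_id),
                   tibble::as_tibble(mat))
}
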