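# Image preprocessing: isotropic resampling, Z-score normalisation, and
# one-level undecimated wavelet decomposition into eight subbands.

# Coiflet-1 decomposition filters (6 taps)
.COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
               0.3848648468648578, 0.8525720202116004,
               0.3378976624574818, -0.07273261951252645)
.COIF1_HI <- c(0.07273261951252645, 0.3378976624574818,
               -0.8525720202116004, 0.3848648468648578,
               0.07273261951252645, -0.015655728135791993)

#' Resample a volume and mask to isotropic spacing
#'
#' Trilinear interpolation for intensities; nearest-neighbour with
#' re-binarisation for the mask. The default target is the 1 mm^3 grid used
#' throughout the feature pipeline.
#'
#' @param vol intensity volume (3D array with `spacing` attribute).
#' @param mask aligned binary mask.
#' @param new_spacing target spacing (mm, scalar or length-3).
#' @return list with resampled `volume` and `mask`.
#' @export
resample_isotropic <- function(vol, mask, new_spacing = 1) {
  sp <- voxel_spacing(vol)
  stopifnot(all(sp > 0), identical(dim(vol), dim(mask)))
  if (sum(mask != 0) == 0) stop("input mask is empty", call. = FALSE)
  ns <- rep(as.numeric(new_spacing), length.out = 3)
  v <- cpp_resample(as.numeric(vol), dim(vol), sp, ns, FALSE)
  m <- cpp_resample(as.numeric(mask != 0), dim(mask), sp, ns, TRUE)
  m <- array(as.integer(m >= 0.5), dim(m))
  if (sum(m) == 0) {
    stop("mask vanished under resampling; increase resolution", call. = FALSE)
  }
  list(volume = as_volume(array(v, dim(v)), ns), mask = as_volume(m, ns))
}

#' Z-score normalise a volume
#'
#' Standardises intensities to mean 0 and SD 1 over the whole volume (not
#' only the ROI), matching normalisation against the image-wide mean and
#' standard deviation.
#'
#' @param vol intensity volume.
#' @return normalised volume (same grid and spacing).
#' @export
zscore_normalize <- function(vol) {
  stopifnot(length(vol) > 1)
  m <- mean(vol)
  s <- sd(as.numeric(vol))
  if (!is.finite(s) || s < 1e-12) {
    stop("volume has zero intensity variance; cannot Z-score", call. = FALSE)
  }
  as_volume(array((vol - m) / s, dim(vol)), voxel_spacing(vol))
}

#' One-level undecimated wavelet decomposition
#'
#' Applies low-pass (L) and high-pass (H) Coiflet-1 filtering along each of
#' the three axes in all combinations, producing the eight subbands LLL, LLH,
#' LHL, LHH, HLL, HLH, HHL, HHH on the same grid as the input (stationary
#' transform, symmetric boundary). Subband letters follow axis order: first
#' letter = axis 1 (x), second = axis 2 (y), third = axis 3 (z).
#'
#' @param vol intensity volume; every axis must be at least 6 voxels
#'   (the filter length).
#' @return object of class `wavelet_bank`: named list of nine volumes
#'   (`original` plus the eight subbands).
#' @export
wavelet_decompose <- function(vol) {
  dm <- dim(vol)
  if (any(dm < 6)) {
    stop("each axis must be at least the filter length (6 voxels)",
         call. = FALSE)
  }
  sp <- voxel_spacing(vol)
  x <- as.numeric(vol)
  # cascade: filter axis 1, then 2, then 3
  ax1 <- list(L = cpp_conv1d_axis(x, dm, .COIF1_LO, 0L, 2L),
              H = cpp_conv1d_axis(x, dm, .COIF1_HI, 0L, 2L))
  bank <- list(original = as_volume(array(x, dm), sp))
  for (l1 in c("L", "H")) {
    ax2 <- list(L = cpp_conv1d_axis(ax1[[l1]], dm, .COIF1_LO, 1L, 2L),
                H = cpp_conv1d_axis(ax1[[l1]], dm, .COIF1_HI, 1L, 2L))
    for (l2 in c("L", "H")) {
      for (l3 in c("L", "H")) {
        ker <- if (l3 == "L") .COIF1_LO else .COIF1_HI
        sub <- cpp_conv1d_axis(ax2[[l2]], dm, ker, 2L, 2L)
        bank[[paste0(l1, l2, l3)]] <- as_volume(array(sub, dm), sp)
      }
    }
  }
  # canonical order
  bank <- bank[c("original", "LLL", "LLH", "LHL", "LHH",
                 "HLL", "HLH", "HHL", "HHH")]
  structure(bank, class = "wavelet_bank")
}

#' Names of the wavelet image sets
#' @return character vector of the nine image-set names.
#' @export
wavelet_set_names <- function() {
  c("original", "LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}
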