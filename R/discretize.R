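# Gray-level discretisation of an ROI for texture matrices.

#' Discretise ROI intensities into gray levels
#'
#' Fixed-bin-number quantisation over the in-mask min-max range. A constant
#' ROI collapses to a single level.
#'
#' @param vol intensity volume.
#' @param mask aligned binary mask (non-empty).
#' @param n_bins requested number of gray levels.
#' @return object of class `quantized_roi`: list with `levels` (integer grid,
#'   0 outside the mask, 1..`n_levels` inside), `n_levels`, `voxel_count`.
#' @export
discretize <- function(vol, mask, n_bins = 32) {
  stopifnot(identical(dim(vol), dim(mask)), n_bins >= 1)
  inm <- mask != 0
  nvox <- sum(inm)
  if (nvox == 0) stop("mask is empty; cannot discretise", call. = FALSE)
  v <- vol[inm]
  lo <- min(v); hi <- max(v)
  lev <- array(0L, dim(vol))
  if (hi - lo < 1e-12) {
    lev[inm] <- 1L
    ng <- 1L
  } else {
    q <- floor((v - lo) / (hi - lo) * n_bins) + 1
    q[q > n_bins] <- n_bins
    lev[inm] <- as.integer(q)
    ng <- as.integer(n_bins)
  }
  structure(list(levels = lev, n_levels = ng, voxel_count = nvox),
            class = "quantized_roi")
}
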