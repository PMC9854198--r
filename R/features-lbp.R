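# Rotation-invariant uniform local binary patterns, slice-wise, pooled over
# all axial slices of the ROI.

.lbp_feature_names <- c(paste0("bin", 0:8), "nonuniform", "code_mean",
                        "code_entropy")

#' LBP features
#'
#' Rotation-invariant uniform LBP codes (8 neighbours, radius 1) are computed
#' per axial slice for every in-mask pixel with a complete 3x3 in-slice
#' neighbourhood (neighbour intensities come from the image, inside or
#' outside the mask); the 10-bin code histogram (codes 0..8 uniform, 9
#' non-uniform) is pooled over slices and normalised, and summarised further
#' by the mean and entropy of the pooled code distribution.
#'
#' @param vol intensity volume (image set).
#' @param mask aligned binary mask; must contain at least one voxel with a
#'   complete in-slice neighbourhood.
#' @return named numeric vector of 12 features.
#' @export
lbp_features <- function(vol, mask) {
  stopifnot(identical(dim(vol), dim(mask)))
  if (sum(mask != 0) == 0) stop("mask is empty", call. = FALSE)
  res <- cpp_lbp_hist(as.numeric(vol), as.integer(mask != 0), dim(vol))
  if (res$n == 0) {
    stop("no in-mask pixel has a complete in-slice neighbourhood",
         call. = FALSE)
  }
  p <- res$counts / res$n
  pe <- p[p > 0]
  setNames(c(p, sum(p * (0:9)), -sum(pe * log2(pe))), .lbp_feature_names)
}
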