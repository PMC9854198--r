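# First-order (histogram) features over in-mask voxels of one image set.

.histogram_feature_names <- c(
  "mean", "variance", "skewness", "kurtosis", "median", "minimum", "maximum",
  "range", "iqr", "energy", "entropy", "uniformity", "rms", "mad")

#' Histogram (first-order) features
#'
#' Fourteen intensity statistics over in-mask voxels. Skewness is
#' `m3 / m2^(3/2)` and kurtosis the non-excess `m4 / m2^2` (so a normal
#' sample scores about 3); both are 0 for a constant ROI. Entropy and
#' uniformity use a 32-bin histogram over the in-mask range (a constant ROI
#' has entropy 0, uniformity 1).
#'
#' @param vol intensity volume (image set).
#' @param mask aligned binary mask (non-empty).
#' @param n_bins histogram bins for entropy/uniformity.
#' @return named numeric vector of 14 features.
#' @export
histogram_features <- function(vol, mask, n_bins = 32) {
  stopifnot(identical(dim(vol), dim(mask)))
  v <- vol[mask != 0]
  if (length(v) == 0) stop("mask is empty", call. = FALSE)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-12) {
    p <- 1
  } else {
    br <- seq(lo, hi, length.out = n_bins + 1)
    cnt <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = n_bins)
    p <- cnt[cnt > 0] / length(v)
  }
  setNames(c(
    m,
    m2,
    if (m2 > 1e-24) mean((v - m)^3) / m2^1.5 else 0,
    if (m2 > 1e-24) mean((v - m)^4) / m2^2 else 0,
    median(v),
    lo,
    hi,
    hi - lo,
    unname(quantile(v, 0.75) - quantile(v, 0.25)),
    sum(v^2),
    -sum(p * log2(p)),
    sum(p^2),
    sqrt(mean(v^2)),
    mean(abs(v - m))
  ), .histogram_feature_names)
}
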