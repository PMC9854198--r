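# Gray-level co-occurrence matrix features (22), direction-averaged over the
# 13 unique 3D offsets at distance 1, matrix-level symmetrisation.

.glcm_feature_names <- c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "joint_energy", "joint_entropy",
  "imc1", "imc2", "inverse_difference", "idn", "inverse_difference_moment",
  "idmn", "inverse_variance", "maximum_probability", "sum_average",
  "sum_entropy")

# direction-averaged symmetric normalized co-occurrence matrix
.glcm_matrix <- function(q) {
  ng <- q$n_levels
  counts <- cpp_glcm_counts(q$levels, dim(q$levels), ng)
  p <- matrix(0, ng, ng)
  nd <- 0L
  for (d in 1:13) {
    cd <- counts[, , d, drop = FALSE]
    dim(cd) <- c(ng, ng)
    s <- sum(cd)
    if (s > 0) {
      p <- p + cd / s
      nd <- nd + 1L
    }
  }
  if (nd == 0L) return(NULL)  # no co-occurring pairs (e.g. single voxel)
  p / nd
}

.glcm_from_matrix <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)                      # symmetric: px == py
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  # difference distribution p_{|i-j|}(k), k = 0..ng-1
  dk <- 0:(ng - 1)
  pdiff <- vapply(dk, function(k) sum(p[abs(i - j) == k]), numeric(1))
  # sum distribution p_{i+j}(k), k = 2..2*ng
  sk <- 2:(2 * ng)
  psum <- vapply(sk, function(k) sum(p[(i + j) == k]), numeric(1))
  lg2 <- function(x) ifelse(x > 0, log2(x), 0)
  hxy <- -sum(p * lg2(p))
  pxy <- outer(px, px)
  hxy1 <- -sum(p * lg2(pxy))
  hxy2 <- -sum(pxy * lg2(pxy))
  hx <- -sum(px * lg2(px))
  da <- sum(dk * pdiff)
  c(autocorrelation = sum(i * j * p),
    joint_average = mu,
    cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    cluster_shade = sum((i + j - 2 * mu)^3 * p),
    cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = if (sig2 > 1e-12) (sum(i * j * p) - mu^2) / sig2 else 0,
    difference_average = da,
    difference_entropy = -sum(pdiff * lg2(pdiff)),
    difference_variance = sum((dk - da)^2 * pdiff),
    joint_energy = sum(p^2),
    joint_entropy = hxy,
    imc1 = if (hx > 1e-12) (hxy - hxy1) / hx else 0,
    imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    inverse_difference = sum(p / (1 + abs(i - j))),
    idn = sum(p / (1 + abs(i - j) / ng)),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    inverse_variance = sum((p / (i - j)^2)[i != j]),
    maximum_probability = max(p),
    sum_average = sum(sk * psum),
    sum_entropy = -sum(psum * lg2(psum)))
}

#' GLCM texture features
#'
#' Builds the direction-averaged symmetric co-occurrence matrix (distance 1,
#' 13 unique 3D offsets) and returns 22 features, including the inverse
#' difference moment normalized (IDMN), the local-homogeneity measure
#' `sum_ij p(i,j) / (1 + (i-j)^2 / Ng^2)`.
#'
#' A single-gray-level ROI is degenerate: homogeneity-type features take
#' their limiting value (IDMN = 1, contrast = 0), entropy-type features 0;
#' the result carries a `degenerate` attribute.
#'
#' @param q a `quantized_roi` from [discretize()].
#' @return named numeric vector of 22 features (attribute `degenerate`
#'   flags a constant or single-voxel ROI).
#' @export
glcm_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  p <- .glcm_matrix(q)
  degen <- is.null(p) || q$n_levels == 1L
  if (is.null(p)) p <- matrix(1, 1, 1)
  out <- .glcm_from_matrix(p)
  names(out) <- .glcm_feature_names
  attr(out, "degenerate") <- degen
  out
}
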