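# Gray-level run-length matrix features (16), computed per direction over the
# 13 unique 3D directions and averaged across directions.

.glrlm_feature_names <- c(
  "sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv", "rv", "re",
  "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle")

.glrlm_from_matrix <- function(R, n_voxels) {
  nr <- sum(R)
  if (nr == 0) return(NULL)
  ng <- nrow(R); nl <- ncol(R)
  i <- matrix(seq_len(ng), ng, nl)
  j <- matrix(rep(seq_len(nl), each = ng), ng, nl)
  p <- R / nr
  mug <- sum(p * i)
  mur <- sum(p * j)
  lg2 <- function(x) ifelse(x > 0, log2(x), 0)
  c(sre = sum(R / j^2) / nr,
    lre = sum(R * j^2) / nr,
    gln = sum(rowSums(R)^2) / nr,
    glnn = sum(rowSums(R)^2) / nr^2,
    rln = sum(colSums(R)^2) / nr,
    rlnn = sum(colSums(R)^2) / nr^2,
    rp = nr / n_voxels,
    glv = sum(p * (i - mug)^2),
    rv = sum(p * (j - mur)^2),
    re = -sum(p * lg2(p)),
    lglre = sum(R / i^2) / nr,
    hglre = sum(R * i^2) / nr,
    srlgle = sum(R / (i^2 * j^2)) / nr,
    srhgle = sum(R * i^2 / j^2) / nr,
    lrlgle = sum(R * j^2 / i^2) / nr,
    lrhgle = sum(R * i^2 * j^2) / nr)
}

#' GLRLM texture features
#'
#' Run-length matrices are built for each of the 13 unique 3D directions
#' (runs are maximal same-level in-mask segments); the 16 features are
#' computed per direction and averaged across directions.
#'
#' @param q a `quantized_roi` from [discretize()].
#' @return named numeric vector of 16 features (attribute `degenerate`
#'   flags a single-level ROI).
#' @export
glrlm_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  counts <- cpp_glrlm_counts(q$levels, dim(q$levels), q$n_levels)
  ng <- q$n_levels
  nl <- dim(counts)[2]
  acc <- NULL
  nd <- 0L
  for (d in 1:13) {
    R <- counts[, , d, drop = FALSE]
    dim(R) <- c(ng, nl)
    f <- .glrlm_from_matrix(R, q$voxel_count)
    if (is.null(f)) next
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  out <- acc / nd
  names(out) <- .glrlm_feature_names
  attr(out, "degenerate") <- q$n_levels == 1L
  out
}
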