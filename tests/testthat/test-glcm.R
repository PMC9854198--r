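# independent re-computation of all 22 features from a normalised matrix,
# written as plain loops over (i, j) pairs
oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  lg2 <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(p)
  mu <- 0; for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  sig2 <- 0; for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (i - mu)^2 * p[i, j]
  acc <- numeric(22); names(acc) <- radsurv:::.glcm_feature_names
  pd <- rep(0, ng); ps <- rep(0, 2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    acc["autocorrelation"] <- acc["autocorrelation"] + i * j * v
    acc["cluster_prominence"] <- acc["cluster_prominence"] + (i + j - 2 * mu)^4 * v
    acc["cluster_shade"] <- acc["cluster_shade"] + (i + j - 2 * mu)^3 * v
    acc["cluster_tendency"] <- acc["cluster_tendency"] + (i + j - 2 * mu)^2 * v
    acc["contrast"] <- acc["contrast"] + (i - j)^2 * v
    acc["joint_energy"] <- acc["joint_energy"] + v^2
    acc["joint_entropy"] <- acc["joint_entropy"] - v * lg2(v)
    acc["inverse_difference"] <- acc["inverse_difference"] + v / (1 + abs(i - j))
    acc["idn"] <- acc["idn"] + v / (1 + abs(i - j) / ng)
    acc["inverse_difference_moment"] <- acc["inverse_difference_moment"] +
      v / (1 + (i - j)^2)
    acc["idmn"] <- acc["idmn"] + v / (1 + (i - j)^2 / ng^2)
    if (i != j) acc["inverse_variance"] <- acc["inverse_variance"] + v / (i - j)^2
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + v
    ps[i + j - 1] <- ps[i + j - 1] + v
  }
  acc["joint_average"] <- mu
  acc["correlation"] <- if (sig2 > 1e-12) {
    (acc["autocorrelation"] - mu^2) / sig2
  } else 0
  acc["maximum_probability"] <- max(p)
  da <- sum((0:(ng - 1)) * pd)
  acc["difference_average"] <- da
  acc["difference_entropy"] <- -sum(vapply(pd, function(x) x * lg2(x), 0))
  acc["difference_variance"] <- sum(((0:(ng - 1)) - da)^2 * pd)
  acc["sum_average"] <- sum((2:(2 * ng)) * ps)
  acc["sum_entropy"] <- -sum(vapply(ps, function(x) x * lg2(x), 0))
  hxy <- acc["joint_entropy"]
  hxy1 <- 0; hxy2 <- 0; hx <- 0
  for (i in 1:ng) {
    hx <- hx - px[i] * lg2(px[i])
    for (j in 1:ng) {
      hxy1 <- hxy1 - p[i, j] * lg2(px[i] * px[j])
      hxy2 <- hxy2 - px[i] * px[j] * lg2(px[i] * px[j])
    }
  }
  acc["imc1"] <- if (hx > 1e-12) (hxy - hxy1) / hx else 0
  acc["imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  acc
}

make_quantized <- function(levels) {
  structure(list(levels = levels, n_levels = max(levels),
                 voxel_count = sum(levels > 0)), class = "quantized_roi")
}

test_that("single-gray-level ROI is degenerate with limiting values", {
  lev <- array(1L, c(3, 3, 3))
  f <- glcm_features(make_quantized(lev))
  expect_true(attr(f, "degenerate"))
  expect_equal(f[["idmn"]], 1)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["joint_energy"]], 1)
  expect_equal(f[["joint_entropy"]], 0)
  expect_equal(f[["maximum_probability"]], 1)
})

test_that("2x2x1 checkerboard matches the brute-force pair enumeration", {
  lev <- array(0L, c(2, 2, 1))
  lev[, , 1] <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  f <- glcm_features(make_quantized(lev))
  p <- oracle_glcm(lev)
  ref <- oracle_glcm_features(p)
  expect_equal(unclass(f)[names(ref)], ref, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("random small ROIs match the oracle exactly", {
  withr::with_seed(5, {
    for (rep in 1:4) {
      dm <- sample(2:5, 3, replace = TRUE)
      lev <- array(sample(0:4, prod(dm), replace = TRUE), dm)
      if (sum(lev > 0) < 3 || max(lev) < 1) next
      q <- make_quantized(lev)
      q$n_levels <- max(lev)
      f <- glcm_features(q)
      ref <- oracle_glcm_features(oracle_glcm(lev))
      expect_equal(unclass(f)[names(ref)], ref, tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  })
})

test_that("probability-derived features respect their bounds", {
  ph <- small_sphere_phantom()
  q <- discretize(ph$volume, ph$mask, 16)
  f <- glcm_features(q)
  expect_gt(f[["idmn"]], 0); expect_lte(f[["idmn"]], 1)
  expect_gt(f[["maximum_probability"]], 0)
  expect_lte(f[["maximum_probability"]], 1)
})

test_that("GLCM features are invariant to mask translation", {
  lev <- array(0L, c(6, 6, 6))
  lev[2:4, 2:4, 2:4] <- array(sample(1:3, 27, replace = TRUE), c(3, 3, 3))
  shifted <- array(0L, c(6, 6, 6))
  shifted[3:5, 3:5, 3:5] <- lev[2:4, 2:4, 2:4]
  f1 <- glcm_features(make_quantized(lev))
  f2 <- glcm_features(make_quantized(shifted))
  expect_equal(unclass(f1), unclass(f2), ignore_attr = TRUE)
})
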