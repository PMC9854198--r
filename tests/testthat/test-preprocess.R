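test_that("resampling at 1 mm input is an identity; masks survive", {
  ph <- small_sphere_phantom()
  rs <- resample_isotropic(ph$volume, ph$mask, 1)
  expect_equal(dim(rs$volume), dim(ph$volume))
  expect_equal(unclass(rs$volume), unclass(ph$volume), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(unclass(rs$mask)[TRUE], unclass(ph$mask)[TRUE])
})

test_that("a 2 mm sphere resamples to its analytic volume at 1 mm", {
  n <- 24
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * 2   # mm at 2 mm spacing
  m <- array(0L, c(n, n, n))
  for (k in seq_len(n)) {
    m[, , k] <- (outer(xs^2, xs^2, "+") + xs[k]^2) <= 64
  }
  vol <- as_volume(array(rnorm(n^3), c(n, n, n)), c(2, 2, 2))
  mask <- as_volume(m, c(2, 2, 2))
  rs <- resample_isotropic(vol, mask, 1)
  vol_mm3 <- sum(rs$mask)   # 1 mm^3 voxels
  expect_lt(abs(vol_mm3 - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.10)
})

test_that("empty and vanishing masks are rejected", {
  vol <- as_volume(array(rnorm(8^3), c(8, 8, 8)), c(1, 1, 1))
  empty <- as_volume(array(0L, c(8, 8, 8)), c(1, 1, 1))
  expect_error(resample_isotropic(vol, empty), "empty")
  # a single 0.4 mm voxel vanishes on the 1 mm grid
  tiny <- array(0L, c(8, 8, 8)); tiny[1, 1, 1] <- 1L
  vol2 <- as_volume(array(rnorm(8^3), c(8, 8, 8)), c(0.4, 0.4, 0.4))
  expect_error(resample_isotropic(vol2, as_volume(tiny, c(0.4, 0.4, 0.4)), 1),
               "vanish")
})

test_that("Z-score normalisation standardises and is affine-invariant", {
  vol <- as_volume(array(rnorm(10^3, 50, 9), c(10, 10, 10)))
  z <- zscore_normalize(vol)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sd(as.numeric(z)) - 1), 1e-6)
  z2 <- zscore_normalize(as_volume(array(3 * vol + 11, dim(vol))))
  expect_equal(unclass(z), unclass(z2), tolerance = 1e-10)
  expect_error(zscore_normalize(as_volume(array(5, c(8, 8, 8)))),
               "zero intensity variance")
})

test_that("wavelet bank has nine congruent sets; high-pass kills DC", {
  const <- as_volume(array(7, c(12, 12, 12)))
  bank <- wavelet_decompose(const)
  expect_named(bank, c("original", "LLL", "LLH", "LHL", "LHH",
                       "HLL", "HLH", "HHL", "HHH"))
  for (s in names(bank)) expect_equal(dim(bank[[s]]), c(12, 12, 12))
  expect_lt(max(abs(bank$LLL - bank$LLL[1])), 1e-8)   # still constant
  for (s in c("LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")) {
    expect_lt(max(abs(bank[[s]])), 1e-8)
  }
  expect_error(wavelet_decompose(as_volume(array(1, c(4, 12, 12)))),
               "filter length")
})

test_that("a pure x-axis alternation concentrates energy in HLL", {
  v <- array(rep_len(c(1, -1), 16), c(16, 16, 16))   # alternates along axis 1
  bank <- wavelet_decompose(as_volume(v))
  en <- vapply(bank[-1], function(b) sum(b^2), numeric(1))
  expect_equal(names(which.max(en)), "HLL")
})

test_that("swapping axes 2 and 3 permutes subbands LLH <-> LHL", {
  set.seed(33)
  v <- array(rnorm(14^3), c(14, 14, 14))
  b1 <- wavelet_decompose(as_volume(v))
  b2 <- wavelet_decompose(as_volume(aperm(v, c(1, 3, 2))))
  expect_equal(unclass(aperm(b2$LLH, c(1, 3, 2))), unclass(b1$LHL),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(aperm(b2$LHL, c(1, 3, 2))), unclass(b1$LLH),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("global intensity shifts vanish after Z-scoring", {
  set.seed(4)
  v <- array(rnorm(12^3), c(12, 12, 12))
  b1 <- wavelet_decompose(zscore_normalize(as_volume(v)))
  b2 <- wavelet_decompose(zscore_normalize(as_volume(array(v + 100, dim(v)))))
  expect_equal(unclass(b1$HHH), unclass(b2$HHH), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unclass(b1$LLL), unclass(b2$LLL), tolerance = 1e-8,
               ignore_attr = TRUE)
})
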