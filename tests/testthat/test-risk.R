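test_that("Weibull-consistent anchors are recovered exactly", {
  hz <- c(3, 12, 18, 24)
  anchors <- tibble::tibble(horizon = hz,
                            threshold = exp(-(hz / 12)^1.5))
  ref <- fit_weibull_reference(anchors)
  expect_equal(ref$shape, 1.5, tolerance = 1e-6)
  expect_equal(ref$scale, 12, tolerance = 1e-6)
  expect_lt(max(abs(ref$anchors$residual)), 1e-9)
  # exponential special case (k = 1)
  ref1 <- fit_weibull_reference(
    tibble::tibble(horizon = hz, threshold = exp(-hz / 10)))
  expect_equal(ref1$shape, 1, tolerance = 1e-6)
  expect_equal(ref1$scale, 10, tolerance = 1e-6)
})

test_that("round-trip recovery holds for random Weibull anchors", {
  withr::with_seed(7, {
    for (i in 1:10) {
      k <- runif(1, 0.5, 3); lam <- runif(1, 5, 30)
      hz <- sort(runif(4, 1, 30))
      ref <- fit_weibull_reference(
        tibble::tibble(horizon = hz, threshold = exp(-(hz / lam)^k)))
      expect_equal(ref$shape, k, tolerance = 1e-6)
      expect_equal(ref$scale, lam, tolerance = 1e-6)
    }
  })
})

test_that("flat or increasing anchors are rejected with diagnostics", {
  hz <- c(3, 12, 18, 24)
  expect_error(fit_weibull_reference(
    tibble::tibble(horizon = hz, threshold = rep(exp(-1), 4))),
    "non-decreasing")
  expect_error(fit_weibull_reference(
    tibble::tibble(horizon = hz, threshold = c(0.2, 0.4, 0.6, 0.8))),
    "non-decreasing")
  expect_error(fit_weibull_reference(
    tibble::tibble(horizon = hz, threshold = c(0.9, 0.5, 1.2, 0.2))),
    "inside")
})

test_that("signed areas behave on constructed curves", {
  ref <- fit_weibull_reference(tibble::tibble(
    horizon = c(3, 12, 18, 24),
    threshold = exp(-(c(3, 12, 18, 24) / 14)^1.3)))
  grid <- seq(0, 24, 0.5)
  same <- ref_survival(ref, grid)
  ra <- risk_area(same, ref)
  expect_equal(ra$area, 0, tolerance = 1e-12)
  expect_equal(nrow(ra$negative_intervals), 0)
  above <- pmin(same + 0.1, 1)
  ra2 <- risk_area(above, ref)
  expect_gt(ra2$area, 0)
  expect_equal(nrow(ra2$negative_intervals), 0)
  expect_true(is.na(ra2$earliest_crossing))
})

test_that("a constructed downward crossing at t = 8 is localised", {
  ref <- fit_weibull_reference(tibble::tibble(
    horizon = c(3, 12, 18, 24),
    threshold = exp(-(c(3, 12, 18, 24) / 14)^1.3)))
  grid <- seq(0, 24, 0.5)
  # sigmoid deficit switching on at t = 8
  surv <- ref_survival(ref, grid) + 0.05 - 0.1 / (1 + exp(-(grid - 8) * 8))
  surv <- pmin(pmax(surv, 0), 1)
  ra <- risk_area(surv, ref)
  expect_equal(nrow(ra$negative_intervals), 1)
  expect_lt(abs(ra$earliest_crossing - 8), 0.25)
})

test_that("risk-period categories follow the checkpoint partition", {
  expect_equal(as.character(classify_risk_period(NA)), ">24 months")
  expect_equal(as.character(classify_risk_period(0)), "<3 months")
  expect_equal(as.character(classify_risk_period(8)), "3-12 months")
  expect_equal(as.character(classify_risk_period(13.5)), "12-18 months")
  expect_equal(as.character(classify_risk_period(20)), "18-24 months")
})

test_that("uniformly lowering a curve never delays the category", {
  ref <- fit_weibull_reference(tibble::tibble(
    horizon = c(3, 12, 18, 24),
    threshold = exp(-(c(3, 12, 18, 24) / 14)^1.3)))
  grid <- seq(0, 24, 0.5)
  base <- pmin(ref_survival(ref, grid) + 0.08, 1)
  lv <- levels(classify_risk_period(0))
  last <- length(lv) + 1
  for (drop in seq(0, 0.4, 0.05)) {
    cur <- pmax(base - drop, 0)
    ra <- risk_area(cur, ref)
    cat_i <- match(as.character(classify_risk_period(ra$earliest_crossing)), lv)
    expect_lte(cat_i, last)
    last <- cat_i
  }
})

test_that("cohort-level early-risk fraction grows with the hazard scale", {
  # personalized curves S0^exp(h) for increasingly strong risk spreads
  ref <- fit_weibull_reference(tibble::tibble(
    horizon = c(3, 12, 18, 24),
    threshold = exp(-(c(3, 12, 18, 24) / 12)^1.4)))
  grid <- seq(0, 24, 0.5)
  s0 <- exp(-(grid / 14)^1.4)   # same shape as the reference, later scale
  frac_early <- vapply(c(0.5, 1, 2), function(scale) {
    hs <- withr::with_seed(5, rnorm(80)) * scale
    cats <- vapply(hs, function(h) {
      ra <- risk_area(s0^exp(h), ref)
      as.character(classify_risk_period(ra$earliest_crossing))
    }, character(1))
    mean(cats == "<3 months")
  }, numeric(1))
  expect_true(all(diff(frac_early) >= 0))
  expect_gt(frac_early[3], frac_early[1])
})
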