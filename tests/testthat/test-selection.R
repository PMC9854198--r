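test_that("the Cox screen keeps a strongly prognostic feature", {
  sim <- simulate_ph(300, beta = 1.0, seed = 21)
  res <- cox_screen(sim$x[, 1], sim$time, sim$event, name = "eta_like")
  expect_true(res$kept)
  expect_lt(res$p_value, 0.001)
})

test_that("the Cox screen type-I error is calibrated at alpha", {
  alpha <- 0.1
  nsim <- 400
  kept <- withr::with_seed(31, vapply(seq_len(nsim), function(i) {
    n <- 80
    x <- rnorm(n)
    tt <- rexp(n); ev <- rbinom(n, 1, 0.8)
    cox_screen(x, tt, ev, alpha = alpha)$kept
  }, logical(1)))
  se <- sqrt(alpha * (1 - alpha) / nsim)
  expect_lt(abs(mean(kept) - alpha), 3 * se)
})

test_that("zero-variance features are flagged and dropped", {
  res <- cox_screen(rep(2, 50), rexp(50), rbinom(50, 1, 0.8))
  expect_false(res$kept)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("chi-squared screen matches hand-computed statistics", {
  # contingency [[30,10],[10,30]]: expected 20 per cell, chi2 = 4*100/20 = 20
  x <- rep(c("a", "b"), each = 40)
  grp_time <- c(rep(20, 30), rep(1, 10), rep(20, 10), rep(1, 30))
  ev <- rep(1, 80)
  res <- chisq_screen(x, grp_time, ev, median_pfs = 10)
  expect_equal(res$statistic, 20, tolerance = 1e-9)
  expect_lt(res$p_value, 0.001)
  expect_true(res$kept)
  # perfectly balanced table: statistic 0, not kept
  bal_time <- rep(c(20, 1, 20, 1), each = 20)
  res2 <- chisq_screen(x, bal_time, ev, median_pfs = 10)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_false(res2$kept)
})

test_that("chi-squared screen excludes patients censored before the median", {
  x <- factor(rep(c("a", "b"), 20))
  tt <- rep(c(5, 20), 20)
  ev <- rep(0, 40)        # all censored: the short ones must be excluded
  res <- chisq_screen(x, tt, ev, median_pfs = 10)
  expect_true(res$degenerate)   # only the "good" column remains
  expect_false(res$kept)
})

test_that("chi-squared null keep-rate is near alpha", {
  nsim <- 400
  kept <- withr::with_seed(41, vapply(seq_len(nsim), function(i) {
    n <- 100
    x <- sample(c("a", "b"), n, replace = TRUE)
    tt <- rexp(n, 1 / 12); ev <- rbinom(n, 1, 0.9)
    chisq_screen(x, tt, ev)$kept
  }, logical(1)))
  se <- sqrt(0.1 * 0.9 / nsim)
  expect_lt(abs(mean(kept) - 0.1), 4 * se)
})

test_that("SFS picks the generating signal first and respects the cap", {
  sim <- simulate_ph(250, beta = c(1.2, rep(0, 9)), seed = 51)
  feats <- tibble::as_tibble(as.data.frame(sim$x))
  names(feats) <- c("true_eta", paste0("noise", 1:9))
  outcomes <- tibble::tibble(pfs_months = sim$time, event = sim$event)
  panel <- sequential_forward_select(feats, outcomes, cap = 5, seed = 3)
  expect_equal(panel$features[1], "true_eta")
  panel1 <- sequential_forward_select(feats, outcomes, cap = 1, seed = 3)
  expect_length(panel1$features, 1)
  # score trace is non-decreasing
  if (nrow(panel$trace) > 1) {
    expect_true(all(diff(panel$trace$score) >= -1e-9))
  }
})

test_that("duplicated features are never both selected", {
  sim <- simulate_ph(200, beta = c(1, 0), seed = 61)
  feats <- tibble::tibble(a = sim$x[, 1], a_copy = sim$x[, 1],
                          b = sim$x[, 2])
  outcomes <- tibble::tibble(pfs_months = sim$time, event = sim$event)
  panel <- sequential_forward_select(feats, outcomes, cap = 3, seed = 5)
  expect_lte(sum(panel$features %in% c("a", "a_copy")), 1)
})

test_that("SFS is deterministic given the fold seed", {
  sim <- simulate_ph(150, beta = c(0.8, 0.4, 0), seed = 71)
  feats <- tibble::as_tibble(as.data.frame(sim$x))
  outcomes <- tibble::tibble(pfs_months = sim$time, event = sim$event)
  p1 <- sequential_forward_select(feats, outcomes, cap = 3, seed = 9)
  p2 <- sequential_forward_select(feats, outcomes, cap = 3, seed = 9)
  expect_identical(p1$features, p2$features)
  expect_equal(p1$trace, p2$trace)
})

test_that("pure-noise pools yield small panels", {
  sizes <- withr::with_seed(81, vapply(1:20, function(i) {
    n <- 120
    feats <- tibble::as_tibble(matrix(rnorm(n * 8), n,
                                      dimnames = list(NULL, paste0("f", 1:8))))
    outcomes <- tibble::tibble(pfs_months = rexp(n, 1 / 12),
                               event = rbinom(n, 1, 0.8))
    length(sequential_forward_select(feats, outcomes, cap = 5,
                                     seed = i)$features)
  }, numeric(1)))
  expect_lte(median(sizes), 2)
})
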