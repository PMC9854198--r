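test_that("concordance has its closed-form extremes", {
  tm <- c(3, 7, 1, 9, 5); ev <- rep(1, 5)
  expect_equal(concordance_index(-tm, tm, ev), 1)
  expect_equal(concordance_index(rep(2, 5), tm, ev), 0.5)
  expect_error(concordance_index(1, 5, 0), "comparable")
})

test_that("the 4-patient worked example matches exhaustive enumeration", {
  tm <- c(2, 4, 5, 7); ev <- c(1, 1, 0, 1); risk <- c(3, 1, 2, 0)
  expect_equal(concordance_index(risk, tm, ev),
               oracle_concordance(risk, tm, ev))
})

test_that("concordance equals pair enumeration and survival::concordance", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      n <- sample(10:28, 1)
      tm <- sample(1:15, n, replace = TRUE)
      ev <- rbinom(n, 1, 0.7); if (sum(ev) == 0) ev[1] <- 1
      risk <- rnorm(n)
      ours <- concordance_index(risk, tm, ev)
      expect_equal(ours, oracle_concordance(risk, tm, ev))
      ref <- survival::concordance(survival::Surv(tm, ev) ~ risk,
                                   reverse = TRUE)$concordance
      expect_equal(ours, unname(ref), tolerance = 1e-12)
    }
  })
})

test_that("time-dependent ROC is exact for a separating marker", {
  tm <- c(1, 2, 3, 20, 25, 30); ev <- c(1, 1, 1, 0, 0, 0)
  marker <- c(0.1, 0.2, 0.15, 0.9, 0.8, 0.95)
  roc <- time_dependent_roc(marker, tm, ev, 12)
  expect_equal(roc$auc, 1)
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)
})

test_that("a 6-patient toy AUC equals the Mann-Whitney pair count", {
  tm <- c(2, 5, 8, 20, 30, 40); ev <- c(1, 1, 1, 0, 0, 0)
  marker <- c(0.2, 0.7, 0.3, 0.5, 0.8, 0.9)
  roc <- time_dependent_roc(marker, tm, ev, 12)
  expect_equal(roc$auc, oracle_time_auc(marker, tm, ev, 12))
  expect_equal(roc$auc, 8 / 9)   # correctly ordered (case < control) pairs
})

test_that("ROC matches the pair-count oracle on random small samples", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      n <- sample(12:30, 1)
      tm <- rexp(n, 1 / 12)
      ev <- rbinom(n, 1, 0.7)
      marker <- round(runif(n), 2)
      h0 <- 10
      if (sum(tm <= h0 & ev == 1) == 0 || sum(tm > h0) == 0) next
      roc <- time_dependent_roc(marker, tm, ev, h0)
      expect_equal(roc$auc, oracle_time_auc(marker, tm, ev, h0),
                   tolerance = 1e-12)
    }
  })
})

test_that("a null marker gives chance-level AUC at n = 2000", {
  withr::with_seed(29, {
    tm <- rexp(2000, 1 / 12); ev <- rbinom(2000, 1, 0.8)
    marker <- runif(2000)
  })
  roc <- time_dependent_roc(marker, tm, ev, 12)
  expect_gte(roc$auc, 0.45)
  expect_lte(roc$auc, 0.55)
})

test_that("AUC is invariant to the monotone hazard-to-survival transform", {
  sim <- simulate_ph(150, beta = 1, seed = 31)
  h <- sim$eta
  s12 <- 0.8^exp(h)   # any fixed S0(12) in (0,1)
  r1 <- time_dependent_roc(s12, sim$time, sim$event, 12)
  r2 <- time_dependent_roc(-h, sim$time, sim$event, 12)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
})

test_that("errors name the horizon when a class is empty", {
  tm <- c(20, 25, 30); ev <- c(0, 0, 0)
  expect_error(time_dependent_roc(runif(3), tm, ev, 3), "3 months")
})

test_that("log-rank agrees with manual risk-table arithmetic", {
  tm <- c(1, 4, 6, 2, 5, 7)
  ev <- c(1, 1, 0, 1, 1, 1)
  grp <- c("A", "A", "A", "B", "B", "B")
  sd0 <- survival::survdiff(survival::Surv(tm, ev) ~ grp)
  # hand-computed: O_A = 2, E_A = 1/2 + 2/5 + 1/2 + 1/3
  expect_equal(unname(sd0$obs[1] - sd0$exp[1]), 2 - (0.5 + 0.4 + 0.5 + 1 / 3),
               tolerance = 1e-9)
  res <- logrank_test(tm, ev, grp)
  expect_equal(res$statistic, unname(sd0$chisq), tolerance = 1e-12)
})

test_that("identical groups give a null log-rank; power under HR = 3", {
  tm <- rep(c(2, 5, 9, 14), 2); ev <- rep(1, 8)
  grp <- rep(c("A", "B"), each = 4)
  res <- logrank_test(tm, ev, grp)
  expect_lt(res$statistic, 1e-9)
  expect_gt(res$p_value, 0.99)
  # exponential groups with hazard ratio 3 reject at alpha = 0.01
  rejections <- withr::with_seed(37, vapply(1:100, function(i) {
    t1 <- rexp(200, 1); t2 <- rexp(200, 3)
    logrank_test(c(t1, t2), rep(1, 400),
                 rep(c("A", "B"), each = 200))$p_value < 0.01
  }, logical(1)))
  expect_gte(mean(rejections), 0.95)
})

test_that("no events in either group is flagged with p = 1", {
  expect_warning(res <- logrank_test(c(1, 2, 3, 4), rep(0, 4),
                                     c("A", "A", "B", "B")),
                 "no events")
  expect_equal(res$p_value, 1)
})

test_that("bootstrap comparison is null for identical models", {
  sim <- simulate_ph(120, beta = 1, seed = 43)
  s12 <- vapply(c(3, 12, 18, 24), function(h0) 0.8^exp(sim$eta),
                numeric(120))
  bc <- bootstrap_compare(s12, s12, sim$time, sim$event, B = 50, seed = 2)
  expect_true(all(abs(bc$tests$mean_diff) < 1e-12))
  expect_true(all(bc$tests$p_value == 1))
  expect_error(bootstrap_compare(s12, s12, sim$time, sim$event, B = 1),
               "B >= 2")
})

test_that("an informative model separates from noise at every horizon", {
  sim <- simulate_ph(250, beta = 1.2, cmax = 60, seed = 47)
  hz <- c(3, 12, 18, 24)
  good <- vapply(hz, function(h0) {
    exp(-(h0 / 15)^1.4)^exp(sim$eta)
  }, numeric(250))
  noise <- withr::with_seed(49, matrix(runif(250 * 4), 250, 4))
  bc <- bootstrap_compare(good, noise, sim$time, sim$event, hz,
                          B = 200, seed = 3)
  aucs <- dplyr::filter(bc$tests, metric == "auc")
  expect_true(all(aucs$p_value < 0.01))
  expect_true(all(aucs$mean_diff > 0))
})
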