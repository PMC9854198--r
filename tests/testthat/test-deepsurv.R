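test_that("zero-score loss has the closed form (1/n) sum log k", {
  n <- 9
  expect_equal(cox_partial_loss(rep(0, n), seq_len(n), rep(1, n)),
               mean(log(seq_len(n))), tolerance = 1e-12)
  # a single event on its own risk set contributes zero
  expect_equal(cox_partial_loss(1.7, 4, 1), 0)
  expect_error(cox_partial_loss(rnorm(5), rexp(5), rep(0, 5)), "no events")
})

test_that("tied event times follow the Breslow convention", {
  # two tied events share the full risk set
  h <- c(0.5, -0.2, 0.1)
  tm <- c(2, 2, 5); ev <- c(1, 1, 0)
  denom <- log(sum(exp(h)))
  expected <- -((h[1] - denom) + (h[2] - denom)) / 2
  expect_equal(cox_partial_loss(h, tm, ev), expected, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(42, {
    for (L in c(0L, 1L, 2L)) {
      hp <- deepsurv_hyperparams(n_hidden_layers = L, nodes_per_layer = 5,
                                 dropout_rate = 0, l2_lambda = 1e-3, seed = 1)
      p <- 4; nb <- 8
      X <- matrix(rnorm(nb * p), nb, p)
      tm <- rexp(nb); ev <- rbinom(nb, 1, 0.8); ev[1] <- 1
      params <- radsurv:::.ds_init_params(p, hp)
      th <- radsurv:::.ds_flatten(params)
      f <- function(v) {
        radsurv:::.ds_loss_grad(radsurv:::.ds_unflatten(v, params), X, tm,
                                ev, hp$l2_lambda)$loss
      }
      g_an <- radsurv:::.ds_flatten(
        radsurv:::.ds_loss_grad(params, X, tm, ev, hp$l2_lambda)$grads)
      g_fd <- vapply(seq_along(th), function(i) {
        e <- th; e[i] <- e[i] + 1e-5; up <- f(e)
        e[i] <- th[i] - 1e-5
        (up - f(e)) / 2e-5
      }, numeric(1))
      expect_lt(max(abs(g_an - g_fd)), 1e-5)
    }
  })
})

test_that("zero hidden layers reduce exactly to a linear Cox predictor", {
  hp <- deepsurv_hyperparams(n_hidden_layers = 0, dropout_rate = 0)
  params <- list(blocks = list(), w_out = c(0.3, -0.7), b_out = 0.2)
  X <- matrix(rnorm(12), 6, 2)
  h <- radsurv:::.ds_forward_eval(params, X, list())
  expect_equal(h, drop(X %*% c(0.3, -0.7)) + 0.2, tolerance = 1e-12)
  # all-zero weights give identically zero output
  params0 <- list(blocks = list(), w_out = c(0, 0), b_out = 0)
  expect_equal(radsurv:::.ds_forward_eval(params0, X, list()), rep(0, 6))
})

test_that("training is deterministic and the loss decreases early", {
  sim <- simulate_ph(120, beta = c(0.9, -0.5), seed = 5)
  hp <- deepsurv_hyperparams(max_epochs = 80, patience = 80, seed = 7)
  m1 <- deepsurv_train(sim$x, sim$time, sim$event, hp)
  m2 <- deepsurv_train(sim$x, sim$time, sim$event, hp)
  expect_identical(radsurv:::.ds_flatten(m1$params),
                   radsurv:::.ds_flatten(m2$params))
  lg <- m1$log
  expect_lt(mean(utils::tail(lg$train_loss, 10)),
            mean(utils::head(lg$train_loss, 3)))
  # duplicate inputs get identical predictions
  h <- predict(m1, sim$x[c(1, 1, 2), ])
  expect_equal(h[1], h[2])
})

test_that("DeepSurv approaches the oracle Cox model on linear PH data", {
  withr::with_seed(7, {
    n <- 300; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    eta <- drop(X %*% c(0.8, -0.5, 0.4, 0, 0))
    tt <- 15 * (-log(runif(n)) / exp(eta))^(1 / 1.4)
    cc <- runif(n, 0, 40)
    tm <- pmin(tt, cc); ev <- as.integer(tt <= cc)
  })
  tr <- 1:210; te <- 211:300
  m <- deepsurv_train(X[tr, ], tm[tr], ev[tr], deepsurv_hyperparams(seed = 5))
  c_ds <- concordance_index(predict(m, X[te, ]), tm[te], ev[te])
  cx <- survival::coxph(survival::Surv(tm[tr], ev[tr]) ~ X[tr, ],
                        ties = "breslow")
  c_cox <- concordance_index(drop(X[te, ] %*% coef(cx)), tm[te], ev[te])
  expect_gte(c_ds, c_cox - 0.03)
})

test_that("no signal is learned from null data", {
  withr::with_seed(9, {
    n <- 300
    X <- matrix(rnorm(n * 5), n, 5)
    tm <- rexp(n, 1 / 12); ev <- rbinom(n, 1, 0.8)
  })
  tr <- 1:210; te <- 211:300
  m <- deepsurv_train(X[tr, ], tm[tr], ev[tr], deepsurv_hyperparams(seed = 3))
  c_ds <- concordance_index(predict(m, X[te, ]), tm[te], ev[te])
  expect_gte(c_ds, 0.45)
  expect_lte(c_ds, 0.55)
})

test_that("training preconditions are enforced", {
  expect_error(deepsurv_train(matrix(rnorm(10), 5), rexp(5), rep(1, 5)),
               "at least 10")
  expect_error(deepsurv_train(matrix(rnorm(48), 12), rexp(12),
                              c(1, 1, rep(0, 10))), "at least 5 events")
})

test_that("grid search returns the singleton and honours the selection rule", {
  sim <- simulate_ph(150, beta = c(0.9, -0.6), seed = 15)
  single <- data.frame(n_hidden_layers = 1, nodes_per_layer = 8,
                       initial_lr = 0.01)
  hp0 <- deepsurv_hyperparams(max_epochs = 60, patience = 60)
  res <- grid_search_deepsurv(sim$x, sim$time, sim$event, single, hp0)
  expect_equal(res$best_hp$nodes_per_layer, 8L)
  grid <- data.frame(n_hidden_layers = c(1, 1),
                     nodes_per_layer = c(4, 16),
                     initial_lr = c(0.01, 0.01))
  res2 <- grid_search_deepsurv(sim$x, sim$time, sim$event, grid, hp0)
  best_c <- max(res2$trace$val_c, na.rm = TRUE)
  sel <- res2$trace$val_c[res2$trace$combo ==
    which(res2$trace$nodes_per_layer == res2$best_hp$nodes_per_layer)]
  expect_equal(max(sel), best_c)
  # on signal-bearing data the selected combination clears chance clearly
  expect_gt(best_c, 0.6)
})
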