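# Feed-forward Cox partial-likelihood network (DeepSurv): hidden blocks of
# fully-connected -> batch-normalisation -> ReLU -> dropout, a single linear
# output node estimating the log relative hazard, trained full-batch with
# Adam under the average negative log partial likelihood (Breslow ties).

.BN_EPS <- 1e-5

#' DeepSurv hyperparameters
#'
#' @param n_hidden_layers number of hidden blocks (0 reduces the network to a
#'   linear Cox predictor).
#' @param nodes_per_layer width of each fully-connected layer.
#' @param initial_lr initial Adam learning rate.
#' @param lr_decay per-epoch decay: `lr = initial_lr / (1 + lr_decay * (epoch - 1))`.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param l2_lambda L2 penalty on fully-connected weights.
#' @param max_epochs,patience epoch budget and early-stopping patience on the
#'   inner-validation loss.
#' @param seed seed for initialisation, the inner split and dropout.
#' @return object of class `deepsurv_hyperparams`.
#' @export
deepsurv_hyperparams <- function(n_hidden_layers = 1, nodes_per_layer = 32,
                                 initial_lr = 0.01, lr_decay = 0.01,
                                 dropout_rate = 0.4, l2_lambda = 1e-4,
                                 max_epochs = 500, patience = 50, seed = 1L) {
  stopifnot(n_hidden_layers >= 0, nodes_per_layer >= 1,
            initial_lr > 0, lr_decay >= 0,
            dropout_rate >= 0, dropout_rate < 1, l2_lambda >= 0,
            max_epochs >= 1, patience >= 1)
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 nodes_per_layer = as.integer(nodes_per_layer),
                 initial_lr = initial_lr, lr_decay = lr_decay,
                 dropout_rate = dropout_rate, l2_lambda = l2_lambda,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "deepsurv_hyperparams")
}

# ---- loss -----------------------------------------------------------------

# risk-set bookkeeping shared by loss and gradient; h, time, event aligned
.cox_risk_terms <- function(h, time, event) {
  ord <- order(time)
  ts <- time[ord]; hs <- h[ord]; es <- event[ord]
  M <- max(hs)
  eh <- exp(hs - M)
  revcs <- rev(cumsum(rev(eh)))
  # tie groups: risk set of a time starts at the first index of its group
  first_idx <- match(ts, ts)                       # first occurrence (sorted)
  last_idx <- rev(length(ts) + 1L - match(rev(ts), rev(ts)))
  S <- revcs[first_idx]
  list(ord = ord, ts = ts, hs = hs, es = es, M = M, eh = eh, S = S,
       last_idx = last_idx)
}

#' Average negative log Cox partial likelihood
#'
#' `L = -(1/N_E) sum_events [h_i - log sum_{T_j >= T_i} exp(h_j)]` with the
#' Breslow convention for tied event times, numerically stabilised by a
#' max-shift inside the log-sum-exp, plus an optional L2 penalty
#' `l2_lambda * sum(weights^2)`.
#'
#' @param h per-patient log relative hazards.
#' @param time,event outcome vectors; at least one event required.
#' @param l2_lambda penalty coefficient.
#' @param weights numeric vector of penalised weights (e.g. the network's
#'   fully-connected weights).
#' @return scalar loss.
#' @export
cox_partial_loss <- function(h, time, event, l2_lambda = 0, weights = NULL) {
  ne <- sum(event)
  if (ne < 1) stop("no events: partial likelihood undefined", call. = FALSE)
  rt <- .cox_risk_terms(h, time, event)
  nll <- -sum((rt$hs - (rt$M + log(rt$S)))[rt$es == 1]) / ne
  pen <- if (!is.null(weights)) l2_lambda * sum(weights^2) else 0
  nll + pen
}

# gradient of the (unpenalised) loss with respect to h, original order
.cox_loss_grad_h <- function(h, time, event) {
  ne <- sum(event)
  rt <- .cox_risk_terms(h, time, event)
  contrib <- ifelse(rt$es == 1, 1 / rt$S, 0)
  cum <- cumsum(contrib)[rt$last_idx]     # all event times <= T_i (ties incl.)
  gs <- -(rt$es - rt$eh * cum) / ne
  g <- numeric(length(h))
  g[rt$ord] <- gs
  g
}

# ---- parameters -----------------------------------------------------------

.ds_init_params <- function(p, hp) {
  blocks <- list()
  d <- p
  if (hp$n_hidden_layers > 0) {
    for (b in seq_len(hp$n_hidden_layers)) {
      m <- hp$nodes_per_layer
      blocks[[b]] <- list(
        W = matrix(rnorm(m * d, sd = sqrt(2 / d)), m, d),
        b = rep(0, m),
        gamma = rep(1, m), beta = rep(0, m))
      d <- m
    }
  }
  list(blocks = blocks,
       w_out = rnorm(d, sd = sqrt(1 / d)),
       b_out = 0)
}

.ds_flatten <- function(params) unlist(params, use.names = FALSE)

.ds_unflatten <- function(vec, skeleton) utils::relist(vec, skeleton)

# ---- forward / backward ---------------------------------------------------

# training-mode forward with caches; masks: list of dropout keep-masks.
# Block order: fully-connected -> batch-norm -> ReLU -> dropout.
.ds_forward_train <- function(params, X, masks = NULL, keep = 1) {
  n <- nrow(X)
  Z <- X
  caches <- list()
  for (b in seq_along(params$blocks)) {
    pb <- params$blocks[[b]]
    Fc <- Z %*% t(pb$W) + matrix(pb$b, n, length(pb$b), byrow = TRUE)
    mu <- colMeans(Fc)
    va <- colMeans(Fc^2) - mu^2
    xhat <- sweep(sweep(Fc, 2, mu), 2, sqrt(va + .BN_EPS), "/")
    H <- sweep(sweep(xhat, 2, pb$gamma, "*"), 2, pb$beta, "+")
    Rl <- pmax(H, 0)
    if (!is.null(masks)) {
      D <- Rl * masks[[b]] / keep
    } else {
      D <- Rl
    }
    caches[[b]] <- list(Z = Z, mu = mu, va = va, xhat = xhat, H = H,
                        Rl = Rl, D = D)
    Z <- D
  }
  h <- drop(Z %*% params$w_out + params$b_out)
  list(h = h, top = Z, caches = caches)
}

# evaluation-mode forward using stored batch-norm statistics, dropout off
.ds_forward_eval <- function(params, X, bn_stats) {
  n <- nrow(X)
  Z <- X
  for (b in seq_along(params$blocks)) {
    pb <- params$blocks[[b]]
    st <- bn_stats[[b]]
    Fc <- Z %*% t(pb$W) + matrix(pb$b, n, length(pb$b), byrow = TRUE)
    xhat <- sweep(sweep(Fc, 2, st$mu), 2, sqrt(st$va + .BN_EPS), "/")
    H <- sweep(sweep(xhat, 2, pb$gamma, "*"), 2, pb$beta, "+")
    Z <- pmax(H, 0)
  }
  drop(Z %*% params$w_out + params$b_out)
}

# loss + full gradient (training mode); returns list(loss, grads)
.ds_loss_grad <- function(params, X, time, event, l2, masks = NULL, keep = 1) {
  n <- nrow(X)
  fw <- .ds_forward_train(params, X, masks, keep)
  wts <- c(unlist(lapply(params$blocks, function(b) b$W)), params$w_out)
  loss <- cox_partial_loss(fw$h, time, event, l2, wts)
  dh <- .cox_loss_grad_h(fw$h, time, event)

  g <- params  # same shape
  g$w_out <- drop(crossprod(fw$top, dh)) + 2 * l2 * params$w_out
  g$b_out <- sum(dh)
  dD <- matrix(dh, n, 1) %*% matrix(params$w_out, 1)   # n x d_L
  for (b in rev(seq_along(params$blocks))) {
    pb <- params$blocks[[b]]
    ca <- fw$caches[[b]]
    dRl <- if (!is.null(masks)) dD * masks[[b]] / keep else dD
    dH <- dRl * (ca$H > 0)
    g$blocks[[b]]$gamma <- colSums(dH * ca$xhat)
    g$blocks[[b]]$beta <- colSums(dH)
    dxhat <- sweep(dH, 2, pb$gamma, "*")
    sd1 <- colSums(dxhat)
    sd2 <- colSums(dxhat * ca$xhat)
    dF <- sweep(n * dxhat, 2, sd1) - sweep(ca$xhat, 2, sd2, "*")
    dF <- sweep(dF, 2, n * sqrt(ca$va + .BN_EPS), "/")
    g$blocks[[b]]$W <- crossprod(dF, ca$Z) + 2 * l2 * pb$W
    g$blocks[[b]]$b <- colSums(dF)
    dD <- dF %*% pb$W
  }
  list(loss = loss, grads = g, h = fw$h,
       bn_stats = lapply(fw$caches, function(c0) list(mu = c0$mu, va = c0$va)))
}

# ---- training -------------------------------------------------------------

#' Train a DeepSurv model
#'
#' Full-batch Adam on the average negative log Cox partial likelihood with a
#' per-epoch learning-rate decay `lr0 / (1 + decay * (epoch - 1))`. An inner
#' 80/20 split of the training data (stratified by event) drives early
#' stopping on the validation loss; the best-epoch weights are restored.
#' Batch-normalisation statistics for evaluation are recomputed on the full
#' training batch under the restored weights. Fully deterministic given
#' `hp$seed`.
#'
#' @param x matrix or data frame of features (standardized internally; the
#'   scaler is stored in the model).
#' @param time,event training outcome; needs >= 10 patients and >= 5 events.
#' @param hp a [deepsurv_hyperparams()].
#' @return object of class `deepsurv_model` with elements `params`, `scaler`,
#'   `hp`, `bn_stats`, `baseline` (Breslow baseline survival tibble),
#'   `log` (per-epoch losses), `val_idx` (inner-validation rows).
#' @export
deepsurv_train <- function(x, time, event, hp = deepsurv_hyperparams()) {
  X0 <- as.matrix(x)
  storage.mode(X0) <- "double"
  n <- nrow(X0)
  if (n < 10) stop("need at least 10 patients", call. = FALSE)
  if (sum(event) < 5) stop("need at least 5 events", call. = FALSE)
  ctr <- colMeans(X0)
  scl <- apply(X0, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  X <- sweep(sweep(X0, 2, ctr), 2, scl, "/")
  keep <- 1 - hp$dropout_rate

  out <- withr::with_seed(hp$seed, {
    # inner validation split, stratified by event
    idx1 <- which(event == 1)
    idx0 <- which(event == 0)
    val <- c(if (length(idx1) > 1) sample(idx1, max(1, round(0.2 * length(idx1)))),
             if (length(idx0) > 1) sample(idx0, round(0.2 * length(idx0))))
    val <- sort(unique(val))
    tr <- setdiff(seq_len(n), val)
    if (sum(event[tr]) < 1 || sum(event[val]) < 1) {
      val <- utils::head(order(-event), max(2, round(0.2 * n)))
      tr <- setdiff(seq_len(n), val)
    }
    params <- .ds_init_params(ncol(X), hp)
    skel <- params
    theta <- .ds_flatten(params)
    mAd <- numeric(length(theta)); vAd <- numeric(length(theta))
    best <- list(loss = Inf, theta = theta, epoch = 0L)
    log <- vector("list", hp$max_epochs)
    ntr <- length(tr)
    for (epoch in seq_len(hp$max_epochs)) {
      lr <- hp$initial_lr / (1 + hp$lr_decay * (epoch - 1))
      masks <- NULL
      if (hp$dropout_rate > 0 && hp$n_hidden_layers > 0) {
        masks <- lapply(seq_len(hp$n_hidden_layers), function(b) {
          matrix(rbinom(ntr * hp$nodes_per_layer, 1, keep),
                 ntr, hp$nodes_per_layer)
        })
      }
      params <- .ds_unflatten(theta, skel)
      lg <- .ds_loss_grad(params, X[tr, , drop = FALSE], time[tr], event[tr],
                          hp$l2_lambda, masks, keep)
      if (!is.finite(lg$loss)) {
        stop(sprintf("training diverged (loss not finite) at epoch %d, lr %.3g",
                     epoch, lr), call. = FALSE)
      }
      gvec <- .ds_flatten(lg$grads)
      mAd <- 0.9 * mAd + 0.1 * gvec
      vAd <- 0.999 * vAd + 0.001 * gvec^2
      mhat <- mAd / (1 - 0.9^epoch)
      vhat <- vAd / (1 - 0.999^epoch)
      theta <- theta - lr * mhat / (sqrt(vhat) + 1e-8)
      # validation loss in evaluation mode with this epoch's batch statistics
      params <- .ds_unflatten(theta, skel)
      fw_tr <- .ds_forward_train(params, X[tr, , drop = FALSE])
      bn <- lapply(fw_tr$caches, function(c0) list(mu = c0$mu, va = c0$va))
      hv <- .ds_forward_eval(params, X[val, , drop = FALSE], bn)
      vloss <- tryCatch(cox_partial_loss(hv, time[val], event[val]),
                        error = function(e) Inf)
      log[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                     train_loss = lg$loss, val_loss = vloss)
      if (is.finite(vloss) && vloss < best$loss - 1e-9) {
        best <- list(loss = vloss, theta = theta, epoch = epoch)
      }
      if (epoch - best$epoch >= hp$patience) break
    }
    list(theta = best$theta, log = dplyr::bind_rows(log), val = val,
         skel = skel, best_epoch = best$epoch)
  })

  params <- .ds_unflatten(out$theta, out$skel)
  fw <- .ds_forward_train(params, X)
  bn_stats <- lapply(fw$caches, function(c0) list(mu = c0$mu, va = c0$va))
  model <- structure(list(params = params, hp = hp,
                          scaler = list(center = ctr, scale = scl),
                          feature_names = colnames(X0),
                          bn_stats = bn_stats,
                          log = out$log, val_idx = out$val,
                          best_epoch = out$best_epoch,
                          n_train = n, n_events = sum(event)),
                     class = "deepsurv_model")
  h_train <- .ds_forward_eval(params, X, bn_stats)
  model$baseline <- breslow_baseline(h_train, time, event)
  model
}

#' @export
print.deepsurv_model <- function(x, ...) {
  cat(sprintf(
    "<deepsurv_model> %d feature(s), %d hidden layer(s) x %d nodes, best epoch %d\n",
    length(x$scaler$center), x$hp$n_hidden_layers, x$hp$nodes_per_layer,
    x$best_epoch))
  invisible(x)
}

#' Predict from a DeepSurv model
#'
#' @param object a `deepsurv_model`.
#' @param newdata matrix or data frame with the model's feature columns.
#' @param type `"lp"` for the log relative hazard, `"survival"` for
#'   personalized survival probabilities on `times`.
#' @param times evaluation grid (months) for `type = "survival"`.
#' @param ... unused.
#' @return for `"lp"` a numeric vector; for `"survival"` a tibble with
#'   `.row`, `time`, `surv`.
#' @export
predict.deepsurv_model <- function(object, newdata, type = c("lp", "survival"),
                                   times = seq(0, 30, by = 1), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    if (!is.null(colnames(X)) &&
        all(object$feature_names %in% colnames(X))) {
      X <- X[, object$feature_names, drop = FALSE]
    }
  }
  if (ncol(X) != length(object$scaler$center)) {
    stop(sprintf("expected %d feature columns, got %d",
                 length(object$scaler$center), ncol(X)), call. = FALSE)
  }
  storage.mode(X) <- "double"
  Xs <- sweep(sweep(X, 2, object$scaler$center), 2, object$scaler$scale, "/")
  h <- .ds_forward_eval(object$params, Xs, object$bn_stats)
  if (type == "lp") return(h)
  predict_survival_curve(object, h = h, times = times)
}
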