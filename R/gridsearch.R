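# Hyperparameter grid search for the DeepSurv network.

#' Default hyperparameter search grid
#'
#' Spans the named tuning axes of the network: hidden layers, nodes per
#' layer, initial learning rate, learning-rate decay and dropout rate.
#'
#' @return data frame of combinations.
#' @export
default_deepsurv_grid <- function() {
  expand.grid(n_hidden_layers = c(1, 2),
              nodes_per_layer = c(16, 32, 64),
              initial_lr = c(0.01, 0.001),
              lr_decay = c(0.01, 0.001),
              dropout_rate = c(0.2, 0.4))
}

#' Grid search over DeepSurv hyperparameters
#'
#' Trains each combination (sharing the seed, hence the inner
#' train/validation split) and selects the combination with the highest
#' inner-validation C-index. Ties break toward fewer parameters, then lower
#' initial learning rate.
#'
#' @param x,time,event training data.
#' @param grid data frame of hyperparameter combinations (columns matching
#'   [deepsurv_hyperparams()] arguments).
#' @param base_hp baseline hyperparameters supplying unlisted fields.
#' @return list: `best_hp` (a `deepsurv_hyperparams`), `trace` tibble with
#'   per-combination validation C-index and parameter count, `best_model`.
#' @export
grid_search_deepsurv <- function(x, time, event, grid = default_deepsurv_grid(),
                                 base_hp = deepsurv_hyperparams()) {
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  rows <- vector("list", nrow(grid))
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hp <- base_hp
    for (nm in names(grid)) hp[[nm]] <- grid[[nm]][i]
    hp <- do.call(deepsurv_hyperparams, hp[setdiff(names(hp), character(0))])
    res <- tryCatch({
      m <- deepsurv_train(x, time, event, hp)
      val <- m$val_idx
      hv <- predict(m, as.matrix(x)[val, , drop = FALSE])
      cv <- concordance_index(hv, time[val], event[val])
      list(model = m, c = cv, err = NA_character_)
    }, error = function(e) list(model = NULL, c = NA_real_,
                                err = conditionMessage(e)))
    models[[i]] <- res$model
    npar <- if (!is.null(res$model)) length(.ds_flatten(res$model$params)) else NA
    rows[[i]] <- tibble::tibble(combo = i, val_c = res$c, n_params = npar,
                                error = res$err,
                                dplyr::as_tibble(grid[i, , drop = FALSE]))
  }
  trace <- dplyr::bind_rows(rows)
  if (all(is.na(trace$val_c))) {
    stop(paste0("all grid combinations failed:\n",
                paste(utils::capture.output(print(trace)), collapse = "\n")),
         call. = FALSE)
  }
  lrcol <- if ("initial_lr" %in% names(trace)) trace$initial_lr else rep(0, nrow(trace))
  ord <- order(-trace$val_c, trace$n_params, lrcol)
  best <- ord[1]
  hp <- base_hp
  for (nm in names(grid)) hp[[nm]] <- grid[[nm]][best]
  best_hp <- do.call(deepsurv_hyperparams,
                     hp[setdiff(names(hp), character(0))])
  list(best_hp = best_hp, trace = trace, best_model = models[[best]])
}
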