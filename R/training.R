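#' Multitask loss: weighted MSE over compartments plus spike BCE
#'
#' Computes
#' `w_spike * BCEwithLogits(spike_logit, y_spike) +
#'  sum_i w_i * MSE(voltage_i, y_i)`
#' where the sum runs over the N compartment tasks and every per-task
#' component is a mean over the batch. The per-task vector (compartments
#' first, spike last) is returned alongside the scalar so that dynamic task
#' weighting can consume it. The binary cross-entropy is evaluated in its
#' numerically stable logit form.
#'
#' @param pred list with `voltage` `[N x B]` and `spike_logit` (length B),
#'   as returned by [forward_mtl()].
#' @param target list with `y_voltage` `[N x B]` and `y_spike` (length B,
#'   values in `{0, 1}`).
#' @param weights optional list with `w_comp` (length N) and `w_spike`
#'   (scalar); defaults to all ones.
#' @return list with `total` (scalar), `per_task` (length N + 1, unweighted
#'   task losses), `weights` (as used).
#' @export
multitask_loss <- function(pred, target, weights = NULL) {
  v <- pred$voltage
  z <- pred$spike_logit
  yv <- target$y_voltage
  ys <- target$y_spike
  if (!all(dim(v) == dim(yv)))
    stop("prediction/target voltage shapes differ")
  if (length(z) != length(ys))
    stop("prediction/target spike lengths differ")
  if (anyNA(v) || anyNA(z)) {
    bad <- if (anyNA(v)) which(apply(is.na(v), 1, any))[1] else length(ys) + 1L
    stop("NaN in predictions (first affected task ", bad, ")")
  }
  N <- nrow(v)
  if (is.null(weights)) weights <- list(w_comp = rep(1, N), w_spike = 1)
  stopifnot(length(weights$w_comp) == N, all(weights$w_comp >= 0),
            weights$w_spike >= 0)
  mse <- rowMeans((v - yv)^2)
  bce <- mean(pmax(z, 0) - z * ys + log1p(exp(-abs(z))))
  per_task <- c(mse, bce)
  total <- sum(weights$w_comp * mse) + weights$w_spike * bce
  list(total = total, per_task = per_task, weights = weights)
}

#' Loss-balanced task weighting (LBTW) state
#'
#' LBTW recomputes task weights every batch from the ratio of the current
#' per-task loss to the per-task loss recorded at the first batch of the
#' epoch: `w_task = (L_task,B / L_task,0)^alpha`. At `alpha = 0` the
#' weights are identically 1 and training reduces to standard multitask
#' learning. Initial losses are re-captured at the start of every epoch.
#'
#' @param alpha balancing strength in `[0, 1]`.
#' @return an `nd_lbtw` state environment; see [lbtw_weights()].
#' @export
lbtw_state <- function(alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  st <- new.env(parent = emptyenv())
  st$alpha <- alpha
  st$initial <- NULL
  st$batch <- 0L
  class(st) <- "nd_lbtw"
  st
}

#' @rdname lbtw_state
#' @param state an `nd_lbtw` state.
#' @export
lbtw_new_epoch <- function(state) {
  state$initial <- NULL
  state$batch <- 0L
  invisible(state)
}

#' Compute LBTW weights for the current batch
#'
#' The first call of an epoch (batch 0) stores the per-task losses as the
#' epoch's initials and returns unit weights. Tasks whose initial loss is
#' zero (degenerate tasks) keep weight 1.
#'
#' @param state an `nd_lbtw` state.
#' @param current_losses per-task loss vector (compartments first, spike
#'   last), as returned in `per_task` by [multitask_loss()].
#' @return list with `w_comp` and `w_spike` in the layout accepted by
#'   [multitask_loss()].
#' @export
lbtw_weights <- function(state, current_losses) {
  stopifnot(inherits(state, "nd_lbtw"))
  n <- length(current_losses)
  if (state$batch == 0L || is.null(state$initial)) {
    state$initial <- current_losses
    state$batch <- 1L
    w <- rep(1, n)
  } else {
    w <- rep(1, n)
    ok <- state$initial > 0
    w[ok] <- (current_losses[ok] / state$initial[ok])^state$alpha
    state$batch <- state$batch + 1L
  }
  list(w_comp = w[-n], w_spike = w[n])
}

#' Train a multitask model
#'
#' Adam optimization of the multitask loss with optional loss-balanced task
#' weighting, per-epoch validation, and best-validation checkpointing. The
#' run is fully seeded (batch shuffling, dropout); gradients are clipped at
#' a global norm of `clip_norm` for stability. The spike-task weight can be
#' scaled by a constant importance factor `gamma` (default 1).
#'
#' @param model an `nd_mtl_model` (modified in place; also returned).
#' @param dataset an `nd_dataset` from [make_dataset()].
#' @param epochs number of epochs.
#' @param batch_size minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param lbtw_alpha `NULL` for unit task weights, otherwise the LBTW
#'   alpha in `[0, 1]`.
#' @param gamma constant multiplier on the spike-task weight (default 1).
#' @param clip_norm global gradient-norm clip (default 5).
#' @param seed integer seed for shuffling and dropout.
#' @param checkpoint_path optional path; the best-validation parameters are
#'   written there with [save_checkpoint()].
#' @param verbose print one line per epoch.
#' @return an `nd_training_history`: list with `history` data frame
#'   (epoch, train_loss, val_loss, seconds), `per_task_val` matrix, the
#'   `best_epoch`, `best_state` parameter list, and the trained `model`
#'   (restored to its best-validation weights).
#' @export
train <- function(model, dataset, epochs = 10, batch_size = 32, lr = 1e-3,
                  lbtw_alpha = NULL, gamma = 1, clip_norm = 5, seed = 1L,
                  checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "nd_mtl_model"), inherits(dataset, "nd_dataset"))
  layers <- param_layers(model)
  adam_init(layers)
  lbtw <- if (!is.null(lbtw_alpha)) lbtw_state(lbtw_alpha) else NULL

  train_w <- prepare_windows(dataset$train, dataset$standardizer)
  n_train <- length(train_w$offsets)
  stopifnot(n_train >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), seconds = numeric(0))
  per_task_val <- NULL
  best_val <- Inf
  best_epoch <- NA_integer_
  best_state <- NULL
  step_t <- 0L

  for (ep in seq_len(epochs)) {
    t0 <- proc.time()[["elapsed"]]
    if (!is.null(lbtw)) lbtw_new_epoch(lbtw)
    ord <- sample.int(n_train)
    ep_loss <- 0
    n_batches <- 0L
    for (b0 in seq(1L, n_train, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n_train)]
      batch <- get_batch(train_w, dataset$standardizer, idx)
      out <- forward_mtl(model, batch$x, train = TRUE, want_cache = TRUE)
      ls0 <- multitask_loss(out, batch)
      w <- if (!is.null(lbtw)) lbtw_weights(lbtw, ls0$per_task)
           else list(w_comp = rep(1, model$config$n_comp), w_spike = 1)
      w$w_spike <- gamma * w$w_spike
      ls <- multitask_loss(out, batch, w)
      if (!is.finite(ls$total))
        stop("training diverged at epoch ", ep, " (non-finite loss)")
      B <- length(idx)
      dv <- (2 / B) * (out$voltage - batch$y_voltage) * w$w_comp
      dz <- (w$w_spike / B) *
        (1 / (1 + exp(-out$spike_logit)) - batch$y_spike)
      zero_grads(layers)
      backward_mtl(model, batch$x, out$cache, dv, dz)
      clip_grads(layers, clip_norm)
      step_t <- step_t + 1L
      adam_step(layers, lr, step_t)
      ep_loss <- ep_loss + ls$total
      n_batches <- n_batches + 1L
    }
    ev <- evaluate(model, dataset, split = "validation",
                   batch_size = batch_size)
    hist <- rbind(hist, data.frame(
      epoch = ep, train_loss = ep_loss / n_batches, val_loss = ev$total_loss,
      seconds = proc.time()[["elapsed"]] - t0))
    per_task_val <- rbind(per_task_val, ev$per_task)
    if (ev$total_loss < best_val) {
      best_val <- ev$total_loss
      best_epoch <- ep
      best_state <- get_param_state(model)
    }
    if (verbose)
      message(sprintf("epoch %d: train %.4f  val %.4f", ep,
                      ep_loss / n_batches, ev$total_loss))
  }
  set_param_state(model, best_state)
  if (!is.null(checkpoint_path))
    save_checkpoint(model, checkpoint_path, standardizer = dataset$standardizer,
                    history = hist, seed = seed)
  structure(list(history = hist, per_task_val = per_task_val,
                 best_epoch = best_epoch, best_val_loss = best_val,
                 best_state = best_state, model = model, seed = seed),
            class = "nd_training_history")
}

#' @export
print.nd_training_history <- function(x, ...) {
  cat("<nd_training_history> ", nrow(x$history), " epochs, best epoch ",
      x$best_epoch, " (val loss ", signif(x$best_val_loss, 4), ")\n",
      sep = "")
  invisible(x)
}

#' Evaluate a model on a dataset split
#'
#' Reports the unit-weight multitask loss, the per-task loss vector, and
#' millivolt-scale error summaries obtained by inverting the z-scoring:
#' the pooled voltage RMSE (mV), the pooled standard deviation of the
#' target voltages (mV), their ratio, and the spike-task BCE.
#'
#' @param model an `nd_mtl_model`.
#' @param dataset an `nd_dataset`.
#' @param split `"validation"` (default) or `"train"`.
#' @param batch_size evaluation batch size.
#' @return list with `total_loss`, `per_task` (length N + 1),
#'   `rmse_mV`, `data_sd_mV`, `rmse_over_sd`, `spike_bce`, `n_samples`.
#' @export
evaluate <- function(model, dataset, split = c("validation", "train"),
                     batch_size = 64) {
  split <- match.arg(split)
  w <- prepare_windows(dataset[[split]], dataset$standardizer)
  n <- length(w$offsets)
  if (n == 0L) stop("empty ", split, " split")
  N <- model$config$n_comp
  sse <- rep(0, N + 1L)
  sq_mv <- 0
  sum_mv <- 0
  sum_sq_mv <- 0
  count <- 0
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    batch <- get_batch(w, dataset$standardizer, idx)
    out <- forward_mtl(model, batch$x, train = FALSE)
    B <- length(idx)
    sse[seq_len(N)] <- sse[seq_len(N)] +
      rowSums((out$voltage - batch$y_voltage)^2)
    z <- out$spike_logit
    sse[N + 1L] <- sse[N + 1L] +
      sum(pmax(z, 0) - z * batch$y_spike + log1p(exp(-abs(z))))
    pred_mv <- apply_standardizer(out$voltage, dataset$standardizer,
                                  invert = TRUE, per_row = FALSE)
    targ_mv <- apply_standardizer(batch$y_voltage, dataset$standardizer,
                                  invert = TRUE, per_row = FALSE)
    sq_mv <- sq_mv + sum((pred_mv - targ_mv)^2)
    sum_mv <- sum_mv + sum(targ_mv)
    sum_sq_mv <- sum_sq_mv + sum(targ_mv^2)
    count <- count + N * B
  }
  per_task <- sse / n
  rmse <- sqrt(sq_mv / count)
  data_sd <- sqrt(sum_sq_mv / count - (sum_mv / count)^2)
  list(total_loss = sum(per_task), per_task = per_task,
       rmse_mV = rmse, data_sd_mV = data_sd,
       rmse_over_sd = rmse / data_sd,
       spike_bce = per_task[N + 1L], n_samples = n)
}

# cache the z-scored voltage matrix inside a windows object so repeated
# get_batch calls do not re-standardize the whole trace
prepare_windows <- function(windows, standardizer) {
  if (!is.null(windows$zvolt)) return(windows)
  windows$zvolt <- apply_standardizer(windows$voltage, standardizer)
  windows
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the model configuration, kind, exclusivity mask,
#' all parameter tensors, the training standardizer, the training history,
#' and the seed and config hash that produced it.
#'
#' @param model an `nd_mtl_model`.
#' @param path file path (`.rds`).
#' @param standardizer optional `nd_standardizer` to embed.
#' @param history optional history data frame to embed.
#' @param seed seed to record.
#' @return `load_checkpoint` returns a list with the rebuilt `model` and
#'   any embedded `standardizer`/`history`.
#' @export
save_checkpoint <- function(model, path, standardizer = NULL,
                            history = NULL, seed = NULL) {
  stopifnot(inherits(model, "nd_mtl_model"))
  obj <- list(kind = model$kind, config = unclass(model$config),
              mask = model$mask, state = get_param_state(model),
              standardizer = standardizer, history = history, seed = seed,
              config_hash = nd_hash(unclass(model$config)))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$config, class = "nd_model_config")
  model <- switch(obj$kind,
                  hard = build_hard_sharing(cfg),
                  mmoe = build_mmoe(cfg),
                  mmoeex = build_mmoeex(cfg),
                  stop("unknown model kind: ", obj$kind))
  if (!is.null(obj$mask)) model$mask <- obj$mask
  set_param_state(model, obj$state)
  list(model = model, standardizer = obj$standardizer,
       history = obj$history, seed = obj$seed,
       config_hash = obj$config_hash)
}
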