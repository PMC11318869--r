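#' Multitask model configuration
#'
#' One configuration drives all three architectures. Tasks are the N
#' compartment-voltage regressions plus one binary somatic-spike task (the
#' last task, whose tower emits a logit). Towers are three-layer ELU
#' feed-forward networks reading the flattened full-sequence TCN output
#' (`last level channels x history` features, 8 x 100 = 800 at the default
#' TCN size); hard-sharing towers use 25 hidden units, soft-sharing towers
#' 10. Soft models use `n_experts` expert TCNs plus one extra TCN as a
#' compressor module whose flattened output feeds every gate, which fixes
#' the gate parameter count regardless of the raw input size.
#'
#' @param n_comp number of compartments N (tasks = N + 1).
#' @param history history window length in bins (default 100).
#' @param level_channels,kernel_size,dropout TCN hyperparameters shared by
#'   bottom, experts and compressor (defaults 32/16/8, 10, 0.2).
#' @param n_experts number of experts in the soft models (default 5).
#' @param tower_hidden_hard,tower_hidden_soft tower width per family.
#' @param alpha_exclusivity exclusivity fraction for the MMoEEx variant, in
#'   `[0, 1]`: `ceiling(alpha * n_experts)` experts are made exclusive to
#'   one uniformly drawn task each (default 0.2).
#' @param seed integer seed used for weight initialization and (for
#'   MMoEEx) the frozen exclusivity mask.
#' @return an `nd_model_config` list.
#' @export
model_config <- function(n_comp, history = 100,
                         level_channels = c(32, 16, 8), kernel_size = 10,
                         dropout = 0.2, n_experts = 5,
                         tower_hidden_hard = 25, tower_hidden_soft = 10,
                         alpha_exclusivity = 0.2, seed = 1L) {
  stopifnot(n_comp >= 1, n_experts >= 1,
            alpha_exclusivity >= 0, alpha_exclusivity <= 1)
  structure(list(
    n_comp = as.integer(n_comp),
    n_tasks = as.integer(n_comp + 1L),
    history = as.integer(history),
    in_channels = as.integer(3L * n_comp),
    level_channels = as.integer(level_channels),
    kernel_size = as.integer(kernel_size),
    dropout = dropout,
    n_experts = as.integer(n_experts),
    tower_hidden_hard = as.integer(tower_hidden_hard),
    tower_hidden_soft = as.integer(tower_hidden_soft),
    alpha_exclusivity = alpha_exclusivity,
    feature_dim = as.integer(utils::tail(level_channels, 1) * history),
    seed = as.integer(seed)), class = "nd_model_config")
}

new_tower <- function(n_in, hidden) {
  list(l1 = new_linear(n_in, hidden),
       l2 = new_linear(hidden, hidden),
       l3 = new_linear(hidden, 1L))
}

tower_forward <- function(tw, feat) {
  f1 <- linear_forward(tw$l1, feat)
  a1 <- elu_forward(f1$out)
  f2 <- linear_forward(tw$l2, a1$out)
  a2 <- elu_forward(f2$out)
  f3 <- linear_forward(tw$l3, a2$out)
  list(out = f3$out,
       cache = list(f1 = f1$cache, a1 = a1$cache, f2 = f2$cache,
                    a2 = a2$cache, f3 = f3$cache))
}

tower_backward <- function(tw, cache, dout) {
  da2 <- linear_backward(tw$l3, cache$f3, dout)
  df2 <- elu_backward(cache$a2, da2)
  da1 <- linear_backward(tw$l2, cache$f2, df2)
  df1 <- elu_backward(cache$a1, da1)
  linear_backward(tw$l1, cache$f1, df1)
}

#' Build the hard parameter sharing model (MH)
#'
#' A single shared TCN bottom whose flattened full-sequence output feeds
#' one three-layer ELU tower per task (feature_dim -> 25 -> 25 -> 1).
#'
#' @param config an `nd_model_config`.
#' @return an `nd_mtl_model` of kind `"hard"`.
#' @export
build_hard_sharing <- function(config) {
  stopifnot(inherits(config, "nd_model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  tcfg <- tcn_config(config$in_channels, config$level_channels,
                     config$kernel_size, config$dropout)
  bottom <- build_tcn(tcfg)
  towers <- lapply(seq_len(config$n_tasks), function(k)
    new_tower(config$feature_dim, config$tower_hidden_hard))
  structure(list(kind = "hard", config = config,
                 bottom = bottom, towers = towers),
            class = "nd_mtl_model")
}

#' Build the compressor-gated multi-gate mixture-of-experts model (MMoE)
#'
#' `n_experts` expert TCNs plus one compressor TCN. Each task owns a gate,
#' a linear map from the flattened compressor output to expert logits
#' followed by a softmax; the task representation is the gate-weighted sum
#' of the flattened expert outputs and feeds a per-task tower
#' (feature_dim -> 10 -> 10 -> 1).
#'
#' @param config an `nd_model_config`.
#' @return an `nd_mtl_model` of kind `"mmoe"`.
#' @export
build_mmoe <- function(config) {
  build_soft(config, kind = "mmoe")
}

#' Build the mixture-of-experts model with expert exclusivity (MMoEEx)
#'
#' The MMoE structure plus a frozen exclusivity mask drawn once at
#' initialization from the config seed: `ceiling(alpha * n_experts)`
#' experts are each assigned one uniformly chosen task and their gate
#' connections to every other task are fixed at exactly zero for the whole
#' life of the model (training never touches them). With `alpha = 0` the
#' mask is all ones and the model is function-identical to MMoE at equal
#' seeds.
#'
#' @param config an `nd_model_config` (uses `alpha_exclusivity`).
#' @return an `nd_mtl_model` of kind `"mmoeex"` with a `mask`
#'   `[n_tasks x n_experts]` attribute of frozen 0/1 entries.
#' @export
build_mmoeex <- function(config) {
  build_soft(config, kind = "mmoeex")
}

build_soft <- function(config, kind) {
  stopifnot(inherits(config, "nd_model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  tcfg <- tcn_config(config$in_channels, config$level_channels,
                     config$kernel_size, config$dropout)
  experts <- lapply(seq_len(config$n_experts), function(j) build_tcn(tcfg))
  compressor <- build_tcn(tcfg)
  gates <- lapply(seq_len(config$n_tasks), function(k)
    new_linear(config$feature_dim, config$n_experts))
  towers <- lapply(seq_len(config$n_tasks), function(k)
    new_tower(config$feature_dim, config$tower_hidden_soft))
  mask <- matrix(1, config$n_tasks, config$n_experts)
  if (kind == "mmoeex" && config$alpha_exclusivity > 0) {
    n_excl <- ceiling(config$alpha_exclusivity * config$n_experts)
    excl_experts <- sample.int(config$n_experts, n_excl)
    for (j in excl_experts) {
      task_j <- sample.int(config$n_tasks, 1L)
      mask[, j] <- 0
      mask[task_j, j] <- 1
    }
  }
  structure(list(kind = kind, config = config, experts = experts,
                 compressor = compressor, gates = gates, towers = towers,
                 mask = mask),
            class = "nd_mtl_model")
}

#' @export
print.nd_mtl_model <- function(x, ...) {
  cat("<nd_mtl_model> ", x$kind, ": ", x$config$n_tasks, " tasks, ",
      format(count_parameters(x), big.mark = ","),
      " trainable parameters\n", sep = "")
  invisible(x)
}

#' Forward pass of a multitask model
#'
#' All three architectures accept the same input (`[3N x history x batch]`)
#' and return one prediction per task: z-scored next-millisecond membrane
#' potentials for the N compartment tasks and a logit for the somatic-spike
#' task. Evaluation mode (`train = FALSE`) is deterministic.
#'
#' @param model an `nd_mtl_model`.
#' @param x input array `[3N x history x batch]` (matrix promoted to
#'   batch 1).
#' @param train logical; enables dropout.
#' @param want_cache keep activations for the internal backward pass.
#' @return list with `voltage` `[N x batch]`, `spike_logit` (length batch),
#'   and for soft models `gates` `[n_experts x batch x n_tasks]` array;
#'   plus `cache` when requested.
#' @export
forward_mtl <- function(model, x, train = FALSE, want_cache = FALSE) {
  stopifnot(inherits(model, "nd_mtl_model"))
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  cfg <- model$config
  if (dim(x)[1] != cfg$in_channels || dim(x)[2] != cfg$history)
    stop("expected input [", cfg$in_channels, " x ", cfg$history,
         " x batch], got [", paste(dim(x), collapse = " x "), "]")
  B <- dim(x)[3]
  n_tasks <- cfg$n_tasks
  Fd <- cfg$feature_dim

  if (model$kind == "hard") {
    bt <- tcn_forward(model$bottom, x, train = train, want_cache = TRUE)
    feat <- bt$out
    dim(feat) <- c(Fd, B)
    preds <- matrix(0, n_tasks, B)
    tcaches <- vector("list", n_tasks)
    for (k in seq_len(n_tasks)) {
      tf <- tower_forward(model$towers[[k]], feat)
      preds[k, ] <- tf$out
      tcaches[[k]] <- tf$cache
    }
    out <- list(voltage = preds[seq_len(cfg$n_comp), , drop = FALSE],
                spike_logit = preds[n_tasks, ])
    if (want_cache)
      out$cache <- list(bottom = bt$cache, towers = tcaches, B = B)
    return(out)
  }

  # soft models
  E <- cfg$n_experts
  ex_out <- vector("list", E)
  ex_cache <- vector("list", E)
  for (j in seq_len(E)) {
    r <- tcn_forward(model$experts[[j]], x, train = train, want_cache = TRUE)
    f <- r$out
    dim(f) <- c(Fd, B)
    ex_out[[j]] <- f
    ex_cache[[j]] <- r$cache
  }
  cp <- tcn_forward(model$compressor, x, train = train, want_cache = TRUE)
  comp_feat <- cp$out
  dim(comp_feat) <- c(Fd, B)

  preds <- matrix(0, n_tasks, B)
  gates_arr <- array(0, c(E, B, n_tasks))
  gcaches <- vector("list", n_tasks)
  tcaches <- vector("list", n_tasks)
  for (k in seq_len(n_tasks)) {
    lf <- linear_forward(model$gates[[k]], comp_feat)
    logits <- lf$out
    logits[model$mask[k, ] == 0, ] <- -Inf
    g <- softmax_cols(logits)
    mix <- matrix(0, Fd, B)
    for (j in seq_len(E)) {
      if (all(g[j, ] == 0)) next
      mix <- mix + ex_out[[j]] * rep(g[j, ], each = Fd)
    }
    tf <- tower_forward(model$towers[[k]], mix)
    preds[k, ] <- tf$out
    gates_arr[, , k] <- g
    gcaches[[k]] <- list(lin = lf$cache, g = g)
    tcaches[[k]] <- tf$cache
  }
  out <- list(voltage = preds[seq_len(cfg$n_comp), , drop = FALSE],
              spike_logit = preds[n_tasks, ],
              gates = gates_arr)
  if (want_cache)
    out$cache <- list(experts = ex_cache, ex_out = ex_out,
                      compressor = cp$cache, comp_feat = comp_feat,
                      gates = gcaches, towers = tcaches, B = B)
  out
}

# backward pass shared by the training loop; d_voltage [N x B], d_spike [B]
backward_mtl <- function(model, x, cache, d_voltage, d_spike) {
  cfg <- model$config
  B <- cache$B
  Fd <- cfg$feature_dim
  n_tasks <- cfg$n_tasks
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  dpred <- rbind(d_voltage, matrix(d_spike, 1L, B))

  if (model$kind == "hard") {
    dfeat <- matrix(0, Fd, B)
    for (k in seq_len(n_tasks)) {
      dfeat <- dfeat + tower_backward(model$towers[[k]],
                                      cache$towers[[k]],
                                      dpred[k, , drop = FALSE])
    }
    dim(dfeat) <- c(utils::tail(cfg$level_channels, 1), cfg$history, B)
    tcn_backward(model$bottom, cache$bottom, dfeat)
    return(invisible(NULL))
  }

  E <- cfg$n_experts
  dE <- lapply(seq_len(E), function(j) matrix(0, Fd, B))
  dcomp <- matrix(0, Fd, B)
  for (k in seq_len(n_tasks)) {
    dmix <- tower_backward(model$towers[[k]], cache$towers[[k]],
                           dpred[k, , drop = FALSE])
    g <- cache$gates[[k]]$g
    dg <- matrix(0, E, B)
    for (j in seq_len(E)) {
      dg[j, ] <- colSums(dmix * cache$ex_out[[j]])
      if (all(g[j, ] == 0)) next
      dE[[j]] <- dE[[j]] + dmix * rep(g[j, ], each = Fd)
    }
    dlogits <- softmax_backward_cols(g, dg)
    dcomp <- dcomp + linear_backward(model$gates[[k]],
                                     cache$gates[[k]]$lin, dlogits)
  }
  ch_out <- utils::tail(cfg$level_channels, 1)
  for (j in seq_len(E)) {
    dEj <- dE[[j]]
    dim(dEj) <- c(ch_out, cfg$history, B)
    tcn_backward(model$experts[[j]], cache$experts[[j]], dEj)
  }
  dim(dcomp) <- c(ch_out, cfg$history, B)
  tcn_backward(model$compressor, cache$compressor, dcomp)
  invisible(NULL)
}

#' Count trainable parameters
#'
#' @param model an `nd_mtl_model` or `nd_tcn`.
#' @return exact number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(param_layers(model),
             function(ly) length(ly$W) + length(ly$b), numeric(1)))
}

#' Mean gate weights per task and expert
#'
#' Averages the softmax gate outputs of a soft model over a set of samples,
#' giving the mean contribution of each expert to each task; these are the
#' quantities projected onto the morphology in gate-weight maps. Optionally
#' the matrix is normalized to the mean weights of the first expert.
#'
#' @param model a soft `nd_mtl_model` (`mmoe` or `mmoeex`).
#' @param x input array `[3N x history x batch]` of probe samples.
#' @param normalize `"none"` (default) or `"first_expert"` (divide by the
#'   mean weight of expert 1).
#' @return matrix `[n_tasks x n_experts]` of mean gate weights.
#' @export
mean_gate_weights <- function(model, x, normalize = c("none", "first_expert")) {
  stopifnot(inherits(model, "nd_mtl_model"))
  normalize <- match.arg(normalize)
  if (model$kind == "hard")
    stop("gate weights are undefined for the hard parameter sharing model")
  out <- forward_mtl(model, x, train = FALSE)
  m <- apply(out$gates, c(3, 1), mean)     # [n_tasks x n_experts]
  if (normalize == "first_expert") {
    ref <- mean(m[, 1])
    if (ref > 0) m <- m / ref
  }
  m
}
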