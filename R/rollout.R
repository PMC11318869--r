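#' Autoregressive rollout of a trained surrogate
#'
#' Simulates a neuron forward in time one millisecond per step. The model
#' keeps a rolling 100 ms buffer of z-scored voltages and synaptic-event
#' channels; each step's voltage prediction is appended to the buffer
#' (closed loop) or replaced by the ground truth (teacher forcing), while
#' the synaptic-event channels always come from the predetermined event
#' trains. Batch elements evolve independently, so the batch dimension can
#' be read as the number of model neurons simulated at once.
#'
#' @param model an `nd_mtl_model`, or a function `(buffer) -> list(voltage,
#'   spike_logit)` implementing the same contract on a `[3N x H x B]`
#'   buffer (useful for closed-form reference models).
#' @param standardizer the training `nd_standardizer` (voltages enter and
#'   leave in mV; z-scoring is internal).
#' @param init_voltage initial history, `[history x N]` matrix in mV or a
#'   `[history x N x B]` array for a batch.
#' @param event_channels binned event counts `[>= history + n_steps x 2N]`
#'   (shared across the batch) or a `[.. x 2N x B]` array.
#' @param n_steps number of 1 ms steps to predict.
#' @param mode `"closed_loop"` (default) or `"teacher_forced"`.
#' @param ground_truth `[n_steps x N]` (or `[n_steps x N x B]`) mV voltages;
#'   required for teacher forcing.
#' @return array `[n_steps x N x B]` of predicted voltages in mV (last
#'   dimension kept even for B = 1).
#' @export
rollout <- function(model, standardizer, init_voltage, event_channels,
                    n_steps, mode = c("closed_loop", "teacher_forced"),
                    ground_truth = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "nd_mtl_model") || is.function(model),
            inherits(standardizer, "nd_standardizer"))
  step_fn <- if (is.function(model)) model
             else function(buf) forward_mtl(model, buf, train = FALSE)
  if (is.function(model)) {
    N <- ncol(init_voltage)
    if (is.na(N)) N <- dim(init_voltage)[2]
    H <- dim(init_voltage)[1]
    if (is.null(H)) H <- nrow(init_voltage)
  } else {
    N <- model$config$n_comp
    H <- model$config$history
  }
  if (length(dim(init_voltage)) == 2L)
    dim(init_voltage) <- c(dim(init_voltage), 1L)
  B <- dim(init_voltage)[3]
  stopifnot(dim(init_voltage)[1] == H, dim(init_voltage)[2] == N)
  if (length(dim(event_channels)) == 2L)
    event_channels <- array(event_channels,
                            c(dim(event_channels), 1L))[, , rep(1L, B),
                                                        drop = FALSE]
  stopifnot(dim(event_channels)[2] == 2L * N, dim(event_channels)[3] == B)
  if (dim(event_channels)[1] < H + n_steps)
    stop("event channels cover ", dim(event_channels)[1],
         " ms but rollout needs ", H + n_steps, " ms")
  if (mode == "teacher_forced") {
    if (is.null(ground_truth)) stop("teacher forcing requires ground_truth")
    if (length(dim(ground_truth)) == 2L)
      dim(ground_truth) <- c(dim(ground_truth), 1L)
    stopifnot(dim(ground_truth)[1] >= n_steps,
              dim(ground_truth)[2] == N, dim(ground_truth)[3] == B)
  }

  buf <- array(0, c(3L * N, H, B))
  for (b in seq_len(B)) {
    buf[1:N, , b] <- t(apply_standardizer(init_voltage[, , b],
                                          standardizer))
    buf[(N + 1):(3 * N), , b] <- t(event_channels[1:H, , b])
  }
  out <- array(0, c(n_steps, N, B))
  for (s in seq_len(n_steps)) {
    pred <- step_fn(buf)
    mv <- apply_standardizer(pred$voltage, standardizer,
                             invert = TRUE, per_row = FALSE)
    out[s, , ] <- mv
    feed_z <- if (mode == "closed_loop") pred$voltage
              else apply_standardizer(matrix(ground_truth[s, , ], N, B),
                                      standardizer, per_row = FALSE)
    buf[, 1:(H - 1L), ] <- buf[, 2:H, , drop = FALSE]
    for (b in seq_len(B)) {
      buf[1:N, H, b] <- feed_z[, b]
      buf[(N + 1):(3 * N), H, b] <- event_channels[H + s, , b]
    }
  }
  out
}

#' Point-source extracellular potential from membrane currents
#'
#' Volume-conductor forward model: each compartment is a point current
#' source at its midpoint in an infinite homogeneous medium of conductivity
#' `sigma`, so `phi(r, t) = 1/(4 pi sigma) * sum_n I_n(t) / |r - r_n|`.
#' With currents in nA, distances in micrometres and `sigma` in S/m the
#' result is in microvolts.
#'
#' @param membrane_currents matrix `[timesteps x N]` in nA (simulator
#'   output or [reconstruct_membrane_currents()] of predicted voltages).
#' @param morph the `nd_morphology` (compartment midpoints).
#' @param electrodes numeric matrix `[n_electrodes x 3]` of positions (µm).
#' @param sigma extracellular conductivity in S/m (default 0.3).
#' @return matrix `[timesteps x n_electrodes]` of potentials in µV.
#' @export
extracellular_potential <- function(membrane_currents, morph, electrodes,
                                    sigma = 0.3) {
  validate_morphology(morph)
  stopifnot(sigma > 0)
  electrodes <- matrix(as.numeric(electrodes), ncol = 3)
  comp <- morph$compartments
  if (ncol(membrane_currents) != morph$n_comp)
    stop("currents have ", ncol(membrane_currents),
         " columns but morphology has ", morph$n_comp, " compartments")
  pos <- cbind(comp$x, comp$y, comp$z)
  phi <- matrix(0, nrow(membrane_currents), nrow(electrodes))
  for (e in seq_len(nrow(electrodes))) {
    d <- sqrt(colSums((t(pos) - electrodes[e, ])^2))
    if (any(d < comp$diameter / 2))
      stop("electrode ", e, " lies inside compartment ",
           which(d < comp$diameter / 2)[1])
    phi[, e] <- membrane_currents %*% (1 / d)
  }
  phi * 1e3 / (4 * pi * sigma)
}

#' Per-compartment error between predicted and ground-truth traces
#'
#' @param predicted,ground_truth matrices `[timesteps x N]` in mV.
#' @return list with `rmse_per_comp` (mV, length N), `rmse_mV` (pooled),
#'   `data_sd_mV` (pooled ground-truth standard deviation), and
#'   `rmse_over_sd`.
#' @export
compare_traces <- function(predicted, ground_truth) {
  if (!all(dim(predicted) == dim(ground_truth)))
    stop("predicted and ground-truth shapes differ")
  err <- predicted - ground_truth
  rmse_pc <- sqrt(colMeans(err^2))
  rmse <- sqrt(mean(err^2))
  sd_gt <- stats::sd(as.numeric(ground_truth))
  list(rmse_per_comp = rmse_pc, rmse_mV = rmse, data_sd_mV = sd_gt,
       rmse_over_sd = rmse / sd_gt)
}

#' Wall-clock inference benchmark
#'
#' Times closed-loop rollouts for each (batch size, duration) pair,
#' repeating each measurement and reporting mean and standard deviation.
#' Runtimes are hardware-dependent throughput indicators, not model
#' quality metrics.
#'
#' @param model an `nd_mtl_model`.
#' @param standardizer an `nd_standardizer` (identity statistics work for
#'   pure timing).
#' @param batch_sizes,durations_ms vectors defining the grid.
#' @param repeats independent repetitions per cell (default 7).
#' @return data frame with columns `runtime_s`, `sd_ms`, `model`,
#'   `simulation_ms`, `batch`, `repeats`.
#' @export
benchmark_inference <- function(model, standardizer,
                                batch_sizes = c(1, 8),
                                durations_ms = c(1, 10), repeats = 7) {
  N <- model$config$n_comp
  H <- model$config$history
  rows <- list()
  for (B in batch_sizes) {
    for (Tm in durations_ms) {
      init <- array(standardizer$mean, c(H, N, B))
      ev <- array(0, c(H + Tm, 2 * N, B))
      times <- vapply(seq_len(repeats), function(r) {
        t0 <- proc.time()[["elapsed"]]
        rollout(model, standardizer, init, ev, n_steps = Tm)
        proc.time()[["elapsed"]] - t0
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        runtime_s = mean(times), sd_ms = stats::sd(times) * 1000,
        model = model$kind, simulation_ms = Tm, batch = B,
        repeats = repeats)
    }
  }
  do.call(rbind, rows)
}
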