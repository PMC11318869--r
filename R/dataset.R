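#' Bin synaptic events into per-synapse count channels
#'
#' Events are counted in half-open bins `[(k-1) dt, k dt)` on the recording
#' grid, one channel per synapse, so the binned channels align with the
#' voltage rows of a trace (row k is time `k dt`). Total counts are
#' conserved.
#'
#' @param events an `nd_event_trains` object.
#' @param record_dt bin width in ms (default 1).
#' @param duration total duration in ms; defaults to the trains' duration.
#' @return integer matrix `[bins x synapses]` of event counts.
#' @export
bin_events <- function(events, record_dt = 1, duration = NULL) {
  stopifnot(inherits(events, "nd_event_trains"))
  if (is.null(duration)) duration <- events$duration
  n_bins <- as.integer(round(duration / record_dt))
  out <- matrix(0L, n_bins, length(events$times))
  for (s in seq_along(events$times)) {
    t <- events$times[[s]]
    if (!length(t)) next
    if (min(t) < 0 || max(t) >= duration)
      stop("event times outside [0, duration) in synapse ", s)
    b <- tabulate(floor(t / record_dt) + 1L, nbins = n_bins)
    out[, s] <- b
  }
  out
}

#' Slice a trace into (history, target) window samples
#'
#' Produces one sample per stride position: a 100 ms history of all voltage
#' and synaptic-event channels, a 1 ms membrane-potential target for every
#' compartment, and a binary somatic-spike target that is 1 iff a somatic
#' spike time falls inside the target bin. Channel layout is `N` voltage
#' channels followed by `2N` event-count channels (3N channels in total).
#' Windows are causal: the history covers bins `k .. k+H-1` and the target
#' is bin `k+H`.
#'
#' Voltages are kept in raw mV here; standardization is applied by
#' [fit_standardizer()] / [apply_standardizer()] downstream. Event channels
#' carry raw integer counts and are never standardized.
#'
#' @param trace an `nd_trace`.
#' @param event_channels binned event matrix from [bin_events()]; computed
#'   from the trace's own trains when omitted.
#' @param history_ms,target_ms,stride_ms window layout in ms on the
#'   recording grid (defaults 100 / 1 / 1).
#' @return An `nd_windows` object: list with `voltage` `[T x N]` (mV),
#'   `events` `[T x 2N]`, `offsets` (window start rows), `target_spike`
#'   (0/1 per window), `history`, `n_comp`, `record_dt`.
#' @export
make_windows <- function(trace, event_channels = NULL,
                         history_ms = 100, target_ms = 1, stride_ms = 1) {
  stopifnot(inherits(trace, "nd_trace"))
  record_dt <- trace$record_dt
  H <- as.integer(round(history_ms / record_dt))
  Tg <- as.integer(round(target_ms / record_dt))
  S <- as.integer(round(stride_ms / record_dt))
  if (is.null(event_channels))
    event_channels <- bin_events(trace$events, record_dt, trace$duration)
  n_rows <- nrow(trace$voltage)
  if (nrow(event_channels) != n_rows)
    stop("event channels and voltage have different numbers of rows")
  if (n_rows <= H + Tg - 1L)
    stop("trace too short: need more than ", H + Tg - 1L, " rows, got ", n_rows)

  offsets <- seq.int(1L, n_rows - H - Tg + 1L, by = S)
  # target bin k+H covers time [(k+H-1) dt, (k+H) dt)
  spike_bins <- unique(floor(trace$somatic_spike_times / record_dt -
                               .Machine$double.eps^0.5) + 1L)
  target_bins <- offsets + H
  target_spike <- as.integer(target_bins %in% spike_bins)

  structure(list(voltage = trace$voltage, events = event_channels,
                 offsets = offsets, target_spike = target_spike,
                 history = H, target = Tg, n_comp = ncol(trace$voltage),
                 record_dt = record_dt),
            class = "nd_windows")
}

#' @export
print.nd_windows <- function(x, ...) {
  cat("<nd_windows> ", length(x$offsets), " windows (history ", x$history,
      " bins, ", x$n_comp, " compartments), spike fraction ",
      signif(mean(x$target_spike), 3), "\n", sep = "")
  invisible(x)
}

#' Balance windows to a fixed spiking-target fraction
#'
#' Keeps every window whose target bin contains a somatic spike and samples
#' non-spiking windows uniformly without replacement so that the requested
#' fraction (default one third) of retained targets contains a spike. The
#' retained set is shuffled with the given seed.
#'
#' @param windows an `nd_windows` object.
#' @param ratio desired spiking fraction (default 1/3).
#' @param seed integer seed for subsampling and shuffling.
#' @return An `nd_windows` object restricted to the balanced subset, with
#'   `spike_fraction` and `seed` fields added.
#' @export
balance_dataset <- function(windows, ratio = 1 / 3, seed = 1L) {
  stopifnot(inherits(windows, "nd_windows"), ratio > 0, ratio < 1)
  spiking <- which(windows$target_spike == 1L)
  non <- which(windows$target_spike == 0L)
  S <- length(spiking)
  if (S == 0L) stop("no spiking windows available; cannot balance")
  n_non <- round(S * (1 - ratio) / ratio)
  if (length(non) < n_non)
    stop("insufficient non-spiking windows: need ", n_non,
         " but only ", length(non), " available (", S, " spiking)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- c(spiking, sample(non, n_non))
  keep <- keep[sample.int(length(keep))]
  out <- windows
  out$offsets <- windows$offsets[keep]
  out$target_spike <- windows$target_spike[keep]
  out$spike_fraction <- mean(out$target_spike)
  out$seed <- seed
  out
}

#' Fit per-compartment z-scoring statistics
#'
#' Means and standard deviations are computed per compartment over all
#' history bins of the supplied (training) windows. Statistics fitted on
#' the training split must be reused unchanged on validation data.
#'
#' @param windows an `nd_windows` object (at least 2 windows).
#' @return An `nd_standardizer`: list with `mean` and `sd` vectors (mV) and
#'   the number of windows they were fitted on.
#' @export
fit_standardizer <- function(windows) {
  stopifnot(inherits(windows, "nd_windows"))
  if (length(windows$offsets) < 2L) stop("need at least 2 windows to fit")
  rows <- unique(unlist(lapply(windows$offsets,
                               function(k) k:(k + windows$history - 1L))))
  v <- windows$voltage[rows, , drop = FALSE]
  mu <- colMeans(v)
  sd <- apply(v, 2, stats::sd)
  if (any(sd <= 1e-12))
    stop("zero-variance compartment(s): ",
         paste(which(sd <= 1e-12), collapse = ", "))
  structure(list(mean = mu, sd = sd, n_windows = length(windows$offsets)),
            class = "nd_standardizer")
}

#' Apply (or invert) z-scoring to voltages
#'
#' Transforms only voltage values; synaptic event-count channels are never
#' standardized. The round trip `apply_standardizer(apply_standardizer(x),
#' invert = TRUE)` is the identity to floating-point precision.
#'
#' @param x a voltage matrix `[rows x N]`, an `[N x B]` prediction matrix
#'   (set `per_row = FALSE`), or an `nd_windows` object.
#' @param standardizer an `nd_standardizer`.
#' @param invert if `TRUE`, maps z-scores back to mV.
#' @param per_row if `TRUE` (default) compartments index columns of `x`;
#'   otherwise they index rows.
#' @return object of the same shape with voltages transformed.
#' @export
apply_standardizer <- function(x, standardizer, invert = FALSE,
                               per_row = TRUE) {
  stopifnot(inherits(standardizer, "nd_standardizer"))
  mu <- standardizer$mean
  sd <- standardizer$sd
  if (inherits(x, "nd_windows")) {
    x$voltage <- apply_standardizer(x$voltage, standardizer, invert)
    return(x)
  }
  x <- as.matrix(x)
  n <- length(mu)
  if (per_row) {
    if (ncol(x) != n) stop("expected ", n, " compartment columns")
    if (invert) sweep(sweep(x, 2, sd, "*"), 2, mu, "+")
    else sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
  } else {
    if (nrow(x) != n) stop("expected ", n, " compartment rows")
    if (invert) x * sd + mu
    else (x - mu) / sd
  }
}

#' Assemble a balanced, standardized train/validation dataset
#'
#' Splits at the level of whole traces (80/20 by default) when several
#' traces are supplied, to avoid temporal leakage between splits; a single
#' trace is split by time (first fraction for training). Each split is then
#' spike-balanced globally with [balance_dataset()] and the z-scoring
#' statistics are fitted on the training split only.
#'
#' @param traces a single `nd_trace` or a list of them.
#' @param ratio spiking-target fraction after balancing (default 1/3).
#' @param train_fraction fraction of traces (or time) used for training.
#' @param seed integer seed controlling split assignment and balancing.
#' @param history_ms,target_ms window layout passed to [make_windows()].
#' @return An `nd_dataset`: list with `train` and `validation`
#'   `nd_windows`, the fitted `standardizer`, `n_comp`, and `seed`.
#' @export
make_dataset <- function(traces, ratio = 1 / 3, train_fraction = 0.8,
                         seed = 1L, history_ms = 100, target_ms = 1) {
  if (inherits(traces, "nd_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  if (length(traces) == 1L) {
    tr <- traces[[1]]
    n_rows <- nrow(tr$voltage)
    cut <- floor(n_rows * train_fraction)
    w <- make_windows(tr, history_ms = history_ms, target_ms = target_ms)
    in_train <- (w$offsets + w$history) <= cut
    wt <- wv <- w
    wt$offsets <- w$offsets[in_train]
    wt$target_spike <- w$target_spike[in_train]
    wv$offsets <- w$offsets[!in_train]
    wv$target_spike <- w$target_spike[!in_train]
  } else {
    old <- .Random.seed_save()
    set.seed(seed)
    n_train <- max(1L, floor(length(traces) * train_fraction))
    ord <- sample.int(length(traces))
    .Random.seed_restore(old)
    train_ids <- ord[seq_len(n_train)]
    wins <- lapply(traces, make_windows,
                   history_ms = history_ms, target_ms = target_ms)
    wt <- concat_windows(wins[train_ids])
    wv <- concat_windows(wins[setdiff(seq_along(traces), train_ids)])
  }
  train <- balance_dataset(wt, ratio = ratio, seed = seed)
  validation <- balance_dataset(wv, ratio = ratio, seed = seed + 1L)
  standardizer <- fit_standardizer(train)
  structure(list(train = train, validation = validation,
                 standardizer = standardizer,
                 n_comp = train$n_comp, seed = seed),
            class = "nd_dataset")
}

# concatenate windows from several traces into one indexable collection
concat_windows <- function(win_list) {
  stopifnot(length(win_list) >= 1)
  w1 <- win_list[[1]]
  if (length(win_list) == 1L) return(w1)
  volt <- do.call(rbind, lapply(win_list, `[[`, "voltage"))
  ev <- do.call(rbind, lapply(win_list, `[[`, "events"))
  row0 <- cumsum(c(0L, vapply(win_list, function(w) nrow(w$voltage),
                              integer(1))))
  offsets <- unlist(lapply(seq_along(win_list),
                           function(i) win_list[[i]]$offsets + row0[i]))
  spikes <- unlist(lapply(win_list, `[[`, "target_spike"))
  out <- w1
  out$voltage <- volt
  out$events <- ev
  out$offsets <- offsets
  out$target_spike <- spikes
  out
}

#' @export
print.nd_dataset <- function(x, ...) {
  cat("<nd_dataset> ", length(x$train$offsets), " train / ",
      length(x$validation$offsets), " validation windows, ",
      x$n_comp, " compartments\n", sep = "")
  invisible(x)
}

#' Materialize a batch of window samples as arrays
#'
#' Builds the `[channels x history x batch]` input array (z-scored voltage
#' channels followed by raw event-count channels) and the z-scored voltage
#' and binary spike targets for the requested windows.
#'
#' @param windows an `nd_windows` object (typically `dataset$train`).
#' @param standardizer the training `nd_standardizer`.
#' @param idx window indices within `windows` (default: all).
#' @return list with `x` `[3N x H x B]`, `y_voltage` `[N x B]` (z-scored),
#'   `y_spike` numeric vector of length B.
#' @export
get_batch <- function(windows, standardizer, idx = NULL) {
  stopifnot(inherits(windows, "nd_windows"))
  if (is.null(idx)) idx <- seq_along(windows$offsets)
  N <- windows$n_comp
  H <- windows$history
  B <- length(idx)
  zvolt <- apply_standardizer(windows$voltage, standardizer)
  x <- array(0, c(3L * N, H, B))
  y_v <- matrix(0, N, B)
  for (b in seq_len(B)) {
    k <- windows$offsets[idx[b]]
    rows <- k:(k + H - 1L)
    x[1:N, , b] <- t(zvolt[rows, , drop = FALSE])
    x[(N + 1):(3 * N), , b] <- t(windows$events[rows, , drop = FALSE])
    y_v[, b] <- zvolt[k + H, ]
  }
  list(x = x, y_voltage = y_v,
       y_spike = as.numeric(windows$target_spike[idx]))
}
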