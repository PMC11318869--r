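#' Temporal convolutional network configuration
#'
#' The TCN used throughout the package as shared bottom, expert, and
#' compressor: a stack of residual levels, each containing two causal
#' dilated convolutions (kernel 10 by default, dilation doubling per level)
#' with ReLU activations and dropout, plus a 1x1 convolution shortcut when
#' the channel counts differ. The activation after the final level's
#' residual sum is a sigmoid rather than the usual ReLU, so the output
#' sequence lies in (0, 1).
#'
#' @param in_channels number of input channels.
#' @param level_channels output channels per level (default `c(32, 16, 8)`).
#' @param kernel_size convolution kernel width (default 10).
#' @param dropout dropout probability in `[0, 1)` (default 0.2),
#'   element-wise, active in training mode only.
#' @return an `nd_tcn_config` list.
#' @export
tcn_config <- function(in_channels, level_channels = c(32, 16, 8),
                       kernel_size = 10, dropout = 0.2) {
  stopifnot(in_channels >= 1, length(level_channels) >= 1,
            all(level_channels >= 1), kernel_size >= 1,
            dropout >= 0, dropout < 1)
  structure(list(in_channels = as.integer(in_channels),
                 level_channels = as.integer(level_channels),
                 kernel_size = as.integer(kernel_size),
                 dropout = dropout),
            class = "nd_tcn_config")
}

#' Build a causal TCN
#'
#' @param config an `nd_tcn_config`.
#' @param seed optional integer seed for weight initialization; identical
#'   seeds give identical initial weights.
#' @return an `nd_tcn` object (list of residual levels).
#' @export
build_tcn <- function(config, seed = NULL) {
  stopifnot(inherits(config, "nd_tcn_config"))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  c_prev <- config$in_channels
  blocks <- list()
  for (lvl in seq_along(config$level_channels)) {
    c_out <- config$level_channels[lvl]
    dil <- 2L^(lvl - 1L)
    blocks[[lvl]] <- list(
      conv1 = new_conv1d(c_prev, c_out, config$kernel_size, dil),
      conv2 = new_conv1d(c_out, c_out, config$kernel_size, dil),
      shortcut = if (c_prev != c_out) new_conv1d(c_prev, c_out, 1L, 1L)
                 else NULL,
      dilation = dil)
    c_prev <- c_out
  }
  structure(list(blocks = blocks, config = config,
                 out_channels = c_prev),
            class = "nd_tcn")
}

#' Forward pass through a TCN
#'
#' Causality holds layer by layer: the output at time t is a function of
#' inputs at times `<= t` only. In evaluation mode (`train = FALSE`,
#' the default) dropout is disabled and the pass is deterministic.
#'
#' @param tcn an `nd_tcn`.
#' @param x input array `[channels x time x batch]` (a `[channels x time]`
#'   matrix is promoted to batch size 1).
#' @param train logical; enables dropout.
#' @param want_cache keep intermediate activations for [tcn_backward()].
#' @return output array `[out_channels x time x batch]` with values in
#'   (0, 1); with `want_cache = TRUE`, a list `(out, cache)`.
#' @export
tcn_forward <- function(tcn, x, train = FALSE, want_cache = FALSE) {
  stopifnot(inherits(tcn, "nd_tcn"))
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] != tcn$config$in_channels)
    stop("expected ", tcn$config$in_channels, " input channels, got ",
         dim(x)[1])
  p <- tcn$config$dropout
  n_blocks <- length(tcn$blocks)
  caches <- vector("list", n_blocks)
  h <- x
  for (i in seq_len(n_blocks)) {
    blk <- tcn$blocks[[i]]
    f1 <- conv1d_forward(blk$conv1, h)
    a1 <- relu_forward(f1$out)
    d1 <- dropout_forward(a1$out, p, train)
    f2 <- conv1d_forward(blk$conv2, d1$out)
    a2 <- relu_forward(f2$out)
    d2 <- dropout_forward(a2$out, p, train)
    res <- if (is.null(blk$shortcut)) list(out = h, cache = NULL)
           else conv1d_forward(blk$shortcut, h)
    s <- d2$out + res$out
    act <- if (i == n_blocks) sigmoid_forward(s) else relu_forward(s)
    caches[[i]] <- list(f1 = f1$cache, a1 = a1$cache, d1 = d1$cache,
                        f2 = f2$cache, a2 = a2$cache, d2 = d2$cache,
                        res = res$cache, act = act$cache)
    h <- act$out
  }
  if (want_cache) list(out = h, cache = caches) else h
}

# reverse pass; accumulates parameter gradients in place, returns dx
tcn_backward <- function(tcn, cache, dout) {
  n_blocks <- length(tcn$blocks)
  dh <- dout
  for (i in rev(seq_len(n_blocks))) {
    blk <- tcn$blocks[[i]]
    cc <- cache[[i]]
    ds <- if (i == n_blocks) sigmoid_backward(cc$act, dh)
          else relu_backward(cc$act, dh)
    # residual branch
    dres <- if (is.null(blk$shortcut)) ds
            else conv1d_backward(blk$shortcut, cc$res, ds)
    # main branch
    dd2 <- dropout_backward(cc$d2, ds)
    da2 <- relu_backward(cc$a2, dd2)
    dd1 <- conv1d_backward(blk$conv2, cc$f2, da2)
    dd1 <- dropout_backward(cc$d1, dd1)
    da1 <- relu_backward(cc$a1, dd1)
    dx <- conv1d_backward(blk$conv1, cc$f1, da1)
    dh <- dx + dres
  }
  dh
}
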