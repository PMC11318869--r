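# Minimal neural-network layer toolkit with explicit reverse-mode gradients.
#
# Activations are stored as arrays [channels x time x batch] for sequence
# layers and matrices [features x batch] for dense layers. Parameters live
# in environments so gradient accumulation and optimizer updates happen in
# place; every parameterized layer carries W/b plus gW/gb and Adam state.

uniform_init <- function(dims, fan_in) {
  s <- sqrt(1 / fan_in)
  array(stats::runif(prod(dims), -s, s), dims)
}

new_linear <- function(n_in, n_out) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "linear"
  ly$W <- matrix(uniform_init(c(n_out, n_in), n_in), n_out, n_in)
  ly$b <- as.numeric(uniform_init(n_out, n_in))
  ly$gW <- ly$W * 0
  ly$gb <- ly$b * 0
  ly
}

linear_forward <- function(ly, x) {
  # x: [n_in x B]
  list(out = ly$W %*% x + ly$b, cache = x)
}

linear_backward <- function(ly, cache, dout) {
  ly$gW <- ly$gW + dout %*% t(cache)
  ly$gb <- ly$gb + rowSums(dout)
  crossprod(ly$W, dout)
}

# Causal dilated 1-D convolution. Weight W is [c_out, c_in, k]; tap j of the
# kernel reads the input delayed by (k - j) * dilation steps, with implicit
# left zero padding of (k - 1) * dilation so output length equals input
# length and output at time t depends on inputs at times <= t only.
new_conv1d <- function(c_in, c_out, kernel, dilation) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv1d"
  ly$c_in <- c_in
  ly$c_out <- c_out
  ly$kernel <- kernel
  ly$dilation <- dilation
  ly$W <- uniform_init(c(c_out, c_in, kernel), c_in * kernel)
  ly$b <- as.numeric(uniform_init(c_out, c_in * kernel))
  ly$gW <- ly$W * 0
  ly$gb <- ly$b * 0
  ly
}

conv1d_forward <- function(ly, x) {
  # x: [c_in x T x B]; compiled tap-loop gemm kernel
  out <- .conv1d_fwd(ly$W, ly$b, x, ly$dilation)
  list(out = out, cache = x)
}

conv1d_backward <- function(ly, cache, dout) {
  r <- .conv1d_bwd(ly$W, cache, dout, ly$dilation)
  ly$gW <- ly$gW + r$dW
  ly$gb <- ly$gb + as.numeric(r$db)
  r$dx
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(cache, dout) dout * cache

elu_forward <- function(x) {
  out <- ifelse(x > 0, x, expm1(x))
  list(out = out, cache = list(pos = x > 0, out = out))
}
elu_backward <- function(cache, dout) dout * ifelse(cache$pos, 1, cache$out + 1)

sigmoid_forward <- function(x) {
  out <- 1 / (1 + exp(-x))
  list(out = out, cache = out)
}
sigmoid_backward <- function(cache, dout) dout * cache * (1 - cache)

dropout_forward <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim(x))
  list(out = x * mask, cache = mask)
}
dropout_backward <- function(cache, dout) {
  if (is.null(cache)) dout else dout * cache
}

softmax_cols <- function(z) {
  # column-wise softmax; -Inf entries give exactly-zero probabilities and a
  # fully -Inf column gives an all-zero column (degenerate gate row)
  zmax <- apply(z, 2, max)
  zmax[!is.finite(zmax)] <- 0
  e <- exp(sweep(z, 2, zmax, "-"))
  e[z == -Inf] <- 0
  s <- colSums(e)
  s[s == 0] <- 1
  sweep(e, 2, s, "/")
}

softmax_backward_cols <- function(p, dout) {
  # dL/dz given p = softmax(z) and dL/dp, column-wise
  dot <- colSums(p * dout)
  p * sweep(dout, 2, dot, "-")
}

# ---- parameter bookkeeping -------------------------------------------------

param_layers <- function(model) {
  # flat list of parameterized layer environments in a model structure
  acc <- list()
  walk <- function(x) {
    if (is.environment(x)) {
      if (!is.null(x$W)) acc[[length(acc) + 1L]] <<- x
    } else if (is.list(x)) {
      lapply(x, walk)
    }
    invisible(NULL)
  }
  walk(model)
  acc
}

zero_grads <- function(layers) {
  for (ly in layers) {
    ly$gW <- ly$gW * 0
    ly$gb <- ly$gb * 0
  }
  invisible(NULL)
}

grad_global_norm <- function(layers) {
  sq <- 0
  for (ly in layers) sq <- sq + sum(ly$gW^2) + sum(ly$gb^2)
  sqrt(sq)
}

clip_grads <- function(layers, max_norm) {
  gn <- grad_global_norm(layers)
  if (is.finite(max_norm) && gn > max_norm) {
    sc <- max_norm / (gn + 1e-12)
    for (ly in layers) {
      ly$gW <- ly$gW * sc
      ly$gb <- ly$gb * sc
    }
  }
  gn
}

adam_init <- function(layers) {
  for (ly in layers) {
    ly$mW <- ly$gW * 0
    ly$vW <- ly$gW * 0
    ly$mb <- ly$gb * 0
    ly$vb <- ly$gb * 0
  }
  invisible(NULL)
}

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (ly in layers) {
    ly$mW <- beta1 * ly$mW + (1 - beta1) * ly$gW
    ly$vW <- beta2 * ly$vW + (1 - beta2) * ly$gW^2
    ly$W <- ly$W - lr * (ly$mW / bc1) / (sqrt(ly$vW / bc2) + eps)
    ly$mb <- beta1 * ly$mb + (1 - beta1) * ly$gb
    ly$vb <- beta2 * ly$vb + (1 - beta2) * ly$gb^2
    ly$b <- ly$b - lr * (ly$mb / bc1) / (sqrt(ly$vb / bc2) + eps)
  }
  invisible(NULL)
}

get_param_state <- function(model) {
  lapply(param_layers(model), function(ly) list(W = ly$W, b = ly$b))
}

set_param_state <- function(model, state) {
  layers <- param_layers(model)
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    stopifnot(identical(dim(layers[[i]]$W), dim(state[[i]]$W)) ||
                length(layers[[i]]$W) == length(state[[i]]$W))
    layers[[i]]$W <- state[[i]]$W
    layers[[i]]$b <- state[[i]]$b
  }
  invisible(model)
}
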