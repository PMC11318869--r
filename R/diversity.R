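#' Squared-distance between two expert representations
#'
#' The diversity between experts n and m is the sum of squared elementwise
#' differences of their representations evaluated on the same sample set:
#' `d(n, m) = sum_i (f_n(x_i) - f_m(x_i))^2`, summed over all samples and
#' representation elements.
#'
#' @param f_n,f_m numeric arrays/matrices of identical shape (flattened
#'   expert outputs, samples along any axis as long as both match).
#' @return non-negative scalar distance.
#' @export
expert_distance <- function(f_n, f_m) {
  if (!identical(dim(f_n), dim(f_m)) || length(f_n) != length(f_m))
    stop("representation shapes differ")
  sum((f_n - f_m)^2)
}

#' Pairwise expert-diversity matrix of a soft model
#'
#' Evaluates every expert TCN (post-sigmoid, flattened) on a fixed probe
#' sample set, computes all pairwise squared distances, and normalizes the
#' matrix by its maximum entry so that near-identical experts score close
#' to 0 and maximally different pairs score exactly 1. An all-zero distance
#' matrix (weight-identical experts) is returned unchanged.
#'
#' @param model a soft `nd_mtl_model` (`mmoe` or `mmoeex`).
#' @param x probe input array `[3N x history x batch]`, typically a
#'   validation subset (256 samples by default in the pipeline helpers).
#' @return an `nd_diversity_matrix`: symmetric `[E x E]` matrix with zero
#'   diagonal and entries in `[0, 1]`.
#' @export
diversity_matrix <- function(model, x) {
  stopifnot(inherits(model, "nd_mtl_model"))
  if (model$kind == "hard")
    stop("expert diversity is undefined for the hard parameter sharing model")
  E <- model$config$n_experts
  if (E < 2) stop("need at least 2 experts")
  reps <- lapply(model$experts, function(ex) {
    f <- tcn_forward(ex, x, train = FALSE)
    as.numeric(f)
  })
  D <- matrix(0, E, E)
  for (n in seq_len(E - 1)) {
    for (m in (n + 1):E) {
      d <- sum((reps[[n]] - reps[[m]])^2)
      D[n, m] <- d
      D[m, n] <- d
    }
  }
  mx <- max(D)
  if (mx > 0) D <- D / mx
  structure(D, class = c("nd_diversity_matrix", "matrix", "array"))
}

#' Summary diversity scores of a diversity matrix
#'
#' The three scalar summaries of a normalized diversity matrix `D`: the
#' mean over all M^2 entries (diagonal included), the determinant, and the
#' permanent. The permanent is computed exactly with Ryser's
#' inclusion-exclusion formula, practical for M up to about 20.
#'
#' @param D a square numeric matrix (an `nd_diversity_matrix` or plain).
#' @return list with `mean`, `determinant`, `permanent`.
#' @export
diversity_scores <- function(D) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix")
  list(mean = mean(D),
       determinant = det(D),
       permanent = matrix_permanent(D))
}

#' Exact matrix permanent (Ryser's formula)
#'
#' `perm(A) = (-1)^M sum over nonempty subsets S of columns of
#' (-1)^|S| prod_i (sum_{j in S} A[i, j])`. Exponential in M; intended for
#' the small expert-count matrices used here (M <= 20).
#'
#' @param A square numeric matrix.
#' @return the permanent of `A`.
#' @export
matrix_permanent <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix")
  M <- nrow(A)
  if (M == 0) return(1)
  if (M > 20) stop("permanent computation limited to M <= 20")
  total <- 0
  for (s in seq_len(2^M - 1)) {
    cols <- which(bitwAnd(s, bitwShiftL(1L, 0:(M - 1))) != 0L)
    rs <- rowSums(A[, cols, drop = FALSE])
    total <- total + (-1)^length(cols) * prod(rs)
  }
  (-1)^M * total
}

#' Probe a trained soft model's expert diversity on a dataset
#'
#' Convenience wrapper: draws a fixed-size probe subset from the validation
#' split, computes the diversity matrix and its three summary scores.
#'
#' @param model a soft `nd_mtl_model`.
#' @param dataset an `nd_dataset`.
#' @param n_probe number of validation samples to probe (default 256,
#'   capped at the split size).
#' @param seed seed for the probe draw.
#' @return list with `matrix` and `scores`.
#' @export
probe_diversity <- function(model, dataset, n_probe = 256, seed = 1L) {
  w <- prepare_windows(dataset$validation, dataset$standardizer)
  n <- length(w$offsets)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- if (n > n_probe) sort(sample.int(n, n_probe)) else seq_len(n)
  batch <- get_batch(w, dataset$standardizer, idx)
  D <- diversity_matrix(model, batch$x)
  list(matrix = D, scores = diversity_scores(D))
}
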