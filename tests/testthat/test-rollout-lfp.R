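identity_std <- function(N) {
  structure(list(mean = rep(0, N), sd = rep(1, N), n_windows = 1L),
            class = "nd_standardizer")
}

test_that("a one-step rollout equals a single forward pass", {
  fit <- fx_trained()
  ds <- fx_dataset()
  std <- ds$standardizer
  w <- ds$train
  k <- w$offsets[1]
  init <- w$voltage[k:(k + 99), ]
  ev <- w$events[k:(k + 100), ]
  r <- rollout(fit$model, std, init, ev, n_steps = 1)
  b <- get_batch(w, std, 1L)
  direct <- forward_mtl(fit$model, b$x[, , 1, drop = FALSE])
  direct_mv <- apply_standardizer(direct$voltage, std, invert = TRUE,
                                  per_row = FALSE)
  expect_equal(r[1, , 1], as.numeric(direct_mv), tolerance = 1e-12)
})

test_that("teacher-forced rollout reproduces per-step forward predictions", {
  fit <- fx_trained()
  ds <- fx_dataset()
  std <- ds$standardizer
  tr <- fx_trace()
  H <- 100
  steps <- 5
  ev <- bin_events(tr$events, 1, tr$duration)
  init <- tr$voltage[1:H, ]
  gt <- tr$voltage[(H + 1):(H + steps), ]
  r <- rollout(fit$model, std, init, ev[1:(H + steps), ], steps,
               mode = "teacher_forced", ground_truth = gt)
  # reference: independent forward passes on ground-truth windows
  zv <- apply_standardizer(tr$voltage, std)
  for (s in seq_len(steps)) {
    x <- array(0, c(3 * 20, H, 1))
    rows <- s:(s + H - 1)
    x[1:20, , 1] <- t(zv[rows, ])
    x[21:60, , 1] <- t(ev[rows, ])
    ref <- forward_mtl(fit$model, x)
    ref_mv <- apply_standardizer(ref$voltage, std, invert = TRUE,
                                 per_row = FALSE)
    expect_equal(r[s, , 1], as.numeric(ref_mv), tolerance = 1e-12)
  }
})

test_that("identical batch elements follow identical trajectories", {
  fit <- fx_trained()
  ds <- fx_dataset()
  tr <- fx_trace()
  ev <- bin_events(tr$events, 1, tr$duration)
  init <- array(rep(tr$voltage[1:100, ], 2), c(100, 20, 2))
  evb <- array(rep(ev[1:110, ], 2), c(110, 40, 2))
  r <- rollout(fit$model, ds$standardizer, init, evb, 10)
  expect_identical(r[, , 1], r[, , 2])
})

test_that("an identity step function yields a constant continuation", {
  N <- 4
  H <- 10
  mock <- function(buf) {
    B <- dim(buf)[3]
    list(voltage = matrix(buf[1:N, H, ], N, B),
         spike_logit = rep(0, dim(buf)[3]))
  }
  std <- identity_std(N)
  init <- matrix(rep(c(-70, -65, -60, -55), each = H), H, N)
  ev <- matrix(0L, H + 6, 2 * N)
  r <- rollout(mock, std, init, ev, 6)
  for (s in 1:6) expect_equal(r[s, , 1], c(-70, -65, -60, -55))
})

test_that("event trains shorter than the horizon are rejected", {
  N <- 2
  mock <- function(buf) list(voltage = matrix(0, N, dim(buf)[3]),
                             spike_logit = 0)
  expect_error(rollout(mock, identity_std(N), matrix(0, 10, N),
                       matrix(0L, 12, 2 * N), 5),
               "rollout needs")
})

test_that("the point-source potential matches the analytic form", {
  m <- build_morphology(0, 0, 1)
  # single compartment with 1 nA at 100 µm and sigma = 0.3 S/m -> 2.653 µV
  I <- matrix(0, 1, 2)
  I[1, 1] <- 1
  soma_xyz <- unlist(m$compartments[1, c("x", "y", "z")])
  el <- matrix(soma_xyz + c(100, 0, 0), 1)
  phi <- extracellular_potential(I, m, el, sigma = 0.3)
  expect_equal(phi[1, 1], 1e3 / (4 * pi * 0.3 * 100), tolerance = 1e-12)
  expect_equal(phi[1, 1], 2.6526, tolerance = 1e-4)
  # doubling the distance halves the potential
  el2 <- matrix(soma_xyz + c(200, 0, 0), 1)
  phi2 <- extracellular_potential(I, m, el2, sigma = 0.3)
  expect_equal(phi2[1, 1], phi[1, 1] / 2, tolerance = 1e-12)
  # superposition
  I_a <- matrix(rnorm(10), 5, 2)
  I_b <- matrix(rnorm(10), 5, 2)
  pa <- extracellular_potential(I_a, m, el)
  pb <- extracellular_potential(I_b, m, el)
  pab <- extracellular_potential(I_a + I_b, m, el)
  expect_equal(pab, pa + pb, tolerance = 1e-10)
  # electrodes inside a compartment are rejected
  expect_error(extracellular_potential(I, m, matrix(soma_xyz + c(1, 0, 0), 1)),
               "inside")
})

test_that("a balanced +/- current pair decays faster than a monopole", {
  m <- build_morphology(0, 0, 1)
  I <- matrix(c(1, -1), 1, 2)    # equal and opposite sources
  base <- unlist(m$compartments[1, c("x", "y", "z")])
  r1 <- 200
  phi_r <- extracellular_potential(I, m, matrix(base + c(r1, 0, 0), 1))
  phi_2r <- extracellular_potential(I, m, matrix(base + c(2 * r1, 0, 0), 1))
  expect_lt(abs(phi_2r[1, 1]), abs(phi_r[1, 1]) / 2)
})

test_that("trace comparison reports exact identities", {
  gt <- matrix(rnorm(200), 20, 10)
  expect_equal(compare_traces(gt, gt)$rmse_mV, 0)
  cmp <- compare_traces(gt + 1, gt)
  expect_equal(cmp$rmse_mV, 1, tolerance = 1e-12)
  expect_equal(cmp$rmse_per_comp, rep(1, 10), tolerance = 1e-12)
  # shuffled predictions give ratio ~ sqrt(2) for i.i.d. draws
  set.seed(9)
  big <- matrix(rnorm(20000), 2000, 10)
  shuf <- matrix(sample(big), 2000, 10)
  expect_equal(compare_traces(shuf, big)$rmse_over_sd, sqrt(2),
               tolerance = 0.05)
  expect_error(compare_traces(gt[, 1:3], gt), "differ")
})

test_that("the benchmark grid reports one row per cell with 7 repeats", {
  cfg <- tiny_config()
  model <- build_mmoe(cfg)
  std <- identity_std(cfg$n_comp)
  # adapt history/channels to the tiny config
  tab <- benchmark_inference(model, std, batch_sizes = c(1, 2),
                             durations_ms = c(1, 20), repeats = 7)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$repeats == 7))
  expect_true(all(tab$runtime_s >= 0))
  # twenty simulated milliseconds cannot run faster than one
  agg <- tapply(tab$runtime_s, tab$batch, function(x) diff(x) >= 0)
  expect_true(all(unlist(agg)))
})
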