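test_that("event binning uses half-open 1 ms bins and conserves counts", {
  syn <- place_synapses(build_morphology(0, 0, 1))
  ev <- sample_event_trains(syn, 0, 0, duration = 10, seed = 1)
  ev$times[[1]] <- c(4.2)
  b <- bin_events(ev, 1, 10)
  expect_equal(b[5, 1], 1L)          # bin 5 covers [4, 5)
  expect_equal(sum(b), 1L)
  ev2 <- sample_event_trains(syn, 5, 5, duration = 2000, seed = 2)
  b2 <- bin_events(ev2)
  expect_equal(sum(b2), sum(lengths(ev2$times)))
  expect_equal(colSums(b2), lengths(ev2$times), ignore_attr = TRUE)
  ev$times[[1]] <- c(10.5)
  expect_error(bin_events(ev, 1, 10), "outside")
})

test_that("window counts and indexing follow the 100 ms -> 1 ms contract", {
  tr <- fx_trace()
  w <- make_windows(tr)
  T_rows <- nrow(tr$voltage)
  expect_length(w$offsets, T_rows - 100)
  # indexing contract: window k has history [k, k+100) and target k+100
  expect_equal(w$offsets[1], 1L)
  expect_equal(max(w$offsets) + w$history, T_rows)
  # materialized history is rows [k, k+100) and the target is row k+100
  ds <- fx_dataset()
  k <- ds$train$offsets[1]
  b <- get_batch(ds$train, ds$standardizer, 1L)
  zv <- apply_standardizer(ds$train$voltage, ds$standardizer)
  expect_equal(b$x[1:20, , 1], t(zv[k:(k + 99), ]), ignore_attr = TRUE)
  expect_equal(b$y_voltage[, 1], zv[k + 100, ], ignore_attr = TRUE)
  # 6000 ms trace yields 5900 windows on the 1 ms grid
  tr6 <- tr
  tr6$voltage <- tr$voltage[1:6000, ]
  tr6$duration <- 6000
  ev6 <- bin_events(tr$events, 1, tr$duration)[1:6000, ]
  expect_length(make_windows(tr6, ev6)$offsets, 5900L)
  # 101 ms trace yields exactly one window
  tr1 <- tr
  tr1$voltage <- tr$voltage[1:101, ]
  tr1$duration <- 101
  expect_length(make_windows(tr1, ev6[1:101, ])$offsets, 1L)
  expect_error(make_windows(tr1, ev6[1:50, ]), "rows")
})

test_that("spike targets mark exactly the windows whose target bin spikes", {
  tr <- fx_trace()
  w <- make_windows(tr)
  spike_rows <- unique(ceiling(tr$somatic_spike_times - 1e-9))
  expected <- as.integer((w$offsets + w$history) %in% spike_rows)
  expect_equal(w$target_spike, expected)
})

test_that("balancing keeps all spiking windows at a one-third fraction", {
  tr <- fx_trace()
  w <- make_windows(tr)
  S <- sum(w$target_spike)
  bal <- balance_dataset(w, seed = 3)
  expect_equal(sum(bal$target_spike), S)       # every spiking window kept
  expect_length(bal$offsets, 3 * S)
  expect_equal(bal$spike_fraction, 1 / 3)
  expect_false(any(duplicated(bal$offsets)))
  # synthetic counts: 100 spiking + 900 non-spiking -> 300 out, 100 spiking
  w2 <- w
  w2$offsets <- seq_len(1000)
  w2$target_spike <- c(rep(1L, 100), rep(0L, 900))
  b2 <- balance_dataset(w2, seed = 1)
  expect_length(b2$offsets, 300L)
  expect_equal(sum(b2$target_spike), 100L)
  # no spiking windows -> error
  w3 <- w2
  w3$target_spike <- rep(0L, 1000)
  expect_error(balance_dataset(w3), "no spiking")
  # insufficient non-spiking -> informative error
  w4 <- w2
  w4$target_spike <- c(rep(1L, 900), rep(0L, 100))
  expect_error(balance_dataset(w4), "insufficient")
})

test_that("z-scoring is exact on training data and round-trips", {
  ds <- fx_dataset()
  std <- ds$standardizer
  expect_true(all(std$sd > 0))
  w <- ds$train
  rows <- unique(unlist(lapply(w$offsets, function(k) k:(k + w$history - 1))))
  z <- apply_standardizer(w$voltage, std)[rows, ]
  expect_lt(max(abs(colMeans(z))), 1e-6)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-6)
  # round trip
  x <- w$voltage[1:50, ]
  back <- apply_standardizer(apply_standardizer(x, std), std, invert = TRUE)
  expect_lt(max(abs(back - x)), 1e-9)
  # point values
  expect_equal(as.numeric(apply_standardizer(matrix(std$mean, 1), std)),
               rep(0, length(std$mean)))
  expect_equal(as.numeric(apply_standardizer(matrix(std$mean + std$sd, 1),
                                             std)),
               rep(1, length(std$mean)))
})

test_that("constant data cannot be standardized", {
  tr <- fx_trace()
  w <- make_windows(tr)
  w$voltage <- matrix(-65, nrow(w$voltage), ncol(w$voltage))
  expect_error(fit_standardizer(w), "variance")
})

test_that("validation statistics differ from training statistics (no leakage)", {
  ds <- fx_dataset()
  refit <- fit_standardizer(ds$validation)
  expect_false(isTRUE(all.equal(refit$mean, ds$standardizer$mean)))
})

test_that("batches carry z-scored voltages and raw event counts", {
  ds <- fx_dataset()
  b <- get_batch(ds$train, ds$standardizer, 1:4)
  N <- ds$n_comp
  expect_equal(dim(b$x), c(3 * N, 100, 4))
  expect_equal(dim(b$y_voltage), c(N, 4))
  ev_part <- b$x[(N + 1):(3 * N), , ]
  expect_true(all(ev_part == round(ev_part)) && all(ev_part >= 0))
  expect_true(all(b$y_spike %in% c(0, 1)))
})

test_that("dataset store round-trips bit-exactly", {
  ds <- fx_dataset()
  path <- withr::local_tempfile(fileext = ".rds")
  write_dataset(ds, path)
  ds2 <- read_dataset(path)
  expect_identical(ds2$train$voltage, ds$train$voltage)
  expect_identical(ds2$train$offsets, ds$train$offsets)
  expect_identical(ds2$standardizer, ds$standardizer)
  tr <- fx_trace()
  tp <- withr::local_tempfile(fileext = ".rds")
  write_trace(tr, tp)
  tr2 <- read_trace(tp)
  expect_identical(tr2$voltage, tr$voltage)
  expect_identical(tr2$somatic_spike_times, tr$somatic_spike_times)
})
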