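test_that("the multitask loss matches closed-form values", {
  # perfect voltages, spike logit 0, spike target 1 -> BCE = ln 2
  pred <- list(voltage = matrix(c(1, -1), 2, 1), spike_logit = 0)
  targ <- list(y_voltage = matrix(c(1, -1), 2, 1), y_spike = 1)
  expect_equal(multitask_loss(pred, targ)$total, log(2), tolerance = 1e-12)
  # single compartment, yhat = 0, y = 2 -> MSE 4 (spike term zeroed)
  pred2 <- list(voltage = matrix(0, 1, 1), spike_logit = 0)
  targ2 <- list(y_voltage = matrix(2, 1, 1), y_spike = 1)
  w0 <- list(w_comp = 1, w_spike = 0)
  expect_equal(multitask_loss(pred2, targ2, w0)$total, 4)
  # doubling every weight doubles the loss
  l1 <- multitask_loss(pred2, targ2, list(w_comp = 1, w_spike = 1))$total
  l2 <- multitask_loss(pred2, targ2, list(w_comp = 2, w_spike = 2))$total
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  # unit weights equal the unweighted sum of task losses
  ml <- multitask_loss(pred2, targ2)
  expect_equal(ml$total, sum(ml$per_task), tolerance = 1e-12)
  # NaN predictions are rejected with the task named
  pred3 <- list(voltage = matrix(NaN, 1, 1), spike_logit = 0)
  expect_error(multitask_loss(pred3, targ2), "NaN")
})

test_that("LBTW weights follow the (current/initial)^alpha law", {
  st <- lbtw_state(alpha = 0.5)
  # batch 0 stores initials and returns unit weights
  w0 <- lbtw_weights(st, c(2.0, 1.0, 0.5))
  expect_equal(w0$w_comp, c(1, 1))
  expect_equal(w0$w_spike, 1)
  # (0.5 / 2.0)^0.5 = 0.5
  w1 <- lbtw_weights(st, c(0.5, 1.0, 0.5))
  expect_equal(w1$w_comp[1], 0.5, tolerance = 1e-12)
  # current = initial -> weight 1 for any alpha
  expect_equal(w1$w_comp[2], 1)
  expect_equal(w1$w_spike, 1)
  # alpha = 0 -> all weights 1 regardless of the losses
  st0 <- lbtw_state(alpha = 0)
  lbtw_weights(st0, c(3, 4, 5))
  wa <- lbtw_weights(st0, c(0.1, 9, 2))
  expect_equal(c(wa$w_comp, wa$w_spike), rep(1, 3))
  # zero initial loss degenerates to weight 1
  stz <- lbtw_state(alpha = 1)
  lbtw_weights(stz, c(0, 1))
  wz <- lbtw_weights(stz, c(5, 2))
  expect_equal(wz$w_comp, 1)
  # epoch reset re-captures initials
  lbtw_new_epoch(st)
  wr <- lbtw_weights(st, c(9, 9, 9))
  expect_equal(c(wr$w_comp, wr$w_spike), rep(1, 3))
})

test_that("training runs end-to-end, is seeded, and checkpoints the best epoch", {
  ds <- fx_dataset()
  mc <- model_config(20, level_channels = c(4, 4, 2), kernel_size = 5,
                     n_experts = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  m1 <- build_mmoe(mc)
  f1 <- train(m1, ds, epochs = 2, batch_size = 64, seed = 9,
              checkpoint_path = path)
  expect_equal(nrow(f1$history), 2)
  expect_true(file.exists(path))
  expect_equal(f1$best_epoch, which.min(f1$history$val_loss))
  # identical seeds give identical histories
  m2 <- build_mmoe(mc)
  f2 <- train(m2, ds, epochs = 2, batch_size = 64, seed = 9)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
  # checkpoint reload reproduces the validation loss bit-for-bit
  ck <- load_checkpoint(path)
  ev1 <- evaluate(f1$model, ds)
  ev2 <- evaluate(ck$model, ds)
  expect_identical(ev1$total_loss, ev2$total_loss)
  expect_identical(ev1$rmse_mV, ev2$rmse_mV)
})

test_that("LBTW-weighted training runs and keeps finite weights", {
  ds <- fx_dataset()
  mc <- model_config(20, level_channels = c(4, 2), kernel_size = 5,
                     n_experts = 2, seed = 4)
  m <- build_hard_sharing(mc)
  f <- train(m, ds, epochs = 1, batch_size = 128, lbtw_alpha = 0.5, seed = 3)
  expect_true(all(is.finite(f$history$train_loss)))
})

test_that("a learnable linear task is actually learned", {
  # targets are a fixed linear map of the last input step: validation MSE
  # must drop by at least half within 20 epochs
  set.seed(31)
  N <- 3
  H <- 20
  n <- 240
  A <- matrix(rnorm(N * N, sd = 0.5), N, N)
  volt <- matrix(rnorm((n + H + 1) * N), n + H + 1, N)
  for (t in 2:nrow(volt)) volt[t, ] <- volt[t - 1, ] %*% A + rnorm(N, sd = .05)
  fake_windows <- structure(list(
    voltage = volt, events = matrix(0L, nrow(volt), 2 * N),
    offsets = seq_len(n), target_spike = rep(c(1L, 0L, 0L), n / 3),
    history = H, target = 1L, n_comp = N, record_dt = 1),
    class = "nd_windows")
  std <- fit_standardizer(fake_windows)
  ds <- structure(list(train = fake_windows,
                       validation = {
                         w <- fake_windows
                         w$offsets <- seq_len(60)
                         w$target_spike <- rep(c(1L, 0L, 0L), 20)
                         w
                       },
                       standardizer = std, n_comp = N, seed = 1),
                  class = "nd_dataset")
  mc <- model_config(N, history = H, level_channels = c(6, 4),
                     kernel_size = 4, dropout = 0, n_experts = 2, seed = 2)
  model <- build_mmoe(mc)
  ev0 <- evaluate(model, ds)
  fit <- train(model, ds, epochs = 20, batch_size = 8, lr = 5e-3, seed = 13)
  ev1 <- evaluate(fit$model, ds)
  mse0 <- sum(ev0$per_task[1:N])
  mse1 <- sum(ev1$per_task[1:N])
  expect_lt(mse1, 0.5 * mse0)
})

test_that("evaluation reports mV-scale errors with the contracted layout", {
  fit <- fx_trained()
  ds <- fx_dataset()
  ev <- evaluate(fit$model, ds)
  expect_length(ev$per_task, 21)
  expect_true(ev$rmse_mV > 0 && ev$data_sd_mV > 0)
  expect_equal(ev$rmse_over_sd, ev$rmse_mV / ev$data_sd_mV)
  ds_empty <- ds
  ds_empty$validation$offsets <- integer(0)
  expect_error(evaluate(fit$model, ds_empty), "empty")
})
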