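test_that("full-scale models land on the reference parameter counts", {
  mc <- model_config(639)
  mh <- build_hard_sharing(mc)
  expect_equal(round(count_parameters(mh) / 1e6), 14)
  rm(mh)
  mm <- build_mmoe(mc)
  expect_equal(round(count_parameters(mm) / 1e6), 12)
})

test_that("toy parameter counts equal the hand tally", {
  # linear 800 -> 25 with bias
  expect_equal(count_parameters(list(neurondistill:::new_linear(800, 25))),
               20025)
  # 2-task hard model: TCN(6; 4,3; k=3) + 2 towers (3*history -> ... )
  mc <- model_config(2, history = 10, level_channels = c(4, 3),
                     kernel_size = 3, n_experts = 2,
                     tower_hidden_hard = 5, seed = 1)
  mh <- build_hard_sharing(mc)
  tcn_n <- (6 * 4 * 3 + 4) + (4 * 4 * 3 + 4) + (6 * 4 + 4) +
           (4 * 3 * 3 + 3) + (3 * 3 * 3 + 3) + (4 * 3 + 3)
  tower_n <- (30 * 5 + 5) + (5 * 5 + 5) + (5 + 1)
  expect_equal(count_parameters(mh), tcn_n + 3 * tower_n)
})

test_that("all architectures share the forward contract", {
  cfg <- tiny_config()
  x <- random_input(cfg, B = 8)
  for (builder in list(build_hard_sharing, build_mmoe, build_mmoeex)) {
    model <- builder(cfg)
    out <- forward_mtl(model, x)
    expect_equal(dim(out$voltage), c(4, 8))
    expect_length(out$spike_logit, 8)
    expect_true(all(is.finite(out$voltage)) && all(is.finite(out$spike_logit)))
    # batch independence in evaluation mode
    single <- forward_mtl(model, x[, , 3, drop = FALSE])
    expect_equal(single$voltage[, 1], out$voltage[, 3], tolerance = 1e-12)
    expect_error(forward_mtl(model, x[1:3, , , drop = FALSE]), "expected")
  }
})

test_that("gate vectors are normalized softmax outputs for every task", {
  cfg <- tiny_config()
  for (builder in list(build_mmoe, build_mmoeex)) {
    model <- builder(cfg)
    out <- forward_mtl(model, random_input(cfg, B = 5))
    sums <- apply(out$gates, c(2, 3), sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
    expect_true(all(out$gates >= 0))
  }
})

test_that("a single-expert MMoE reduces to tower(expert(x))", {
  cfg <- model_config(3, history = 12, level_channels = c(4, 3),
                      kernel_size = 3, dropout = 0, n_experts = 1, seed = 2)
  model <- build_mmoe(cfg)
  x <- random_input(cfg, B = 2)
  out <- forward_mtl(model, x)
  feat <- tcn_forward(model$experts[[1]], x)
  dim(feat) <- c(cfg$feature_dim, 2)
  direct <- neurondistill:::tower_forward(model$towers[[1]], feat)$out
  expect_equal(out$voltage[1, ], as.numeric(direct), tolerance = 1e-12)
  expect_true(all(out$gates == 1))
})

test_that("MMoEEx exclusivity mask has the contracted structure", {
  # alpha = 0: all-ones mask, function-identical to MMoE at equal seeds
  cfg0 <- tiny_config(alpha_exclusivity = 0)
  m0 <- build_mmoeex(cfg0)
  expect_true(all(m0$mask == 1))
  x <- random_input(cfg0, B = 2)
  expect_identical(forward_mtl(build_mmoe(cfg0), x)$voltage,
                   forward_mtl(m0, x)$voltage)
  # alpha = 1 at full scale: every expert exclusive to exactly one task
  cfg1 <- model_config(639, alpha_exclusivity = 1, seed = 3)
  m1 <- build_mmoeex(cfg1)
  expect_equal(colSums(m1$mask == 0), rep(639, 5), ignore_attr = TRUE)
  expect_equal(sum(m1$mask == 0), 5 * 639)
  expect_equal(colSums(m1$mask), rep(1, 5), ignore_attr = TRUE)
})

test_that("masked gate entries are exactly zero and survive training", {
  cfg <- tiny_config(alpha_exclusivity = 0.5)
  model <- build_mmoeex(cfg)
  masked <- which(model$mask == 0)
  expect_gt(length(masked), 0)
  x <- random_input(cfg, B = 4)
  out <- forward_mtl(model, x)
  for (k in seq_len(cfg$n_tasks)) {
    zero_experts <- which(model$mask[k, ] == 0)
    expect_true(all(out$gates[zero_experts, , k] == 0))
  }
  # one optimization step must not unfreeze the mask
  yv <- matrix(rnorm(4 * 4), 4, 4)
  ys <- c(1, 0, 0, 1)
  layers <- neurondistill:::param_layers(model)
  neurondistill:::adam_init(layers)
  o <- forward_mtl(model, x, train = TRUE, want_cache = TRUE)
  dv <- (2 / 4) * (o$voltage - yv)
  dz <- (1 / 4) * (1 / (1 + exp(-o$spike_logit)) - ys)
  neurondistill:::zero_grads(layers)
  neurondistill:::backward_mtl(model, x, o$cache, dv, dz)
  neurondistill:::adam_step(layers, 1e-3, 1)
  out2 <- forward_mtl(model, x)
  for (k in seq_len(cfg$n_tasks)) {
    zero_experts <- which(model$mask[k, ] == 0)
    expect_true(all(out2$gates[zero_experts, , k] == 0))
  }
})

test_that("mean gate weights summarize and normalize correctly", {
  cfg <- tiny_config()
  model <- build_mmoe(cfg)
  x <- random_input(cfg, B = 6)
  m <- mean_gate_weights(model, x)
  expect_equal(dim(m), c(cfg$n_tasks, cfg$n_experts))
  expect_equal(rowSums(m), rep(1, cfg$n_tasks), tolerance = 1e-12)
  # single sample: means equal that sample's gates
  m1 <- mean_gate_weights(model, x[, , 1, drop = FALSE])
  out1 <- forward_mtl(model, x[, , 1, drop = FALSE])
  expect_equal(m1, t(out1$gates[, 1, ]), tolerance = 1e-12)
  # exclusive expert has zero mean weight outside its task
  cfgx <- tiny_config(alpha_exclusivity = 1)
  mx <- build_mmoeex(cfgx)
  mm <- mean_gate_weights(mx, x)
  for (j in seq_len(cfgx$n_experts))
    expect_equal(sum(mm[, j] > 0), 1)
  expect_error(mean_gate_weights(build_hard_sharing(cfg), x), "hard")
})

test_that("parameter counts are deterministic functions of the config", {
  cfg <- tiny_config()
  expect_equal(count_parameters(build_mmoe(cfg)),
               count_parameters(build_mmoe(cfg)))
})
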