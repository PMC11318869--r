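# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; no stored data files.

.fx <- new.env(parent = emptyenv())

fx_morph <- function() {
  if (is.null(.fx$morph)) .fx$morph <- build_morphology(8, 4, 7)  # 20 comps
  .fx$morph
}

fx_trace <- function() {
  if (is.null(.fx$trace)) {
    m <- fx_morph()
    s <- place_synapses(m)
    e <- sample_event_trains(s, duration = 12000, seed = 11)
    .fx$trace <- run_simulation(m, s, e, duration = 12000)
  }
  .fx$trace
}

fx_dataset <- function() {
  if (is.null(.fx$dataset)) .fx$dataset <- make_dataset(fx_trace(), seed = 2)
  .fx$dataset
}

# a tiny trained soft model over the fixture dataset (3 quick epochs)
fx_trained <- function() {
  if (is.null(.fx$trained)) {
    mc <- model_config(20, level_channels = c(8, 8, 4), n_experts = 2,
                       seed = 4)
    model <- build_mmoe(mc)
    .fx$trained <- train(model, fx_dataset(), epochs = 3, seed = 5)
  }
  .fx$trained
}

tiny_config <- function(...) {
  model_config(4, history = 12, level_channels = c(4, 3), kernel_size = 3,
               dropout = 0, n_experts = 3, seed = 9, ...)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

random_input <- function(cfg, B = 3, seed = 21) {
  set.seed(seed)
  array(rnorm(cfg$in_channels * cfg$history * B),
        c(cfg$in_channels, cfg$history, B))
}
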