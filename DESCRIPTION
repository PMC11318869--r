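Package: neurondistill
Title: Multitask-Learning Surrogates of Multicompartment Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distills the voltage dynamics of biophysically detailed
    multicompartment neuron models into fast multitask neural-network
    surrogates. Provides a self-contained cable-equation simulator
    (passive dendrites, Hodgkin-Huxley soma, conductance synapses driven
    by Poisson presynaptic trains), windowed and spike-balanced dataset
    construction with z-scoring, causal temporal convolutional networks
    used as shared bottoms, experts and a compressor module, three
    multitask architectures (hard parameter sharing, multi-gate
    mixture-of-experts, and its exclusivity variant), a loss-balanced
    task-weighting training loop, expert-diversity metrics (mean,
    determinant and permanent of the normalized pairwise-distance
    matrix), closed-loop autoregressive rollout, and point-source
    extracellular-potential prediction from membrane currents.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
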