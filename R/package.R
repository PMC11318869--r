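#' neurondistill: multitask-learning surrogates of compartmental neuron
#' models
#'
#' Tools to distill the full per-compartment voltage dynamics of a
#' multicompartment neuron model into fast multitask neural-network
#' surrogates, and to carry the predictions forward to extracellular
#' potentials. The package covers the whole pipeline: ground-truth data
#' generation with a compiled cable-equation simulator, balanced windowed
#' dataset construction, three multitask architectures built on causal
#' temporal convolutional networks, training with optional loss-balanced
#' task weighting, expert-diversity analysis, autoregressive rollout, and
#' point-source volume-conductor forward modeling.
#'
#' @useDynLib neurondistill, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"
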