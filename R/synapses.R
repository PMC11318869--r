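#' Place one excitatory and one inhibitory synapse on every compartment
#'
#' Synapses are distributed uniformly over the whole span of the neuron in
#' the sense that every compartment carries exactly one excitatory and one
#' inhibitory conductance synapse, so a morphology with N compartments ends
#' up with 2N synapses. Synapses are single-exponential conductance
#' synapses: excitatory with reversal 0 mV and decay 3 ms, inhibitory with
#' reversal -80 mV and decay 8 ms by default.
#'
#' @param morph an `nd_morphology`.
#' @param synapse_params optional named list overriding defaults
#'   (`exc_reversal`, `exc_tau`, `exc_gpeak`, `inh_reversal`, `inh_tau`,
#'   `inh_gpeak`); conductances in nS, times in ms, reversals in mV.
#' @return An `nd_synapses` data frame with one row per synapse:
#'   `compartment`, `kind`, `reversal`, `peak_conductance`, `tau`.
#' @examples
#' syn <- place_synapses(build_morphology(8, 4, 8))
#' nrow(syn)  # 2 x 21
#' @export
place_synapses <- function(morph, synapse_params = list()) {
  validate_morphology(morph)
  p <- utils::modifyList(default_synapse_params(), synapse_params)
  n <- morph$n_comp
  syn <- data.frame(
    compartment = rep(seq_len(n), each = 2L),
    kind = rep(c("excitatory", "inhibitory"), times = n),
    stringsAsFactors = FALSE)
  exc <- syn$kind == "excitatory"
  syn$reversal <- ifelse(exc, p$exc_reversal, p$inh_reversal)
  syn$peak_conductance <- ifelse(exc, p$exc_gpeak, p$inh_gpeak)
  syn$tau <- ifelse(exc, p$exc_tau, p$inh_tau)
  class(syn) <- c("nd_synapses", "data.frame")
  syn
}

#' Default synaptic parameters
#'
#' Single-exponential conductance synapses. Peak conductances are chosen so
#' that the default Poisson drive (1.4 Hz excitatory, 1.3 Hz inhibitory per
#' synapse) produces both sub- and suprathreshold dendritic dynamics and a
#' somatic firing rate in the low-Hz range on the reduced default morphology.
#'
#' @return named list of synapse defaults.
#' @export
default_synapse_params <- function() {
  list(exc_reversal = 0, exc_tau = 3, exc_gpeak = 1.8,
       inh_reversal = -80, inh_tau = 8, inh_gpeak = 2.5)
}

#' Sample homogeneous Poisson presynaptic spike trains
#'
#' Draws an independent homogeneous Poisson train for every synapse:
#' excitatory synapses at `rate_exc` and inhibitory synapses at `rate_inh`
#' (the defaults, 1.4 Hz and 1.3 Hz, are the standard presynaptic drive for
#' this class of layer-5 pyramidal cell dataset). Event counts are Poisson
#' with mean rate x duration and event times are uniform on `[0, duration)`.
#'
#' @param synapses an `nd_synapses` table from [place_synapses()].
#' @param rate_exc,rate_inh firing rates in Hz (non-negative).
#' @param duration trace duration in ms (positive).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return An `nd_event_trains` object: list with `times` (per-synapse
#'   sorted numeric vectors, ms), `duration`, `rate_exc`, `rate_inh`, `seed`.
#' @examples
#' syn <- place_synapses(build_morphology(4, 2, 4))
#' ev <- sample_event_trains(syn, 1.4, 1.3, duration = 1000, seed = 1)
#' lengths(ev$times)[1:4]
#' @export
sample_event_trains <- function(synapses, rate_exc = 1.4, rate_inh = 1.3,
                                duration, seed = 1L) {
  stopifnot(inherits(synapses, "nd_synapses"))
  if (rate_exc < 0 || rate_inh < 0) stop("rates must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  rates <- ifelse(synapses$kind == "excitatory", rate_exc, rate_inh)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- stats::rpois(length(rates), rates * duration / 1000)
  times <- lapply(counts, function(k) sort(stats::runif(k, 0, duration)))
  structure(list(times = times, duration = duration,
                 rate_exc = rate_exc, rate_inh = rate_inh, seed = seed),
            class = "nd_event_trains")
}

#' @export
print.nd_event_trains <- function(x, ...) {
  cat("<nd_event_trains> ", length(x$times), " synapses, ",
      sum(lengths(x$times)), " events over ", x$duration, " ms\n", sep = "")
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
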