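#' Run a compartmental cable simulation
#'
#' Integrates the discretized cable equation on the morphology tree with
#' single-exponential conductance synapses on every compartment and, by
#' default, Hodgkin-Huxley Na+/K+ spiking currents on the soma (dendrites
#' are passive). Integration is backward (implicit) Euler on the linear
#' cable/conductance terms with channel gates advanced by exponential Euler
#' each step, solved exactly per step with a Hines-ordered tree elimination;
#' this is unconditionally stable for the stiff cable system.
#'
#' The stored membrane current of a compartment is its net axial inflow
#' (which, by charge conservation, equals the total transmembrane current);
#' summed over all compartments it telescopes to exactly zero.
#'
#' @param morph an `nd_morphology`.
#' @param synapses an `nd_synapses` table.
#' @param events an `nd_event_trains` object (times within `[0, duration)`).
#' @param duration simulated time in ms; must be a multiple of `record_dt`.
#' @param internal_dt solver step in ms (default 0.025); must divide
#'   `record_dt`.
#' @param record_dt recording step in ms (default 1).
#' @param active_soma logical; `FALSE` turns off the somatic spiking
#'   currents (fully passive model).
#' @param inject optional list `list(compartment =, amplitude_nA =)` for a
#'   constant current injection.
#' @param hh_params named list overriding the somatic channel defaults
#'   (`gna_density`, `gk_density` in mS/cm2; `ena`, `ek` in mV).
#' @param v_init initial voltage (mV); defaults to the leak reversal.
#' @param v_bounds length-2 physiological bound (mV); the solver aborts with
#'   an error naming the first offending timestep if exceeded.
#' @param spike_threshold,spike_refractory somatic spike detection
#'   parameters (mV, ms) applied to the recorded soma trace.
#' @return An `nd_trace`: list with `voltage` and `membrane_current`
#'   matrices `[timesteps x compartments]` (mV, nA; row k is time
#'   `k * record_dt`), `somatic_spike_times` (ms), `record_dt`,
#'   `internal_dt`, `duration`, and references to the inputs.
#' @examples
#' m <- build_morphology(4, 2, 6)
#' s <- place_synapses(m)
#' e <- sample_event_trains(s, duration = 500, seed = 1)
#' tr <- run_simulation(m, s, e, duration = 500)
#' dim(tr$voltage)
#' @export
run_simulation <- function(morph, synapses, events, duration,
                           internal_dt = 0.025, record_dt = 1,
                           active_soma = TRUE, inject = NULL,
                           hh_params = list(),
                           v_init = NULL, v_bounds = c(-120, 60),
                           spike_threshold = -20, spike_refractory = 3) {
  validate_morphology(morph)
  stopifnot(inherits(synapses, "nd_synapses"),
            inherits(events, "nd_event_trains"))
  if (abs(record_dt / internal_dt - round(record_dt / internal_dt)) > 1e-9)
    stop("internal_dt must divide record_dt")
  if (abs(duration / record_dt - round(duration / record_dt)) > 1e-9)
    stop("duration must be a multiple of record_dt")
  if (any(unlist(lapply(events$times, function(t)
    length(t) && (min(t) < 0 || max(t) >= events$duration)))))
    stop("event times must lie within [0, duration)")

  hh <- utils::modifyList(
    list(gna_density = 120, gk_density = 36, ena = 50, ek = -77), hh_params)
  comp <- morph$compartments
  soma_area <- comp$area[morph$soma_index]
  gna_nS <- hh$gna_density * 1e-3 * soma_area * 10   # mS/cm² -> nS
  gk_nS <- hh$gk_density * 1e-3 * soma_area * 10
  if (is.null(v_init)) v_init <- morph$leak_reversal

  inj_comp <- -1L
  inj_nA <- 0
  if (!is.null(inject)) {
    inj_comp <- as.integer(inject$compartment) - 1L
    inj_nA <- inject$amplitude_nA
    stopifnot(inj_comp >= 0, inj_comp < morph$n_comp)
  }

  record_every <- as.integer(round(record_dt / internal_dt))
  n_steps <- as.integer(round(duration / internal_dt))

  parent0 <- ifelse(comp$parent < 0L, -1L, as.integer(comp$parent) - 1L)
  # conductances enter the solver in µS so that g·V terms are in nA,
  # consistent with C[nF]·dV/dt[mV/ms] = nA and injected currents in nA
  out <- .cable_simulate(
    parent = parent0,
    cap_nF = comp$cap_nF, g_leak_nS = comp$g_leak_nS * 1e-3,
    e_leak = morph$leak_reversal, g_axial_nS = comp$g_axial_nS * 1e-3,
    soma_index = morph$soma_index - 1L, active_soma = active_soma,
    gna_nS = gna_nS * 1e-3, gk_nS = gk_nS * 1e-3, ena = hh$ena, ek = hh$ek,
    syn_comp = as.integer(synapses$compartment) - 1L,
    syn_e = synapses$reversal,
    syn_gpeak = synapses$peak_conductance * 1e-3,
    syn_tau = synapses$tau, syn_events = events$times,
    dt = internal_dt, record_every = record_every, n_steps = n_steps,
    inject_comp = inj_comp, inject_nA = inj_nA,
    v_init = v_init, v_lo = v_bounds[1], v_hi = v_bounds[2])

  trace <- structure(list(
    voltage = out$voltage, membrane_current = out$membrane_current,
    record_dt = record_dt, internal_dt = internal_dt, duration = duration,
    soma_index = morph$soma_index, morphology = morph,
    synapses = synapses, events = events,
    spike_threshold = spike_threshold, spike_refractory = spike_refractory),
    class = "nd_trace")
  trace$somatic_spike_times <- detect_somatic_spikes(
    trace, threshold_mV = spike_threshold, refractory_ms = spike_refractory)
  trace
}

#' @export
print.nd_trace <- function(x, ...) {
  cat("<nd_trace> ", nrow(x$voltage), " x ", ncol(x$voltage),
      " (timesteps x compartments), dt ", x$record_dt, " ms, ",
      length(x$somatic_spike_times), " somatic spikes\n", sep = "")
  invisible(x)
}

#' Detect somatic spikes by threshold crossing
#'
#' Spike times are upward crossings of `threshold_mV` in the recorded soma
#' voltage, with successive spikes separated by at least `refractory_ms`.
#'
#' @param trace an `nd_trace` (or a plain numeric soma-voltage vector with
#'   attribute-free 1-based indexing at `record_dt` spacing).
#' @param threshold_mV crossing threshold (default -20 mV).
#' @param refractory_ms minimum separation between detected spikes.
#' @param record_dt recording step, taken from the trace when available.
#' @return numeric vector of spike times in ms.
#' @export
detect_somatic_spikes <- function(trace, threshold_mV = -20,
                                  refractory_ms = 3, record_dt = NULL) {
  if (inherits(trace, "nd_trace")) {
    v <- trace$voltage[, trace$soma_index]
    record_dt <- trace$record_dt
  } else {
    v <- as.numeric(trace)
    if (is.null(record_dt)) record_dt <- 1
  }
  above <- v >= threshold_mV
  up <- which(above & !c(FALSE, above[-length(above)]))
  times <- up * record_dt
  keep <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last >= refractory_ms) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep
}

#' Reconstruct membrane currents from voltages
#'
#' Computes, per compartment and timestep, the net axial inflow
#' `I_n(t) = sum over neighbours m of g_axial(n,m) (V_m(t) - V_n(t))`,
#' which equals the total transmembrane current of the compartment. The
#' per-timestep sum over compartments is exactly zero (telescoping pairwise
#' cancellation), so reconstructed currents are usable for volume-conductor
#' forward models even when the voltages come from a surrogate model.
#'
#' @param voltage matrix `[timesteps x compartments]` in mV.
#' @param morph the `nd_morphology` the voltages refer to.
#' @return matrix `[timesteps x compartments]` of membrane currents in nA.
#' @export
reconstruct_membrane_currents <- function(voltage, morph) {
  validate_morphology(morph)
  if (ncol(voltage) != morph$n_comp)
    stop("voltage has ", ncol(voltage), " columns but morphology has ",
         morph$n_comp, " compartments")
  comp <- morph$compartments
  im <- matrix(0, nrow(voltage), ncol(voltage))
  for (i in 2:morph$n_comp) {
    p <- comp$parent[i]
    # g in µS so that µS · mV = nA
    flow <- comp$g_axial_nS[i] * 1e-3 * (voltage[, p] - voltage[, i])
    im[, i] <- im[, i] + flow
    im[, p] <- im[, p] - flow
  }
  im
}
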