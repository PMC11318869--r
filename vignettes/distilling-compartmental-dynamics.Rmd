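---
title: "Distilling compartmental neuron dynamics into multitask surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distilling compartmental neuron dynamics into multitask surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Biophysically detailed multicompartment neuron models are accurate but
expensive: every compartment carries coupled nonlinear ODEs that must be
integrated at tens of microseconds. A *surrogate* (or distilled) model is a
neural network trained to map a short history of the neuron's state and its
synaptic input to the state one time step later. Once trained, the surrogate
replaces the integrator at inference time, and because a network evaluates a
whole batch at once, the batch dimension doubles as a population of
independently simulated neurons.

Predicting *every* compartment's membrane potential — rather than the soma
alone — turns the problem into multitask learning (MTL): one task per
compartment voltage, plus a binary task for the presence of a somatic spike
in the predicted millisecond. This package implements that whole pipeline in
R: the ground-truth simulator, dataset construction, three MTL architectures,
training, expert-diversity analysis, autoregressive rollout, and
extracellular-potential prediction.

## The ground-truth simulator

The simulator is deliberately a *reduced, documented stand-in* for detailed
cortical layer-5 pyramidal-cell models, built so that its statistics match
the structure such models produce (sub- and suprathreshold dendritic
voltages, somatic spikes, per-compartment synaptic event trains) while
remaining analytically testable at desk scale:

* **Morphology** (`build_morphology`): a deterministic tree with one somatic
  root, an apical trunk, single-compartment oblique twigs along the trunk,
  and two basal chains. Region labels (`soma`, `basal`, `oblique`,
  `apical`) mirror the taxonomy used for pyramidal-cell reconstructions.
  The default passive constants are textbook values: axial resistivity
  100 Ω·cm, specific capacitance 1 µF/cm², leak 5·10⁻⁵ S/cm² (membrane
  time constant 20 ms), leak reversal −70 mV.
* **Membrane dynamics**: dendrites are passive; the soma carries classic
  Hodgkin–Huxley Na⁺/K⁺ currents (120 and 36 mS/cm², reversals +50 and
  −77 mV). This preserves the essential data feature — a spiking soma
  embedded in a passive cable — without the ten ionic currents and Ca²⁺
  dynamics of full layer-5 models, which are out of scope.
* **Synapses** (`place_synapses`): exactly one excitatory and one
  inhibitory single-exponential conductance synapse per compartment
  (excitatory: E = 0 mV, τ = 3 ms; inhibitory: E = −80 mV, τ = 8 ms), so a
  morphology with N compartments has 2N synapses. Presynaptic trains are
  independent homogeneous Poisson processes at 1.4 Hz (excitatory) and
  1.3 Hz (inhibitory).
* **Peak conductances** default to 1.8 nS (excitatory) and 2.5 nS
  (inhibitory). These are at the upper end of the physiological single-
  synapse range because the desk-scale morphology carries only ~40
  synapses rather than the thousands on a real cell; with these values the
  default 20-compartment neuron fires at ≈ 3 Hz across seeds, comfortably
  inside the 0.5–20 Hz band we consider realistic spontaneous activity,
  and spends most of its time subthreshold.
* **Integration** (`run_simulation`): backward (implicit) Euler on the
  cable/conductance terms with gates advanced by exponential Euler,
  solved exactly per step by a Hines-ordered tree elimination (O(N) per
  step, unconditionally stable). Internal step 0.025 ms, recorded at
  1 ms. All quantities are kept in mV/ms/nA/nS/µm; conductances enter the
  solver in µS so that g·V products are in nA, consistent with nF·mV/ms.
* **Spike detection**: upward crossings of −20 mV separated by at least
  3 ms. The reference simulators do not publish their criterion; these are
  declared defaults, not inferred ones.
* **Membrane currents** are stored as net axial inflow, which equals the
  total transmembrane current and telescopes to exactly zero over the
  cell — the property the extracellular forward model relies on.

Two analytic oracles pin the implementation down: with synapses silent and
the soma passive, the cell sits exactly at the leak reversal; and a steady
current into the sealed tip of an unbranched passive cable reproduces the
finite-cable attenuation profile V(x) = V(0)·cosh((L−x)/λ)/cosh(L/λ) to
better than 2 % per compartment.

What the generator does *not* emulate: active dendritic nonlinearities
(Ca²⁺ spikes, backpropagation-activated events), synaptic plasticity and
receptor kinetics beyond a single exponential, and morphological detail at
the level of reconstructed cells. Tests passing on this generator therefore
demonstrate that the learning pipeline works on data with the right
structure; they do not certify performance on recordings from full
biophysical models.

## Dataset construction

`make_windows` slices a trace into causal samples: a 100 ms history of all
3N channels (N z-scored voltage channels followed by 2N raw synaptic event
counts per 1 ms bin) and a 1 ms target (all N voltages plus the binary
somatic-spike flag for the target bin). Bins are half-open, `[k−1, k)` ms,
and a window's history never overlaps its own target bin.

Because subthreshold dynamics dominate raw traces, `balance_dataset` keeps
every spiking-target window and subsamples non-spiking windows without
replacement so that one third of retained targets contain a spike.
Balancing is the only subsampling step (stride 1 before it), performed
globally over the windows of a split.

Z-scoring statistics are per compartment, fitted on the training split
only (`fit_standardizer`) and reused unchanged on validation data; event
counts are never standardized. The train/validation split is made at the
level of whole traces (80/20) to avoid temporal leakage; when only one
trace exists, it is split by time with the first 80 % for training, which
preserves the same no-leakage property at desk scale.

## Architectures

All three models read `[3N × 100]` inputs and emit one output per task
(N z-scored voltages and one spike logit), built from a shared component,
the **causal temporal convolutional network** (TCN): three residual levels
of channel sizes 32/16/8 with kernel 10, dilations 1/2/4, dropout 0.2, and
two causal convolutions per level plus a 1×1 shortcut where channel counts
change. The standard TCN design leaves block internals to the implementer;
we fix two convolutions per level because the 14 M / 12 M reference
parameter totals (below) are only consistent with that choice, making it
load-bearing. The
activation after the final residual sum is a sigmoid rather than a ReLU,
so the sequence representation lies in (0, 1).

* **Hard parameter sharing (MH)**: one shared TCN bottom; each task owns a
  three-layer ELU tower. Towers read the *flattened full sequence*
  (8 × 100 = 800 features), not the last timestep — again required for
  consistency with the reference totals — through 800→25→25→1.
* **MMoE**: five expert TCNs plus one *compressor* TCN. Each task's gate
  is a linear map from the flattened compressor output to five expert
  logits followed by a softmax; the task representation is the gate-
  weighted sum of flattened expert outputs, fed to an 800→10→10→1 tower.
  Routing through the compressor fixes the gate parameter count regardless
  of the raw input size, which is what makes the soft models viable at
  1917 input channels.
* **MMoEEx**: MMoE plus a frozen exclusivity mask drawn once at
  initialization: ⌈α·E⌉ experts are each assigned one uniformly chosen
  task, and their gate connections to all other tasks are fixed at exactly
  zero for the life of the model (implemented as −∞ logits, so masked
  softmax outputs are exactly zero and gradients never touch them). At
  α = 0 the model is function-identical to MMoE at equal seeds. At α = 1
  with more tasks than experts, most tasks retain no expert: such rows
  yield all-zero gates and the tower sees a zero representation. The
  default α = 0.2 keeps every task's gate row a proper softmax. We draw
  the mask once rather than per batch because redrawing would break the
  frozen-zero invariant that makes exclusivity meaningful.

At the full 639-compartment scale these choices give 13,944,072 trainable
parameters for MH and 11,939,632 for MMoE — rounding to the reference
14 M and 12 M.

The number of experts (five) follows common practice in gate-weight
analyses of this architecture family; the literature leaves it free.

## Training

The loss is
`w_spike · BCE_logits(ŷ_spike, y_spike) + Σ_i w_i · MSE(ŷ_i, y_i)`,
with unit weights by default; per-task components are returned so that
**loss-balanced task weighting** (LBTW) can reweight them: at each batch B
of an epoch, `w_task = (L_task,B / L_task,0)^α`, where `L_task,0` is
captured at the epoch's first batch (weights there are 1). At α = 0 this
reduces to standard multitask training; zero initial losses degenerate to
weight 1. A spike-importance factor γ multiplies `w_spike` as a constant;
it defaults to 1 and gives the spike task an adjustable importance
without changing the loss structure.

Optimization is Adam (default learning rate 10⁻³, batch 32) with global
gradient-norm clipping at 5; these are package defaults chosen for
stability. Desk-scale distillation runs
use 3·10⁻³, which converges substantially faster on the reduced networks.
Validation is evaluated every epoch and the best-validation parameters are
checkpointed; reloading a checkpoint reproduces the validation loss
bit-for-bit. Runs are fully seeded and deterministic on a fixed BLAS.

`evaluate` reports, besides the loss vector, millivolt-scale summaries
obtained by inverting the z-scoring: pooled voltage RMSE, the pooled
standard deviation of the target voltages, and their ratio — the
scale-free fidelity number used throughout.

## Expert diversity

The diversity of two experts n, m is the summed squared difference of
their flattened post-sigmoid representations over a fixed probe set
(`expert_distance`). The pairwise matrix is normalized by its maximum
entry — so "1" literally means "the most different pair" and a zero matrix
(weight-identical experts) stays zero — and summarized by the mean over
all M² entries (diagonal included; including it only rescales the score),
the determinant, and the permanent. The permanent is computed exactly with
Ryser's inclusion–exclusion formula, which is exact and affordable for the
expert counts used here (M ≤ 20); it dominates |det| for elementwise
nonnegative matrices, a property the tests assert on random matrices.

## Rollout and extracellular potentials

`rollout` simulates forward autoregressively: a rolling 100 ms buffer is
advanced one millisecond at a time, with the model's own de-z-scored
prediction fed back (**closed loop**) or replaced by ground truth
(**teacher forcing** — useful to isolate one-step error from error
accumulation; with teacher forcing the rollout reproduces independent
per-step forward passes exactly). Synaptic event channels always come from
the predetermined trains; the spike logit is not fed back, since inputs
contain only voltages and events — somatic spikes can be read off the
predicted soma voltage by thresholding.

Predicted voltages yield membrane currents through the same net-axial-
inflow identity the simulator uses (`reconstruct_membrane_currents`), and
currents yield extracellular potentials through a point-source volume
conductor: φ(r, t) = (4πσ)⁻¹ Σ_n I_n(t)/|r − r_n| with σ = 0.3 S/m, each
compartment a point source at its midpoint (line sources are a documented
non-goal). With currents in nA and distances in µm the result is in µV;
1 nA at 100 µm gives 2.653 µV. Because reconstructed currents sum to zero
exactly, far-field potentials decay faster than 1/r, as a dipole should.

## Numerical choices and degenerate inputs

* Backward Euler is used for the cable system because the axial coupling
  is stiff; gates use exponential Euler at the current voltage.
* The solver aborts (naming the first offending timestep) if any voltage
  leaves the configured physiological bounds ([−120, 60] mV).
* Zero-variance compartments make z-scoring impossible and raise an error
  rather than silently producing infinities.
* Dropout is element-wise; evaluation mode is deterministic.
* Softmax gates treat −∞ logits exactly (masked entries are 0, fully
  masked rows are all-zero rather than NaN).
* All RNG flows through explicit seeds; fixture- and model-building
  functions save and restore the caller's RNG state.

## Problem sizes

The shipped tests and examples run at desk scale by design: morphologies
of 20–50 compartments, traces of 12–60 s, reduced networks (two experts,
8/8/4 channels) trained for tens of epochs, and the full 639-compartment
configuration instantiated only to verify parameter counts. These sizes
are the package's chosen experimental conditions; the architecture code
itself is size-agnostic. On the default 20-compartment neuron with 60 s of
data, the reduced MMoE reaches a validation RMSE/SD ratio of ≈ 0.19–0.25
depending on seeds — the qualitative analogue, not a reproduction, of the
fidelity reported for the full-scale problem.

## Known limitations

* The simulator's simplified physiology means distillation difficulty is
  lower than on full layer-5 models; absolute losses are not comparable.
* Training is CPU-bound R/BLAS; full-scale training (millions of
  parameters, tens of gigabytes of data) is out of scope.
* The binary somatic-spike task is carried through the loss but is hard
  to learn at realistic spike sparsity; voltage thresholding of the
  predicted soma trace is the recommended spike readout.
* Checkpoints serialize with R's native format; no cross-language format
  is provided.
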