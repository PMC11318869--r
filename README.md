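# neurondistill

Multitask-learning surrogates of multicompartment neuron models, in R.

Simulating a biophysically detailed neuron — hundreds of electrically
coupled compartments with nonlinear membrane currents — is accurate but
slow. `neurondistill` *distills* such a model into a neural-network
surrogate that predicts the membrane potential of **every** compartment one
millisecond at a time, given a 100 ms history of all voltages and incoming
synaptic events. Because one trained network evaluates a whole batch at
once, the inference batch dimension can be read directly as a population of
simultaneously simulated neurons, and the predicted voltages carry forward
to membrane currents and extracellular potentials (LFP-type signals).

The package is the complete pipeline:

* a self-contained **cable-equation simulator** (passive dendrites,
  Hodgkin–Huxley soma, one excitatory + one inhibitory conductance synapse
  per compartment driven by Poisson trains at 1.4/1.3 Hz; backward-Euler /
  Hines integration, compiled core) that generates the ground truth;
* **dataset construction**: causal (100 ms → 1 ms) windows over 3N
  channels, spike-balancing to a one-third spiking-target fraction,
  per-compartment z-scoring fitted on training data only;
* three **multitask architectures** over a causal temporal convolutional
  network (TCN; levels 32/16/8, kernel 10, dilations 1/2/4, final
  sigmoid): hard parameter sharing (MH), multi-gate mixture-of-experts
  (MMoE) with a *compressor* TCN feeding all gates, and MMoEEx with a
  frozen expert-exclusivity mask;
* **training** of the multitask loss
  `w_spike·BCE_logits(ŷ_spike, y_spike) + Σ_i w_i·MSE(ŷ_i, y_i)` with Adam
  and optional loss-balanced task weighting
  `w_task = (L_task,B / L_task,0)^α`;
* **expert-diversity** metrics: pairwise distances
  `d(n,m) = Σ_i (f_n(x_i) − f_m(x_i))²`, the max-normalized diversity
  matrix `D`, and its mean, determinant, and permanent (exact Ryser);
* closed-loop / teacher-forced **rollout** and a point-source
  volume-conductor forward model
  `φ(r,t) = (4πσ)⁻¹ Σ_n I_n(t)/|r − r_n|`.

At the full 639-compartment configuration the architectures count
13,944,072 (MH) and 11,939,632 (MMoE) trainable parameters — 14 M and 12 M
to the nearest million.

## Worked example

Distill a 20-compartment neuron (8 basal, 4 oblique, 7 apical + soma) from
60 s of simulated activity into a reduced MMoE (2 experts, 8/8/4 TCN
channels):

```r
library(neurondistill)

m  <- build_morphology(8, 4, 7)                   # 20 compartments
s  <- place_synapses(m)                           # 40 synapses
e  <- sample_event_trains(s, duration = 60000, seed = 11)
tr <- run_simulation(m, s, e, duration = 60000)
length(tr$somatic_spike_times)
#> [1] 133                                         # ~2.2 Hz somatic rate

ds <- make_dataset(tr, seed = 2)                  # balanced, z-scored
ds
#> <nd_dataset> 339 train / 60 validation windows, 20 compartments

mc  <- model_config(20, level_channels = c(8, 8, 4), n_experts = 2,
                    seed = 4)
fit <- train(build_mmoe(mc), ds, epochs = 30, lr = 3e-3, seed = 5)
ev  <- evaluate(fit$model, ds)
round(c(rmse_mV = ev$rmse_mV, sd_mV = ev$data_sd_mV,
        ratio = ev$rmse_over_sd), 3)
#>  rmse_mV    sd_mV    ratio
#>    8.674   44.867    0.193
```

The ratio is the pooled validation voltage RMSE over the pooled standard
deviation of the target voltages, both in mV after inverting the
z-scoring: the surrogate's error is about a fifth of the signal's spread.
(The spread is large because balanced targets include spike bins.) From
here, `rollout()` continues the neuron autoregressively,
`reconstruct_membrane_currents()` turns predicted voltages into membrane
currents (they sum to zero per timestep by construction), and
`extracellular_potential()` maps currents to µV-scale potentials at
arbitrary electrode positions.

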