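#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Classic Hodgkin-Huxley gating rate functions (voltage in mV, rates in 1/ms).
static inline double vtrap(double x, double y) {
  // x / (exp(x / y) - 1) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

static inline double alpha_m(double v) { return 0.1 * vtrap(-(v + 40.0), 10.0); }
static inline double beta_m(double v)  { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double beta_h(double v)  { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }
static inline double alpha_n(double v) { return 0.01 * vtrap(-(v + 55.0), 10.0); }
static inline double beta_n(double v)  { return 0.125 * std::exp(-(v + 65.0) / 80.0); }

// Backward-Euler integration of a compartmental cable with conductance
// synapses and (optionally) Hodgkin-Huxley Na+/K+ currents on the soma.
//
// The tree is solved exactly per step with a Hines-ordered elimination;
// compartments must be ordered so that parent[i] < i (root has parent -1).
// Units: mV, ms, nA, nS, nF, µm throughout.
//
// [[Rcpp::export(name = ".cable_simulate")]]
List cable_simulate(IntegerVector parent,        // 0-based, -1 for root
                    NumericVector cap_nF,
                    NumericVector g_leak_nS,
                    double e_leak,
                    NumericVector g_axial_nS,    // conductance to parent, 0 for root
                    int soma_index,              // 0-based
                    bool active_soma,
                    double gna_nS, double gk_nS, double ena, double ek,
                    IntegerVector syn_comp,      // 0-based
                    NumericVector syn_e, NumericVector syn_gpeak,
                    NumericVector syn_tau,
                    List syn_events,             // per-synapse sorted times (ms)
                    double dt, int record_every, int n_steps,
                    int inject_comp,             // 0-based, -1 = none
                    double inject_nA,
                    double v_init,
                    double v_lo, double v_hi) {
  const int n = parent.size();
  const int n_syn = syn_comp.size();
  const int n_rec = n_steps / record_every;

  NumericMatrix voltage(n_rec, n);
  NumericMatrix imembrane(n_rec, n);

  std::vector<double> v(n, v_init), g_syn(n_syn, 0.0);
  std::vector<int> ev_ptr(n_syn, 0);
  std::vector<const double*> ev_ptr_data(n_syn);
  std::vector<int> ev_len(n_syn);
  for (int s = 0; s < n_syn; ++s) {
    NumericVector t = syn_events[s];
    ev_ptr_data[s] = t.size() ? REAL(t) : nullptr;
    ev_len[s] = t.size();
  }

  // soma gating variables at steady state for v_init
  double m = alpha_m(v_init) / (alpha_m(v_init) + beta_m(v_init));
  double h = alpha_h(v_init) / (alpha_h(v_init) + beta_h(v_init));
  double ng = alpha_n(v_init) / (alpha_n(v_init) + beta_n(v_init));

  std::vector<double> syn_decay(n_syn);
  for (int s = 0; s < n_syn; ++s) syn_decay[s] = std::exp(-dt / syn_tau[s]);

  std::vector<double> d(n), u(n), rhs(n), cdt(n);
  for (int i = 0; i < n; ++i) cdt[i] = cap_nF[i] / dt;

  // static part of the diagonal: C/dt + g_leak + sum of axial conductances
  std::vector<double> d0(n);
  for (int i = 0; i < n; ++i) d0[i] = cdt[i] + g_leak_nS[i] + g_axial_nS[i];
  for (int i = 0; i < n; ++i)
    if (parent[i] >= 0) d0[parent[i]] += g_axial_nS[i];

  for (int step = 0; step < n_steps; ++step) {
    const double t_next = (step + 1) * dt;

    // update soma gates with the current voltage (exponential Euler)
    double g_na_now = 0.0, g_k_now = 0.0;
    if (active_soma) {
      const double vs = v[soma_index];
      const double am = alpha_m(vs), bm = beta_m(vs);
      const double ah = alpha_h(vs), bh = beta_h(vs);
      const double an = alpha_n(vs), bn = beta_n(vs);
      m = am / (am + bm) + (m - am / (am + bm)) * std::exp(-dt * (am + bm));
      h = ah / (ah + bh) + (h - ah / (ah + bh)) * std::exp(-dt * (ah + bh));
      ng = an / (an + bn) + (ng - an / (an + bn)) * std::exp(-dt * (an + bn));
      g_na_now = gna_nS * m * m * m * h;
      g_k_now = gk_nS * ng * ng * ng * ng;
    }

    // advance synaptic conductances to t_next, consuming events in (t, t_next]
    for (int i = 0; i < n; ++i) {
      d[i] = d0[i];
      rhs[i] = cdt[i] * v[i] + g_leak_nS[i] * e_leak;
    }
    for (int s = 0; s < n_syn; ++s) {
      g_syn[s] *= syn_decay[s];
      while (ev_ptr[s] < ev_len[s] && ev_ptr_data[s][ev_ptr[s]] <= t_next) {
        g_syn[s] += syn_gpeak[s];
        ++ev_ptr[s];
      }
      const int c = syn_comp[s];
      d[c] += g_syn[s];
      rhs[c] += g_syn[s] * syn_e[s];
    }
    if (active_soma) {
      d[soma_index] += g_na_now + g_k_now;
      rhs[soma_index] += g_na_now * ena + g_k_now * ek;
    }
    if (inject_comp >= 0) rhs[inject_comp] += inject_nA;

    // Hines elimination (children before parents) and back-substitution
    for (int i = n - 1; i >= 1; --i) {
      const int p = parent[i];
      const double g = g_axial_nS[i];
      d[p] -= g * g / d[i];
      rhs[p] += g * rhs[i] / d[i];
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) v[i] = (rhs[i] + g_axial_nS[i] * v[parent[i]]) / d[i];

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(v[i]) || v[i] < v_lo || v[i] > v_hi)
        stop("simulation diverged at t = %f ms (compartment %d, V = %f mV)",
             t_next, i + 1, v[i]);
    }

    if ((step + 1) % record_every == 0) {
      const int r = (step + 1) / record_every - 1;
      for (int i = 0; i < n; ++i) voltage(r, i) = v[i];
      // membrane current = net axial inflow (telescopes to zero over the cell)
      for (int i = 1; i < n; ++i) {
        const int p = parent[i];
        const double flow = g_axial_nS[i] * (v[p] - v[i]); // nA into i
        imembrane(r, i) += flow;
        imembrane(r, p) -= flow;
      }
    }
  }

  return List::create(_["voltage"] = voltage, _["membrane_current"] = imembrane);
}
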