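// Core loops of the chain simulator: fixed-step (first-order Euler)
// integration of conductance-based LIF pools with kinetic AMPA/NMDA/GABA
// receptor channels, and the event-driven STDP processor with
// activity-dependent synaptic efficacy.  All randomness lives in R; these
// routines are deterministic given their inputs.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double mg_unblock(double V, double Mg, double K, double gamma) {
  return 1.0 / (1.0 + (Mg / K) * std::exp(-gamma * V));
}

// y[post] += sum_pre W[post, pre] * s[pre]  for a CSC matrix (cols = pre).
// Columns whose gating is (numerically) closed are skipped.
static void accum_csc(const IntegerVector& p, const IntegerVector& i,
                      const NumericVector& x, const NumericVector& s,
                      std::vector<double>& y) {
  const int ncol = p.size() - 1;
  for (int j = 0; j < ncol; ++j) {
    const double sj = s[j];
    if (sj < 1e-12) continue;
    for (int k = p[j]; k < p[j + 1]; ++k) y[i[k]] += x[k] * sj;
  }
}

// Advance the network by n_steps of size dt starting at t0.
//
// net: list(n, pool_of (0-based), WleP/WleI/WleX, WliP/WliI/WliX,
//           WinP/WinI/WinX  (CSC triplets, rows = post, cols = pre),
//           VL, Vthr, Vreset, C_m (nF), gL, tauref,
//           g_ampa, a_ampa, b_ampa, g_nmda, a_nmda, b_nmda, Mg, mgK, mgGamma,
//           g_gaba, E_gaba, a_gaba, b_gaba, g_ext, chw (3 channel weights),
//           Tamp, Tdur, n_pools)
// st:  list(V, s_ampa, s_nmda, s_gaba, s_ext (n_ch x n), pulse_end,
//           ext_pulse_end (n_ch x n), refr)
// ext: list of n_ch lists (one per external channel), each with sorted `t`
//      and 1-based `id` of external spikes falling inside this chunk.
//
// Per step (explicit scheme): consume external spikes; evaluate currents
// from start-of-step V and s; advance V / detect spikes; advance gating.
// [[Rcpp::export]]
List cpp_run_chunk(List net, List st, List ext, double t0, int n_steps,
                   double dt, bool record_currents) {
  const int n = as<int>(net["n"]);
  const IntegerVector pool_of = net["pool_of"];
  const int n_pools = as<int>(net["n_pools"]);

  const IntegerVector WleP = net["WleP"], WleI = net["WleI"];
  const NumericVector WleX = net["WleX"];
  const IntegerVector WliP = net["WliP"], WliI = net["WliI"];
  const NumericVector WliX = net["WliX"];
  const IntegerVector WinP = net["WinP"], WinI = net["WinI"];
  const NumericVector WinX = net["WinX"];

  const double VL = net["VL"], Vthr = net["Vthr"], Vreset = net["Vreset"];
  const double C_pF = 1000.0 * as<double>(net["C_m"]);
  const double gL = net["gL"], tauref = net["tauref"];
  const double g_ampa = net["g_ampa"], a_ampa = net["a_ampa"], b_ampa = net["b_ampa"];
  const double g_nmda = net["g_nmda"], a_nmda = net["a_nmda"], b_nmda = net["b_nmda"];
  const double Mg = net["Mg"], mgK = net["mgK"], mgGamma = net["mgGamma"];
  const double g_gaba = net["g_gaba"], E_gaba = net["E_gaba"];
  const double a_gaba = net["a_gaba"], b_gaba = net["b_gaba"];
  const double g_ext = net["g_ext"];
  const NumericVector chw = net["chw"];
  const double Tamp = net["Tamp"], Tdur = net["Tdur"];

  NumericVector V = clone(as<NumericVector>(st["V"]));
  NumericVector s_ampa = clone(as<NumericVector>(st["s_ampa"]));
  NumericVector s_nmda = clone(as<NumericVector>(st["s_nmda"]));
  NumericVector s_gaba = clone(as<NumericVector>(st["s_gaba"]));
  NumericMatrix s_ext = clone(as<NumericMatrix>(st["s_ext"]));
  NumericVector pulse_end = clone(as<NumericVector>(st["pulse_end"]));
  NumericMatrix ext_pulse_end = clone(as<NumericMatrix>(st["ext_pulse_end"]));
  NumericVector refr = clone(as<NumericVector>(st["refr"]));

  const int n_ch = chw.size();
  std::vector<NumericVector> ext_t(n_ch);
  std::vector<IntegerVector> ext_id(n_ch);
  std::vector<int> ext_ptr(n_ch, 0);
  for (int c = 0; c < n_ch; ++c) {
    List ch = as<List>(ext[c]);
    ext_t[c] = as<NumericVector>(ch["t"]);
    ext_id[c] = as<IntegerVector>(ch["id"]);
  }

  std::vector<double> sp_t;
  std::vector<int> sp_id;
  // current decomposition: prev, local_E, local_I, then one per ext channel
  NumericMatrix cur(n_pools, 3 + n_ch);

  std::vector<double> aLa(n), aLn(n), aIa(n), aIn(n), aG(n);

  for (int step = 0; step < n_steps; ++step) {
    const double t = t0 + step * dt;
    const double t_next = t0 + (step + 1) * dt;

    // external spikes with time in [t, t_next) open/extend transmitter pulses
    for (int c = 0; c < n_ch; ++c) {
      const int m = ext_t[c].size();
      while (ext_ptr[c] < m && ext_t[c][ext_ptr[c]] < t_next) {
        const int id = ext_id[c][ext_ptr[c]] - 1;
        ext_pulse_end(c, id) = ext_t[c][ext_ptr[c]] + Tdur;
        ++ext_ptr[c];
      }
    }

    std::fill(aLa.begin(), aLa.end(), 0.0);
    std::fill(aLn.begin(), aLn.end(), 0.0);
    std::fill(aIa.begin(), aIa.end(), 0.0);
    std::fill(aIn.begin(), aIn.end(), 0.0);
    std::fill(aG.begin(), aG.end(), 0.0);
    accum_csc(WleP, WleI, WleX, s_ampa, aLa);
    accum_csc(WleP, WleI, WleX, s_nmda, aLn);
    accum_csc(WinP, WinI, WinX, s_ampa, aIa);
    accum_csc(WinP, WinI, WinX, s_nmda, aIn);
    accum_csc(WliP, WliI, WliX, s_gaba, aG);

    for (int k = 0; k < n; ++k) {
      const double Vk = V[k];
      const double B = mg_unblock(Vk, Mg, mgK, mgGamma);
      const double I_localE = -g_ampa * Vk * aLa[k] - g_nmda * B * Vk * aLn[k];
      const double I_prev   = -g_ampa * Vk * aIa[k] - g_nmda * B * Vk * aIn[k];
      const double I_localI = -g_gaba * (Vk - E_gaba) * aG[k];
      double I_ext_tot = 0.0;
      const int p = pool_of[k];
      for (int c = 0; c < n_ch; ++c) {
        const double I_c = -g_ext * chw[c] * Vk * s_ext(c, k);
        I_ext_tot += I_c;
        if (record_currents) cur(p, 3 + c) += I_c;
      }
      const double I_syn = I_localE + I_prev + I_localI + I_ext_tot;

      if (record_currents) {
        cur(p, 0) += I_prev;  cur(p, 1) += I_localE; cur(p, 2) += I_localI;
      }

      if (refr[k] > 1e-12) {
        V[k] = Vreset;
        refr[k] = std::max(0.0, refr[k] - dt);
      } else {
        V[k] = Vk + dt * (-gL * (Vk - VL) + I_syn) / C_pF;
        if (V[k] >= Vthr) {
          sp_t.push_back(t_next);
          sp_id.push_back(k + 1);
          V[k] = Vreset;
          refr[k] = tauref;
          pulse_end[k] = t_next + Tdur;  // extend, not stack
        }
      }
    }

    // receptor gating: one Euler step per presynaptic gating variable
    for (int k = 0; k < n; ++k) {
      const double T = (pulse_end[k] > t) ? Tamp : 0.0;
      double s;
      s = s_ampa[k] + dt * (a_ampa * T * (1 - s_ampa[k]) - b_ampa * s_ampa[k]);
      s_ampa[k] = std::min(1.0, std::max(0.0, s));
      s = s_nmda[k] + dt * (a_nmda * T * (1 - s_nmda[k]) - b_nmda * s_nmda[k]);
      s_nmda[k] = std::min(1.0, std::max(0.0, s));
      s = s_gaba[k] + dt * (a_gaba * T * (1 - s_gaba[k]) - b_gaba * s_gaba[k]);
      s_gaba[k] = std::min(1.0, std::max(0.0, s));
      for (int c = 0; c < n_ch; ++c) {
        const double Te = (ext_pulse_end(c, k) > t) ? Tamp : 0.0;
        s = s_ext(c, k) + dt * (a_ampa * Te * (1 - s_ext(c, k)) - b_ampa * s_ext(c, k));
        s_ext(c, k) = std::min(1.0, std::max(0.0, s));
      }
    }
  }

  if (record_currents) {
    const double denom = (double)n_steps;
    // per-pool mean over steps and neurons
    std::vector<int> psz(n_pools, 0);
    for (int k = 0; k < n; ++k) psz[pool_of[k]]++;
    for (int p = 0; p < n_pools; ++p)
      for (int c = 0; c < 3 + n_ch; ++c)
        cur(p, c) /= denom * std::max(1, psz[p]);
  }

  return List::create(
    _["spike_t"] = wrap(sp_t), _["spike_id"] = wrap(sp_id),
    _["state"] = List::create(
      _["V"] = V, _["s_ampa"] = s_ampa, _["s_nmda"] = s_nmda,
      _["s_gaba"] = s_gaba, _["s_ext"] = s_ext,
      _["pulse_end"] = pulse_end, _["ext_pulse_end"] = ext_pulse_end,
      _["refr"] = refr),
    _["currents"] = cur);
}

// Event-driven STDP with activity-dependent efficacy.
//
// Edges are given as parallel arrays (pre, post, w) plus CSR-style
// indices: in_p/in_e give, for each neuron, the edge ids of its incoming
// synapses; out_p/out_e its outgoing ones.  Spikes (t sorted ascending,
// id 1-based) are processed in order; at each spike of neuron j at time t:
//   * potentiation  dw = eta * E_pre(t) * A_plus  * x_pre(i, t)  on i -> j
//   * depression    dw = -eta * E_j(t)  * A_minus * x_post(k, t) on j -> k
//   * j's own pairing traces are refreshed (reset to 1 under nearest-spike
//     pairing, incremented under all-pairs) and its efficacy depressed,
//     E <- E (1 - u).
// Traces and efficacy decay/recover with exact exponentials between
// events, so the all-pairs mode agrees with a brute-force sum over spike
// pairs to machine precision.  Weights are clipped to [w_min, w_max]
// after every update.
// [[Rcpp::export]]
List cpp_stdp_run(NumericVector w, IntegerVector edge_pre, IntegerVector edge_post,
                  IntegerVector in_p, IntegerVector in_e,
                  IntegerVector out_p, IntegerVector out_e,
                  NumericVector sp_t, IntegerVector sp_id, int n_neurons,
                  double eta, double A_plus, double A_minus,
                  double tau_plus, double tau_minus,
                  double tau_E, double u, double w_min, double w_max,
                  bool all_pairs) {
  NumericVector W = clone(w);
  const int n_sp = sp_t.size();
  std::vector<double> x_pre(n_neurons, 0.0), x_post(n_neurons, 0.0);
  std::vector<double> t_pre(n_neurons, R_NegInf), t_post(n_neurons, R_NegInf);
  std::vector<double> E(n_neurons, 1.0), t_E(n_neurons, R_NegInf);

  auto eff_at = [&](int i, double t) {
    if (!std::isfinite(t_E[i])) return 1.0;
    return 1.0 - (1.0 - E[i]) * std::exp(-(t - t_E[i]) / tau_E);
  };

  for (int s = 0; s < n_sp; ++s) {
    const double t = sp_t[s];
    const int j = sp_id[s] - 1;

    const double Ej = eff_at(j, t);  // before this spike's own depression

    // potentiation of incoming synapses: pre fired earlier, post fires now
    for (int k = in_p[j]; k < in_p[j + 1]; ++k) {
      const int e = in_e[k];
      const int i = edge_pre[e];
      if (!std::isfinite(t_pre[i])) continue;
      const double x = x_pre[i] * std::exp(-(t - t_pre[i]) / tau_plus);
      double nw = W[e] + eta * eff_at(i, t) * A_plus * x;
      W[e] = std::min(w_max, std::max(w_min, nw));
    }
    // depression of outgoing synapses: post fired earlier, pre fires now
    for (int k = out_p[j]; k < out_p[j + 1]; ++k) {
      const int e = out_e[k];
      const int i = edge_post[e];
      if (!std::isfinite(t_post[i])) continue;
      const double x = x_post[i] * std::exp(-(t - t_post[i]) / tau_minus);
      double nw = W[e] - eta * Ej * A_minus * x;
      W[e] = std::min(w_max, std::max(w_min, nw));
    }

    // refresh j's traces and efficacy
    if (all_pairs) {
      x_pre[j] = (std::isfinite(t_pre[j]) ?
                  x_pre[j] * std::exp(-(t - t_pre[j]) / tau_plus) : 0.0) + 1.0;
      x_post[j] = (std::isfinite(t_post[j]) ?
                   x_post[j] * std::exp(-(t - t_post[j]) / tau_minus) : 0.0) + 1.0;
    } else {
      x_pre[j] = 1.0;
      x_post[j] = 1.0;
    }
    t_pre[j] = t;
    t_post[j] = t;
    E[j] = Ej * (1.0 - u);
    t_E[j] = t;
  }

  return List::create(_["w"] = W, _["E"] = wrap(E));
}
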