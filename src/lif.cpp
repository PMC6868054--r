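#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Time-stepped LIF network integration.
//
// Dynamics per neuron (subthreshold):
//   C du/dt = -g_l (u - E_leak) - g_e(t) (u - E_exc) - g_i(t) (u - E_inh)
// with g_l = C / tau_mem. Conductances follow exponential kernels: each
// presynaptic spike at t_sp adds J to the matching conductance at onset
// t_sp + d, after which it decays with the postsynaptic neuron's tau_syn.
//
// Integration: exponential Euler for u (conductances held constant over one
// step, decayed exactly between steps). Threshold is detected on the
// post-step value; the spike timestamp is the end-of-step boundary. During
// [t_sp, t_sp + tau_ref) the membrane is clamped to V_reset.
//
// Everything is deterministic: all stochasticity enters through the external
// input spike trains.

struct Delivery {
  int post;
  double w;
  bool inh;
};

// [[Rcpp::export]]
List cpp_lif_simulate(NumericMatrix par,
                      IntegerVector syn_pre, IntegerVector syn_post,
                      NumericVector syn_w, IntegerVector syn_inh,
                      NumericVector syn_delay,
                      IntegerVector esyn_src, IntegerVector esyn_post,
                      NumericVector esyn_w, IntegerVector esyn_inh,
                      NumericVector esyn_delay,
                      NumericVector ext_t, IntegerVector ext_id, int n_trains,
                      double duration, double dt,
                      IntegerVector record, NumericVector u0) {
  const int n = par.nrow();
  const long nsteps = (long)std::llround(duration / dt);

  std::vector<double> Vr(n), El(n), Vt(n), Ei(n), Ee(n), tref(n), gl(n),
      C(n), dec_e(n), dec_i(n);
  for (int i = 0; i < n; ++i) {
    Vr[i] = par(i, 0);
    El[i] = par(i, 1);
    Vt[i] = par(i, 2);
    Ei[i] = par(i, 3);
    Ee[i] = par(i, 4);
    tref[i] = par(i, 5);
    // conductances are in nS, times in ms, C_mem in nF: tau_ms = C/g needs
    // C expressed in nS*ms = 1000 * nF
    C[i] = 1000.0 * par(i, 7);
    gl[i] = 1000.0 * par(i, 7) / par(i, 6);
    dec_e[i] = std::exp(-dt / par(i, 8));
    dec_i[i] = std::exp(-dt / par(i, 9));
  }

  // adjacency: synapses by presynaptic neuron / by external train
  const int ns = syn_pre.size(), nes = esyn_src.size();
  std::vector<std::vector<int>> adj(n), tadj(n_trains);
  std::vector<long> sdel(ns), edel(nes);
  long maxdel = 0;
  for (int j = 0; j < ns; ++j) {
    adj[syn_pre[j]].push_back(j);
    sdel[j] = (long)std::llround(syn_delay[j] / dt);
    if (sdel[j] > maxdel) maxdel = sdel[j];
  }
  for (int j = 0; j < nes; ++j) {
    tadj[esyn_src[j]].push_back(j);
    edel[j] = (long)std::llround(esyn_delay[j] / dt);
    if (edel[j] > maxdel) maxdel = edel[j];
  }
  const long ringN = maxdel + 2;
  std::vector<std::vector<Delivery>> ring(ringN);

  // emission step of external spikes (causal: first grid point >= spike time)
  const int nev = ext_t.size();
  std::vector<long> estep(nev);
  for (int k = 0; k < nev; ++k)
    estep[k] = (long)std::ceil(ext_t[k] / dt - 1e-9);

  std::vector<double> u(n), ge(n, 0.0), gi(n, 0.0), refend(n, -1.0);
  for (int i = 0; i < n; ++i) u[i] = u0[i];

  const int nrec = record.size();
  std::vector<int> recidx(n, -1);
  for (int r = 0; r < nrec; ++r) recidx[record[r]] = r;
  NumericMatrix traces(nrec, nrec > 0 ? nsteps : 0);

  std::vector<double> sp_t;
  std::vector<int> sp_id;
  sp_t.reserve(1024);
  sp_id.reserve(1024);

  int k = 0;  // external spike cursor
  for (long s = 0; s < nsteps; ++s) {
    const double t = s * dt;
    // enqueue external arrivals whose emission step is s
    while (k < nev && estep[k] == s) {
      const std::vector<int>& js = tadj[ext_id[k]];
      for (size_t q = 0; q < js.size(); ++q) {
        const int j = js[q];
        ring[(s + edel[j]) % ringN].push_back(
            {esyn_post[j], esyn_w[j], esyn_inh[j] != 0});
      }
      ++k;
    }
    // deliver conductance increments with onset at time t
    std::vector<Delivery>& slot = ring[s % ringN];
    for (size_t q = 0; q < slot.size(); ++q) {
      if (slot[q].inh)
        gi[slot[q].post] += slot[q].w;
      else
        ge[slot[q].post] += slot[q].w;
    }
    slot.clear();

    for (int i = 0; i < n; ++i) {
      const bool refr = t < refend[i] - 1e-9;
      if (refr) u[i] = Vr[i];
      if (recidx[i] >= 0) traces(recidx[i], s) = u[i];
      if (refr) continue;
      const double gtot = gl[i] + ge[i] + gi[i];
      const double uinf =
          (gl[i] * El[i] + ge[i] * Ee[i] + gi[i] * Ei[i]) / gtot;
      const double unew = uinf + (u[i] - uinf) * std::exp(-dt * gtot / C[i]);
      // spike only on a genuine crossing from below: a membrane resting
      // exactly at threshold (E_leak = V_thresh, no input) stays silent
      if (unew >= Vt[i] && unew > u[i]) {
        const double tsp = t + dt;
        sp_t.push_back(tsp);
        sp_id.push_back(i);
        u[i] = Vr[i];
        refend[i] = tsp + tref[i];
        const std::vector<int>& js = adj[i];
        for (size_t q = 0; q < js.size(); ++q) {
          const int j = js[q];
          ring[(s + 1 + sdel[j]) % ringN].push_back(
              {syn_post[j], syn_w[j], syn_inh[j] != 0});
        }
      } else {
        u[i] = unew;
      }
    }
    for (int i = 0; i < n; ++i) {
      ge[i] *= dec_e[i];
      gi[i] *= dec_i[i];
    }
  }

  return List::create(_["times"] = wrap(sp_t), _["ids"] = wrap(sp_id),
                      _["traces"] = traces, _["dt"] = dt,
                      _["nsteps"] = (double)nsteps);
}
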