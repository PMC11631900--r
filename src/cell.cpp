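#include <Rcpp.h>
#include "model.h"
using namespace Rcpp;

// Single-cell integrator: Rush-Larsen exponential update for gates,
// forward Euler for membrane potential and intracellular calcium.
// Stimulus current is depolarising-positive; dV/dt = -I_ion + I_stim.
// [[Rcpp::export]]
List cell_sim_cpp(NumericVector par, NumericVector y0, NumericVector stim_times,
                  double duration, double dt, double record_dt) {
  if (par.size() != N_PAR) stop("parameter vector has wrong length");
  if (y0.size() != N_STATE) stop("state vector has wrong length");
  double p[N_PAR], y[N_STATE];
  for (int i = 0; i < N_PAR; ++i) p[i] = par[i];
  for (int i = 0; i < N_STATE; ++i) y[i] = y0[i];

  long nsteps = (long)std::llround(duration / dt);
  long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  long nrec = nsteps / rec_every + 1;
  NumericVector t_out(nrec), v_out(nrec), cai_out(nrec);

  double inf[N_GATE], tau[N_GATE];
  double stim_dur = p[P_STIM_DUR], stim_amp = p[P_STIM_AMP];
  int nstim = stim_times.size(), stim_ptr = 0;
  bool diverged = false;
  double t_fail = NA_REAL;
  long irec = 0;
  t_out[0] = 0.0; v_out[0] = y[0]; cai_out[0] = y[I_CAI];

  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    // stimulus
    double istim = 0.0;
    while (stim_ptr < nstim && t >= stim_times[stim_ptr] + stim_dur) ++stim_ptr;
    for (int k = stim_ptr; k < nstim; ++k) {
      if (stim_times[k] > t) break;
      if (t >= stim_times[k] && t < stim_times[k] + stim_dur) { istim = stim_amp; break; }
    }
    double dCai;
    double iion = ionic_current(y, p, &dCai);
    gate_rates(y[0], inf, tau);
    scale_taus(p, tau, y[0]);
    for (int g = 0; g < N_GATE; ++g)
      y[g + 1] += (inf[g] - y[g + 1]) * (1.0 - std::exp(-dt / tau[g]));
    y[0] += dt * (-iion + istim);
    y[I_CAI] += dt * dCai;
    if (y[I_CAI] < 1e-12) y[I_CAI] = 1e-12;
    if (y[0] < -150.0 || y[0] > 100.0 || !std::isfinite(y[0])) {
      diverged = true;
      t_fail = t + dt;
      break;
    }
    if ((step + 1) % rec_every == 0) {
      ++irec;
      t_out[irec] = (step + 1) * dt;
      v_out[irec] = y[0];
      cai_out[irec] = y[I_CAI];
    }
  }
  if (diverged && irec + 1 < nrec) {
    t_out = head(t_out, irec + 1);
    v_out = head(v_out, irec + 1);
    cai_out = head(cai_out, irec + 1);
  }
  NumericVector yf(N_STATE);
  for (int i = 0; i < N_STATE; ++i) yf[i] = y[i];
  return List::create(_["time"] = t_out, _["Vm"] = v_out, _["Cai"] = cai_out,
                      _["final_state"] = yf,
                      _["diverged"] = diverged, _["t_fail"] = t_fail);
}
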