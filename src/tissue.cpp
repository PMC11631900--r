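#include <Rcpp.h>
#include <vector>
#include "model.h"
using namespace Rcpp;

// ---- lookup tables over membrane potential ----------------------------------
static const double TAB_VMIN = -150.0, TAB_VMAX = 100.0, TAB_STEP = 0.05;
static const int TAB_N = (int)((TAB_VMAX - TAB_VMIN) / TAB_STEP) + 1;
static const double TAB_UMIN = -120.0, TAB_UMAX = 280.0;
static const int TAB_UN = (int)((TAB_UMAX - TAB_UMIN) / TAB_STEP) + 1;

struct RateTables {
  // interleaved layout: for each potential index, 22 consecutive values
  // (10 gate steady states, 10 Rush-Larsen factors, xi, Kp) so one cell's
  // lookups touch two adjacent cache-line runs
  static const int NCOL = 2 * N_GATE + 2;
  std::vector<double> tab;  // TAB_N x NCOL
  std::vector<double> k1;   // over u = V - E_K1
  void build(const double *p, double dt) {
    tab.resize((size_t)TAB_N * NCOL);
    k1.resize(TAB_UN);
    double gi[N_GATE], gt[N_GATE];
    for (int i = 0; i < TAB_N; ++i) {
      double V = TAB_VMIN + i * TAB_STEP;
      gate_rates(V, gi, gt);
      scale_taus(p, gt, V);
      double *row = &tab[(size_t)i * NCOL];
      for (int g = 0; g < N_GATE; ++g) {
        row[g] = gi[g];
        row[N_GATE + g] = 1.0 - std::exp(-dt / gt[g]);
      }
      row[2 * N_GATE] = xi_gate(V);
      row[2 * N_GATE + 1] = 1.0 / (1.0 + std::exp((7.488 - V) / 5.98));
    }
    for (int i = 0; i < TAB_UN; ++i) k1[i] = k1_inf(TAB_UMIN + i * TAB_STEP);
  }
};

static inline double lin(const std::vector<double> &tab, double pos) {
  int i = (int)pos;
  double f = pos - i;
  return tab[i] * (1.0 - f) + tab[i + 1] * f;
}

// ---- per-cell derived constants ---------------------------------------------
struct CellConst {
  std::vector<double> gNa, gNaL, gsi, gK, gK1, gKp, gb, gto, katp, ENa, EK, EK1;
  void compute(const NumericMatrix &par) {
    int n = par.ncol();
    gNa.resize(n); gNaL.resize(n); gsi.resize(n); gK.resize(n); gK1.resize(n);
    gKp.resize(n); gb.resize(n); gto.resize(n); katp.resize(n);
    ENa.resize(n); EK.resize(n); EK1.resize(n);
    for (int c = 0; c < n; ++c) {
      double Ko = par(P_KO, c), Ki = par(P_KI, c), Nao = par(P_NAO, c), Nai = par(P_NAI, c);
      double sKo = std::sqrt(Ko / 5.4);
      gNa[c] = par(P_GNA, c);
      gNaL[c] = par(P_GNAL, c);
      gsi[c] = par(P_GSI, c);
      gK[c] = par(P_GK, c) * sKo;
      gK1[c] = par(P_GK1, c) * sKo;
      gKp[c] = par(P_GKP, c);
      gb[c] = par(P_GB, c);
      gto[c] = par(P_GTO, c);
      katp[c] = par(P_GKATP, c) * par(P_KATP_FRAC, c) * std::pow(Ko / 5.4, par(P_KATP_EXP, c));
      ENa[c] = RTF * std::log(Nao / Nai);
      EK[c] = RTF * std::log((Ko + 0.01833 * Nao) / (Ki + 0.01833 * Nai));
      EK1[c] = RTF * std::log(Ko / Ki);
    }
  }
};

static void check_uniform_taus(const NumericMatrix &par) {
  static const int rows[7] = {P_TAUH_S, P_TAUJ_S, P_TAUM_S, P_TAUHL_S, P_TAUHL_B,
                              P_TAUD_S, P_TAUS_S};
  for (int k = 0; k < 7; ++k)
    for (int c = 1; c < par.ncol(); ++c)
      if (std::fabs(par(rows[k], c) - par(rows[k], 0)) > 1e-12)
        stop("gate time-constant scales must be uniform across the tissue");
  for (int c = 1; c < par.ncol(); ++c)
    if (std::fabs(par(P_TAUF_S, c) - par(P_TAUF_S, 0)) > 1e-12 ||
        std::fabs(par(P_TAUFP_S, c) - par(P_TAUFP_S, 0)) > 1e-12 ||
        std::fabs(par(P_TAUX_S, c) - par(P_TAUX_S, 0)) > 1e-12)
      stop("gate time-constant scales must be uniform across the tissue");
}

// ---- anisotropic diffusion with flux form (no-flux boundaries) --------------
// dV[c] += dt/dx^2 * div(D grad V) with face-averaged tensor components.
static void diffuse(const std::vector<double> &V, std::vector<double> &out,
                    const double *Dxx, const double *Dyy, const double *Dxy,
                    int nx, int ny, double dx, double dt, bool mixed) {
  double r = dt / (dx * dx);
  // x faces
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx - 1; ++i) {
      int c = i + j * nx, cr = c + 1;
      double F = 0.5 * (Dxx[c] + Dxx[cr]) * (V[cr] - V[c]);
      if (mixed) {
        // dV/dy at the two cells flanking the face (one-sided at the boundary)
        double g1 = (j > 0 && j < ny - 1) ? 0.5 * (V[c + nx] - V[c - nx])
                                          : (j == 0 ? V[c + nx] - V[c] : V[c] - V[c - nx]);
        double g2 = (j > 0 && j < ny - 1) ? 0.5 * (V[cr + nx] - V[cr - nx])
                                          : (j == 0 ? V[cr + nx] - V[cr] : V[cr] - V[cr - nx]);
        F += 0.5 * (Dxy[c] + Dxy[cr]) * 0.5 * (g1 + g2);
      }
      out[c] += r * F;
      out[cr] -= r * F;
    }
  }
  // y faces
  for (int j = 0; j < ny - 1; ++j) {
    for (int i = 0; i < nx; ++i) {
      int c = i + j * nx, cu = c + nx;
      double F = 0.5 * (Dyy[c] + Dyy[cu]) * (V[cu] - V[c]);
      if (mixed) {
        double g1 = (i > 0 && i < nx - 1) ? 0.5 * (V[c + 1] - V[c - 1])
                                          : (i == 0 ? V[c + 1] - V[c] : V[c] - V[c - 1]);
        double g2 = (i > 0 && i < nx - 1) ? 0.5 * (V[cu + 1] - V[cu - 1])
                                          : (i == 0 ? V[cu + 1] - V[cu] : V[cu] - V[cu - 1]);
        F += 0.5 * (Dxy[c] + Dxy[cu]) * 0.5 * (g1 + g2);
      }
      out[c] += r * F;
      out[cu] -= r * F;
    }
  }
}

// Exposed for property tests: one explicit diffusion step on a potential field.
// [[Rcpp::export]]
NumericMatrix diffusion_step_cpp(NumericMatrix Vm, NumericVector Dxx, NumericVector Dyy,
                                 NumericVector Dxy, double dx, double dt) {
  int nx = Vm.nrow(), ny = Vm.ncol(), n = nx * ny;
  std::vector<double> V(n), out(n);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) V[i + j * nx] = Vm(i, j);
  out = V;
  bool mixed = false;
  if (nx > 1 && ny > 1)
    for (int c = 0; c < n; ++c) if (Dxy[c] != 0.0) { mixed = true; break; }
  diffuse(V, out, Dxx.begin(), Dyy.begin(), Dxy.begin(), nx, ny, dx, dt, mixed);
  NumericMatrix res(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) res(i, j) = out[i + j * nx];
  return res;
}

// ---- monodomain engine -------------------------------------------------------
// Operator-split explicit update: Rush-Larsen gates + Euler reaction, then
// explicit finite-difference diffusion, both at time level n.
// par_epochs: list of N_PAR x ncell matrices; epoch_times[k] is when epoch k starts.
// stims: list of list(t0, dur, amp, cells [1-based]).
// [[Rcpp::export]]
List monodomain_cpp(int nx, int ny, double dx,
                    NumericVector Dxx, NumericVector Dyy, NumericVector Dxy,
                    List par_epochs, NumericVector epoch_times,
                    NumericMatrix y0, List stims,
                    double duration, double dt, double frame_dt,
                    bool record_frames) {
  int ncell = nx * ny;
  if (y0.nrow() != N_STATE || y0.ncol() != ncell) stop("bad initial state shape");
  NumericMatrix par0 = par_epochs[0];
  if (par0.nrow() != N_PAR || par0.ncol() != ncell) stop("bad parameter matrix shape");
  int nepoch = par_epochs.size();
  for (int e = 0; e < nepoch; ++e) check_uniform_taus(as<NumericMatrix>(par_epochs[e]));

  RateTables tab;
  {
    double p0[N_PAR];
    for (int i = 0; i < N_PAR; ++i) p0[i] = par0(i, 0);
    tab.build(p0, dt);
  }
  CellConst cc;
  cc.compute(par0);
  int epoch = 0;

  std::vector<double> V(ncell), Vtmp(ncell);
  std::vector<double> gates(ncell * N_GATE);
  std::vector<double> Cai(ncell);
  for (int c = 0; c < ncell; ++c) {
    V[c] = y0(0, c);
    for (int g = 0; g < N_GATE; ++g) gates[c * N_GATE + g] = y0(g + 1, c);
    Cai[c] = y0(I_CAI, c);
  }
  bool mixed = false;
  if (nx > 1 && ny > 1)
    for (int c = 0; c < ncell; ++c) if (Dxy[c] != 0.0) { mixed = true; break; }

  // stimuli
  int nstim = stims.size();
  std::vector<double> st_t0(nstim), st_dur(nstim), st_amp(nstim);
  std::vector<IntegerVector> st_cells(nstim);
  for (int s = 0; s < nstim; ++s) {
    List st = stims[s];
    st_t0[s] = as<double>(st["t0"]);
    st_dur[s] = as<double>(st["dur"]);
    st_amp[s] = as<double>(st["amp"]);
    st_cells[s] = as<IntegerVector>(st["cells"]);
  }
  std::vector<double> istim(ncell, 0.0);

  long nsteps = (long)std::llround(duration / dt);
  long frame_every = record_frames ? std::max(1L, (long)std::llround(frame_dt / dt)) : nsteps + 1;
  int nframes = record_frames ? (int)(nsteps / frame_every) + 1 : 0;
  NumericMatrix frames(record_frames ? ncell : 0, nframes);
  NumericVector frame_times(nframes);
  int iframe = 0;
  if (record_frames) {
    for (int c = 0; c < ncell; ++c) frames(c, 0) = V[c];
    frame_times[0] = 0.0;
  }
  std::vector<double> act(ncell, -1.0);
  bool diverged = false;
  double t_fail = NA_REAL;
  int cell_fail = NA_INTEGER;

  for (long step = 0; step < nsteps && !diverged; ++step) {
    double t = step * dt;
    if (epoch + 1 < nepoch && t >= epoch_times[epoch + 1] - 0.5 * dt) {
      ++epoch;
      cc.compute(as<NumericMatrix>(par_epochs[epoch]));
    }
    // stimulus field
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int s = 0; s < nstim; ++s) {
      if (t >= st_t0[s] && t < st_t0[s] + st_dur[s]) {
        const IntegerVector &cl = st_cells[s];
        for (int k = 0; k < cl.size(); ++k) istim[cl[k] - 1] += st_amp[s];
      }
    }
    // reaction
    for (int c = 0; c < ncell; ++c) {
      double v = V[c];
      double pos = (v - TAB_VMIN) / TAB_STEP;
      if (pos < 0) pos = 0;
      if (pos > TAB_N - 2) pos = TAB_N - 2;
      int i0 = (int)pos;
      double w1 = pos - i0, w0 = 1.0 - w1;
      const double *r0 = &tab.tab[(size_t)i0 * RateTables::NCOL];
      const double *r1 = r0 + RateTables::NCOL;
      double *g = &gates[c * N_GATE];
      double m = g[0], h = g[1], j = g[2], d = g[3], f = g[4], x = g[5],
             mL = g[6], hL = g[7], rr = g[8], ss = g[9];
      double ca = Cai[c];
      double INa = cc.gNa[c] * m * m * m * h * j * (v - cc.ENa[c]);
      double INaL = cc.gNaL[c] * mL * hL * (v - cc.ENa[c]);
      double Esi = 7.7 - 13.0287 * std::log(ca);
      double Isi = cc.gsi[c] * d * f * (v - Esi);
      double xi = r0[2 * N_GATE] * w0 + r1[2 * N_GATE] * w1;
      double kp = r0[2 * N_GATE + 1] * w0 + r1[2 * N_GATE + 1] * w1;
      double IK = cc.gK[c] * x * xi * (v - cc.EK[c]);
      double u = v - cc.EK1[c];
      double upos = (u - TAB_UMIN) / TAB_STEP;
      if (upos < 0) upos = 0;
      if (upos > TAB_UN - 2) upos = TAB_UN - 2;
      int ui = (int)upos;
      double uf = upos - ui;
      double IK1 = cc.gK1[c] * (tab.k1[ui] * (1.0 - uf) + tab.k1[ui + 1] * uf) * u;
      double IKp = cc.gKp[c] * kp * u;
      double Ib = cc.gb[c] * (v + 59.87);
      double Ito = cc.gto[c] * rr * ss * u;
      double IKATP = cc.katp[c] * u;
      double iion = INa + INaL + Isi + IK + IK1 + IKp + Ib + Ito + IKATP;
      for (int q = 0; q < N_GATE; ++q)
        g[q] += (r0[q] * w0 + r1[q] * w1 - g[q]) *
                (r0[N_GATE + q] * w0 + r1[N_GATE + q] * w1);
      Cai[c] += dt * (-1e-4 * Isi + 0.07 * (1e-4 - ca));
      if (Cai[c] < 1e-12) Cai[c] = 1e-12;
      Vtmp[c] = v + dt * (-iion + istim[c]);
    }
    // diffusion on the pre-reaction field
    diffuse(V, Vtmp, Dxx.begin(), Dyy.begin(), Dxy.begin(), nx, ny, dx, dt, mixed);
    for (int c = 0; c < ncell; ++c) {
      double vold = V[c], vnew = Vtmp[c];
      if (act[c] < 0.0 && vold < -20.0 && vnew >= -20.0)
        act[c] = t + dt;
      if (vnew < -150.0 || vnew > 100.0 || !std::isfinite(vnew)) {
        diverged = true;
        t_fail = t + dt;
        cell_fail = c + 1;
        break;
      }
      V[c] = vnew;
    }
    if (record_frames && !diverged && (step + 1) % frame_every == 0) {
      ++iframe;
      for (int c = 0; c < ncell; ++c) frames(c, iframe) = V[c];
      frame_times[iframe] = (step + 1) * dt;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  if (record_frames && iframe + 1 < nframes) {
    frames = frames(_, Range(0, iframe));
    frame_times = head(frame_times, iframe + 1);
  }
  NumericMatrix yf(N_STATE, ncell);
  for (int c = 0; c < ncell; ++c) {
    yf(0, c) = V[c];
    for (int g = 0; g < N_GATE; ++g) yf(g + 1, c) = gates[c * N_GATE + g];
    yf(I_CAI, c) = Cai[c];
  }
  NumericVector act_out(ncell);
  for (int c = 0; c < ncell; ++c) act_out[c] = act[c] < 0 ? NA_REAL : act[c];
  return List::create(_["frames"] = frames, _["frame_times"] = frame_times,
                      _["activation_times"] = act_out, _["final_state"] = yf,
                      _["diverged"] = diverged, _["t_fail"] = t_fail,
                      _["cell_fail"] = cell_fail);
}

// ---- infinite-medium pseudo-ECG ---------------------------------------------
// Unipolar potential at each pole: sum over cells of
//   -cond * grad(Vm) . (pole - cell) / r^3 * dx^2.
// poles: npole x 3 (x, y, z) in the same length unit as dx.
// [[Rcpp::export]]
NumericMatrix pseudo_ecg_cpp(NumericMatrix frames, int nx, int ny, double dx,
                             NumericMatrix poles, NumericVector cond) {
  int ncell = nx * ny, nf = frames.ncol(), np = poles.nrow();
  if (frames.nrow() != ncell) stop("frame/grid mismatch");
  // precompute kernels per pole
  std::vector<std::vector<double> > kx(np), ky(np);
  for (int p = 0; p < np; ++p) {
    kx[p].resize(ncell);
    ky[p].resize(ncell);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = i + j * nx;
        double rx = poles(p, 0) - (i + 0.5) * dx;
        double ry = poles(p, 1) - (j + 0.5) * dx;
        double rz = poles(p, 2);
        double r2 = rx * rx + ry * ry + rz * rz;
        if (r2 < 1e-12) stop("electrode coincides with a tissue point");
        double r3 = r2 * std::sqrt(r2);
        kx[p][c] = cond[c] * rx / r3;
        ky[p][c] = cond[c] * ry / r3;
      }
  }
  NumericMatrix out(np, nf);
  std::vector<double> gx(ncell), gy(ncell);
  for (int fidx = 0; fidx < nf; ++fidx) {
    const double *V = &frames(0, fidx);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = i + j * nx;
        gx[c] = (nx == 1) ? 0.0
                : (i > 0 && i < nx - 1) ? (V[c + 1] - V[c - 1]) / (2 * dx)
                : (i == 0 ? (V[c + 1] - V[c]) / dx : (V[c] - V[c - 1]) / dx);
        gy[c] = (ny == 1) ? 0.0
                : (j > 0 && j < ny - 1) ? (V[c + nx] - V[c - nx]) / (2 * dx)
                : (j == 0 ? (V[c + nx] - V[c]) / dx : (V[c] - V[c - nx]) / dx);
      }
    for (int p = 0; p < np; ++p) {
      double s = 0.0;
      const std::vector<double> &kxp = kx[p], &kyp = ky[p];
      for (int c = 0; c < ncell; ++c) s -= gx[c] * kxp[c] + gy[c] * kyp[c];
      out(p, fidx) = s * dx * dx;
    }
  }
  return out;
}
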