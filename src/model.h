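#ifndef VFIB_MODEL_H
#define VFIB_MODEL_H

#include <cmath>

// Parameter vector layout. Must match vfib_par_names() in R/parameters.R.
enum ParIdx {
  P_GNA = 0,   // fast sodium conductance (mS/uF)
  P_GNAL,      // late sodium conductance
  P_GSI,       // slow inward (L-type calcium like) conductance
  P_GK,        // delayed rectifier conductance
  P_GK1,       // inward rectifier conductance
  P_GKP,       // plateau potassium conductance
  P_GB,        // background current conductance
  P_GTO,       // transient outward conductance
  P_GKATP,     // maximal ATP-sensitive potassium conductance
  P_KATP_FRAC, // I_K(ATP) activation fraction in [0,1]
  P_KATP_EXP,  // Ko dependence exponent of I_K(ATP)
  P_TAUH_S,    // scale on tau_h
  P_TAUJ_S,    // scale on tau_j
  P_TAUM_S,    // scale on tau_m (and tau_mL)
  P_TAUHL_S,   // scale on tau_hL
  P_TAUHL_B,   // baseline tau_hL (ms)
  P_TAUD_S,    // scale on tau_d
  P_TAUF_S,    // scale on tau_f (diastolic recovery)
  P_TAUFP_S,   // scale on tau_f at plateau potentials (inactivation)
  P_TAUX_S,    // scale on tau_x
  P_TAUS_S,    // scale on tau_s (transient outward inactivation)
  P_KO,        // extracellular potassium (mM)
  P_KI,        // intracellular potassium (mM)
  P_NAO,       // extracellular sodium (mM)
  P_NAI,       // intracellular sodium (mM)
  P_STIM_AMP,  // stimulus amplitude (uA/uF, depolarising positive)
  P_STIM_DUR,  // stimulus duration (ms)
  N_PAR
};

#define N_STATE 12
// state order: V, m, h, j, d, f, x, mL, hL, r, s, Cai(mM)
#define N_GATE 10
// gate order within state: m h j d f x mL hL r s (state index = gate index + 1)
#define I_CAI 11

static const double RTF = 26.712338; // RT/F in mV at 310 K

// Hodgkin-Huxley rate functions; inf and tau for the 8 gates, unscaled.
inline void gate_rates(double V, double *inf, double *tau) {
  double am = (std::fabs(V + 47.13) < 1e-6)
                  ? 3.2
                  : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  double bm = 0.08 * std::exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V < -40.0) {
    // Diastolic-branch rates are slowed by a fixed factor, giving the long
    // post-repolarisation recovery of sodium availability that underlies the
    // premature-stimulus refractoriness of this reduced model; the fast
    // branch below keeps its raw kinetics so inactivation during the spike
    // stays on the sub-millisecond scale that shapes conduction velocity.
    const double krec = 8.0;
    ah = 0.135 * std::exp(-(80.0 + V) / 6.8) / krec;
    bh = (3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V)) / krec;
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23))) / krec;
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14))) / krec;
  } else {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
  double ad = 0.095 * std::exp(-0.01 * (V - 5.0)) / (1.0 + std::exp(-0.072 * (V - 5.0)));
  double bd = 0.07 * std::exp(-0.017 * (V + 44.0)) / (1.0 + std::exp(0.05 * (V + 44.0)));
  double af = 0.012 * std::exp(-0.008 * (V + 28.0)) / (1.0 + std::exp(0.15 * (V + 28.0)));
  double bf = 0.0065 * std::exp(-0.02 * (V + 30.0)) / (1.0 + std::exp(-0.2 * (V + 30.0)));
  double ax = 0.0005 * std::exp(0.083 * (V + 50.0)) / (1.0 + std::exp(0.057 * (V + 50.0)));
  double bx = 0.0013 * std::exp(-0.06 * (V + 20.0)) / (1.0 + std::exp(-0.04 * (V + 20.0)));

  inf[0] = am / (am + bm);            tau[0] = 1.0 / (am + bm);
  inf[1] = ah / (ah + bh);            tau[1] = 1.0 / (ah + bh);
  inf[2] = aj / (aj + bj);            tau[2] = 1.0 / (aj + bj);
  inf[3] = ad / (ad + bd);            tau[3] = 1.0 / (ad + bd);
  inf[4] = af / (af + bf);            tau[4] = 1.0 / (af + bf);
  inf[5] = ax / (ax + bx);            tau[5] = 1.0 / (ax + bx);
  inf[6] = 1.0 / (1.0 + std::exp(-(V + 42.85) / 5.264)); tau[6] = tau[0]; // mL
  inf[7] = 1.0 / (1.0 + std::exp((V + 87.61) / 7.488));  tau[7] = 1.0;   // hL: constant tau set by caller
  inf[8] = 1.0 / (1.0 + std::exp(-(V + 15.0) / 9.0));    tau[8] = 2.5;   // r (Ito activation)
  inf[9] = 1.0 / (1.0 + std::exp((V + 40.0) / 5.0));     tau[9] = 40.0;  // s (Ito inactivation)
}

// Apply the per-parameter-set tau scales; tau_hL becomes an absolute value.
// tau_f_scale acts on diastolic recovery only (V below -40 mV), leaving
// plateau inactivation kinetics untouched.
inline void scale_taus(const double *p, double *tau, double V) {
  tau[0] *= p[P_TAUM_S];
  tau[1] *= p[P_TAUH_S];
  tau[2] *= p[P_TAUJ_S];
  tau[3] *= p[P_TAUD_S];
  tau[4] *= (V < -40.0) ? p[P_TAUF_S] : p[P_TAUFP_S];
  tau[5] *= p[P_TAUX_S];
  tau[6] *= p[P_TAUM_S];
  tau[7] = p[P_TAUHL_B] * p[P_TAUHL_S];
  tau[9] *= p[P_TAUS_S];
}

inline double xi_gate(double V) {
  if (V <= -100.0) return 1.0;
  if (std::fabs(V + 77.0) < 1e-6)
    return 2.837 * 0.04 / std::exp(0.04 * (V + 35.0));
  return 2.837 * (std::exp(0.04 * (V + 77.0)) - 1.0) /
         ((V + 77.0) * std::exp(0.04 * (V + 35.0)));
}

inline double k1_inf(double u) { // u = V - E_K1
  double aK1 = 1.02 / (1.0 + std::exp(0.2385 * (u - 59.215)));
  double bK1 = (0.49124 * std::exp(0.08032 * (u + 5.476)) +
                std::exp(0.06175 * (u - 594.31))) /
               (1.0 + std::exp(-0.5143 * (u + 4.753)));
  return aK1 / (aK1 + bK1);
}

// Total ionic current (uA/uF) and calcium derivative, direct evaluation.
inline double ionic_current(const double *y, const double *p, double *dCai) {
  double V = y[0], m = y[1], h = y[2], j = y[3], d = y[4], f = y[5],
         x = y[6], mL = y[7], hL = y[8], r = y[9], s = y[10], Cai = y[11];
  double ENa = RTF * std::log(p[P_NAO] / p[P_NAI]);
  double INa = p[P_GNA] * m * m * m * h * j * (V - ENa);
  double INaL = p[P_GNAL] * mL * hL * (V - ENa);
  double Esi = 7.7 - 13.0287 * std::log(Cai);
  double Isi = p[P_GSI] * d * f * (V - Esi);
  double sKo = std::sqrt(p[P_KO] / 5.4);
  double EK = RTF * std::log((p[P_KO] + 0.01833 * p[P_NAO]) /
                             (p[P_KI] + 0.01833 * p[P_NAI]));
  double IK = p[P_GK] * sKo * x * xi_gate(V) * (V - EK);
  double EK1 = RTF * std::log(p[P_KO] / p[P_KI]);
  double u = V - EK1;
  double IK1 = p[P_GK1] * sKo * k1_inf(u) * u;
  double IKp = p[P_GKP] / (1.0 + std::exp((7.488 - V) / 5.98)) * u;
  double Ib = p[P_GB] * (V + 59.87);
  double Ito = p[P_GTO] * r * s * u;
  double IKATP = p[P_GKATP] * p[P_KATP_FRAC] *
                 std::pow(p[P_KO] / 5.4, p[P_KATP_EXP]) * u;
  *dCai = -1e-4 * Isi + 0.07 * (1e-4 - Cai);
  return INa + INaL + Isi + IK + IK1 + IKp + Ib + Ito + IKATP;
}

#endif
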