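# Canonical parameter layout for the reduced human ventricular model.
# Order must match the ParIdx enum in src/model.h.

vfib_par_names <- c(
  "g_Na", "g_NaL", "g_si", "g_K", "g_K1", "g_Kp", "g_b", "g_to",
  "g_KATP", "katp_frac", "katp_ko_exp",
  "tau_h_scale", "tau_j_scale", "tau_m_scale", "tau_hL_scale", "tau_hL_base",
  "tau_d_scale", "tau_f_scale", "tau_fp_scale", "tau_x_scale", "tau_s_scale",
  "Ko", "Ki", "Nao", "Nai",
  "stim_amp", "stim_dur"
)

# Baseline (endocardial, healthy) parameter values. Conductances in mS/uF,
# time constants in ms, concentrations in mM. Calibrated against human
# anchors: APD90 at 2 Hz pacing in the experimental control band, conduction
# velocity 65 cm/s on a calibrated strand, and the restitution-steepness
# targets of the VF-optimised variant (see the methods vignette).
vfib_base_params <- c(
  g_Na = 16, g_NaL = 0.02, g_si = 0.086, g_K = 0.77, g_K1 = 0.6047,
  g_Kp = 0.0183, g_b = 0.03921, g_to = 0.084,
  g_KATP = 1.0, katp_frac = 0, katp_ko_exp = 0.24,
  tau_h_scale = 1, tau_j_scale = 1, tau_m_scale = 1.7,
  tau_hL_scale = 1, tau_hL_base = 200,
  tau_d_scale = 1.29, tau_f_scale = 4.05, tau_fp_scale = 1, tau_x_scale = 1,
  tau_s_scale = 1.12,
  Ko = 5.4, Ki = 145, Nao = 140, Nai = 18,
  stim_amp = 50, stim_dur = 1
)

# Transmural heterogeneity: multiplicative factors on the repolarising
# delayed rectifier and the slow inward current per cell type, giving the
# conventional ordering APD(epi) < APD(endo) < APD(mid).
vfib_celltype_factors <- list(
  endocardial     = c(g_K = 1.00, g_si = 1.00),
  `mid-myocardial` = c(g_K = 0.72, g_si = 1.05),
  epicardial      = c(g_K = 1.30, g_si = 0.95)
)

# Default resting state (relaxed further by resting_state()).
# Order: V, m, h, j, d, f, x, mL, hL, r, s, Cai (mM).
vfib_init_state <- c(-84.55, 0.0017, 0.983, 0.995, 0.003, 0.999, 0.0057,
                     0.0008, 0.36, 0.0004, 0.9999, 1e-4)

#' Cell type labels
#'
#' Transmural cell types supported by the ionic-model layer.
#' @return Character vector of the three cell-type labels.
#' @export
cell_types <- function() names(vfib_celltype_factors)

#' Default transmural cell-type mix
#'
#' Fraction of endocardial, mid-myocardial and epicardial cardiomyocytes used
#' when building tissue maps (50/30/20).
#' @return Named numeric vector summing to 1.
#' @export
transmural_mix <- function() {
  c(endocardial = 0.5, `mid-myocardial` = 0.3, epicardial = 0.2)
}

#' Ischaemia configuration
#'
#' Bundle of the acute-ischaemia modifiers applied to a cell model:
#' extracellular potassium (hyperkalaemia), the activation fraction of the
#' ATP-sensitive potassium current (hypoxia), and multiplicative scales on the
#' fast sodium and slow inward (L-type calcium like) conductances (acidosis).
#'
#' Severity presets: `healthy` leaves everything at baseline; `mild` raises
#' potassium to 7 mM with low I_K(ATP) activation; `moderate` raises potassium
#' to 9 mM with higher I_K(ATP) activation and 25% block of the sodium and
#' calcium currents. All values can be overridden.
#'
#' @param severity One of `"healthy"`, `"mild"`, `"moderate"`.
#' @param extracellular_potassium mM; default depends on severity.
#' @param katp_activation Fraction in \[0, 1\].
#' @param sodium_current_scale,calcium_current_scale Dimensionless scales.
#' @return An object of class `ischaemia_config`.
#' @export
ischaemia_config <- function(severity = c("healthy", "mild", "moderate"),
                             extracellular_potassium = NULL,
                             katp_activation = NULL,
                             sodium_current_scale = NULL,
                             calcium_current_scale = NULL) {
  severity <- match.arg(severity)
  def <- switch(severity,
    healthy  = list(ko = 5.4, katp = 0,     na = 1,    ca = 1),
    mild     = list(ko = 7,   katp = 0.001, na = 1,    ca = 1),
    moderate = list(ko = 8,   katp = 0.003, na = 0.85, ca = 0.85)
  )
  cfg <- list(
    severity = severity,
    extracellular_potassium = extracellular_potassium %||% def$ko,
    katp_activation = katp_activation %||% def$katp,
    sodium_current_scale = sodium_current_scale %||% def$na,
    calcium_current_scale = calcium_current_scale %||% def$ca
  )
  if (cfg$extracellular_potassium <= 0) stop("extracellular potassium must be > 0")
  if (cfg$katp_activation < 0 || cfg$katp_activation > 1)
    stop("katp_activation must lie in [0, 1]")
  if (cfg$sodium_current_scale <= 0 || cfg$calcium_current_scale <= 0)
    stop("current scales must be > 0")
  structure(cfg, class = "ischaemia_config")
}

#' Ionic-model parameter deltas
#'
#' Multiplicative changes to the fast and late sodium current applied on top
#' of the baseline model: scales on the inactivation time constants tau_h,
#' tau_j and tau_hL and on the conductances g_Na and g_NaL.
#'
#' @param tau_h_scale,tau_j_scale,tau_hL_scale,g_Na_scale,g_NaL_scale
#'   Dimensionless positive scales.
#' @return An object of class `variant_delta`.
#' @export
variant_delta <- function(tau_h_scale = 1, tau_j_scale = 1, tau_hL_scale = 1,
                          g_Na_scale = 1, g_NaL_scale = 1) {
  d <- list(tau_h_scale = tau_h_scale, tau_j_scale = tau_j_scale,
            tau_hL_scale = tau_hL_scale, g_Na_scale = g_Na_scale,
            g_NaL_scale = g_NaL_scale)
  if (any(unlist(d) <= 0)) stop("all delta scales must be > 0")
  structure(d, class = "variant_delta")
}

#' @rdname variant_delta
#' @export
identity_delta <- function() variant_delta()

#' VF-optimised variant delta
#'
#' The parameter changes of the fibrillation-optimised cell variant: halved
#' tau_h and tau_j, tau_hL reduced by 34%, and fast and late sodium
#' conductances increased by 39%.
#' @return A `variant_delta`.
#' @export
vf_variant_delta <- function() {
  variant_delta(tau_h_scale = 0.50, tau_j_scale = 0.50, tau_hL_scale = 0.66,
                g_Na_scale = 1.39, g_NaL_scale = 1.39)
}

#' Apicobasal I_Ks-like scale
#'
#' Multiplicative factor on the delayed rectifier conductance representing the
#' apicobasal gradient in slow delayed rectifier current. The default value
#' was tuned so that an apex cell (factor applied) is about 11 ms shorter in
#' APD90 than a base cell (factor 1) at 2 Hz pacing.
#' @return A single numeric factor.
#' @export
apicobasal_iks_scale <- function() 1.23

`%||%` <- function(a, b) if (is.null(a)) b else a
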