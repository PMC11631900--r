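# Shared fixtures, lazily computed once per test session and cached, so the
# expensive simulations (restitution sweeps, strand CV panel, the 2D re-entry
# run) are shared between the module tests and the acceptance tests.

vf_cache_env <- new.env(parent = emptyenv())

vf_fixture <- function(name, expr) {
  if (!exists(name, envir = vf_cache_env, inherits = FALSE))
    assign(name, force(expr), envir = vf_cache_env)
  get(name, envir = vf_cache_env, inherits = FALSE)
}

fix_variant_curve <- function() vf_fixture("variant_curve", {
  s1s2_restitution(make_cell_model(delta = vf_variant_delta()))
})

fix_baseline_curve <- function() vf_fixture("baseline_curve", {
  s1s2_restitution(make_cell_model())
})

# conduction-velocity panel: calibrated diffusivity, baseline and variant CV
# at that diffusivity, and the reduced-conductivity scale and CVs
fix_cv_panel <- function() vf_fixture("cv_panel", {
  mb <- make_cell_model()
  mv <- make_cell_model(delta = vf_variant_delta())
  cal <- calibrate_conductivity(mb, target_cv = 65, D0 = 0.002)
  cv_base <- cal$cv
  cv_var <- strand_cv(mv, cal$D)
  red <- conductivity_scale_for_cv_ratio(mb, cal$D, ratio = 0.8)
  cv_var_red <- strand_cv(mv, cal$D * red$scale)
  list(D = cal$D, cv_base = cv_base, cv_var = cv_var,
       scale = red$scale, cv_base_red = red$cv, cv_var_red = cv_var_red)
})

# 2 Hz steady-pacing APD90 of a model (mean of the last two beats, which
# makes the biomarker well defined even for alternans-prone variants)
apd90_2hz <- function(model, n_beats = 8, cl = 500) {
  rs <- resting_state(model, duration = 2000)
  tr <- simulate_cell(model, pacing_schedule(cl, n_beats),
                      duration = cl * n_beats, init = rs,
                      dt = 0.02, record_dt = 0.25)
  a <- apd(tr)
  a <- a[a$repolarised, ]
  mean(utils::tail(a$apd, 2))
}

fix_apd_by_severity <- function() vf_fixture("apd_by_severity", {
  out <- list()
  for (ct in cell_types()) {
    out[[ct]] <- vapply(c("healthy", "mild", "moderate"), function(sev) {
      apd90_2hz(make_cell_model(ct, ischaemia_config(sev),
                                delta = vf_variant_delta()))
    }, numeric(1))
  }
  out
})

# the shared 2D fixture: ischaemic sheet (core + border zone), reduced
# conductivity, escalating remote severity (protocol III analogue), re-entry
# induced by a cross-field S2; reused by the PS-oracle, persistence and
# end-to-end AMSA tests
fix_reentry <- function() vf_fixture("reentry", {
  spec <- regional_ischaemia_spec("anteroseptal", "transmural", radius_mm = 7,
                                  border_width_mm = 4)
  prot <- severity_protocol("III", switch_time = 600)
  tis <- build_tissue(spec, prot, nx = 60, ny = 60, dx_mm = 0.4,
                      conductivity_scale = 0.674)
  coupling <- 150
  movie <- induce_reentry(tis, "cross_field", coupling_ms = coupling,
                          origin = 10, duration = 10 + coupling + 2400,
                          dt = 0.03, frame_dt = 5)
  list(tissue = tis, movie = movie, s2 = 10 + coupling,
       last_stimulus = 10 + coupling)
})

# brute-force O(n^2) discrete Fourier transform (oracle for the fft path)
brute_dft_amplitude <- function(x) {
  n <- length(x)
  k <- 0:(floor(n / 2) - 1)
  amp <- vapply(k, function(kk) {
    w <- exp(-2i * pi * kk * (0:(n - 1)) / n)
    2 * Mod(sum(x * w)) / n
  }, numeric(1))
  amp
}

# construct a spectral_window directly from samples (for closed-form oracles)
raw_window <- function(x, fs = 250, taper_alpha = 0) {
  x <- x - mean(x)
  structure(list(samples = x, tapered = x * tukey_window(length(x), taper_alpha),
                 fs = fs, start_ms = 0, end_ms = length(x) / fs * 1000,
                 taper_alpha = taper_alpha, id = 1L),
            class = "spectral_window")
}

# random phantom-field specification generator for the PS fixture suite
random_phantom_spec <- function(seed) {
  set.seed(seed)
  nx <- sample(60:90, 1)
  ny <- sample(60:90, 1)
  k <- sample(1:4, 1)
  repeat {
    s <- data.frame(x = runif(k, 16, nx - 15), y = runif(k, 16, ny - 15),
                    chirality = sample(c(-1, 1), k, replace = TRUE))
    if (k == 1) break
    d <- as.matrix(stats::dist(s[, c("x", "y")]))
    diag(d) <- Inf
    if (min(d) >= 12) break
  }
  # rotor rates span the physiological VF range; below ~4 Hz the smooth
  # phantom profile never attains the 2 mV/ms rate isovalue, so the detector
  # criterion would be vacuously untestable
  phantom_field_spec(nx, ny, s, rotation_hz = runif(1, 5, 8), wavelength = 40)
}
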