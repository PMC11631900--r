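# Synthetic-data generators: surrogate VF ECGs with controlled spectra and
# phantom voltage movies with known phase-singularity content. Every stage of
# the analysis is testable against these without running the tissue solver.

#' Surrogate VF ECG specification
#'
#' @param duration_s Record length (s).
#' @param fs Sampling rate (Hz).
#' @param components `data.frame(freq, amp)`: sinusoid frequencies (Hz, below
#'   Nyquist) and amplitudes (mV).
#' @param noise_mv Broadband Gaussian noise level (mV, standard deviation).
#' @param amp_drift Fractional amplitude change per second.
#' @param freq_drift Dominant-frequency drift (Hz/s) applied to every
#'   component.
#' @param seed Integer seed.
#' @return Object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(duration_s = 8, fs = 500,
                           components = data.frame(freq = c(4, 5.5, 7),
                                                   amp = c(0.6, 0.4, 0.3)),
                           noise_mv = 0.02, amp_drift = 0, freq_drift = 0,
                           seed = 1L) {
  if (any(components$freq >= fs / 2)) stop("component above Nyquist")
  if (any(components$amp < 0)) stop("amplitudes must be >= 0")
  structure(list(duration_s = duration_s, fs = fs, components = components,
                 noise_mv = noise_mv, amp_drift = amp_drift,
                 freq_drift = freq_drift, seed = as.integer(seed)),
            class = "surrogate_spec")
}

#' Severity-styled surrogate specifications
#'
#' Presets mirroring the VF regimes by remote-ischaemia severity: healthy-RM
#' fibrillation has high amplitude and a broad low band (dominant frequency
#' 1.5-5.5 Hz); mild is intermediate (3-9 Hz); moderate (global ischaemia)
#' gives stable low-amplitude (~0.3 mV) waves near 8 Hz.
#'
#' @param style `"healthy"`, `"mild"`, `"moderate"`.
#' @param seed Integer seed.
#' @return A [surrogate_spec()].
#' @export
severity_styled_spec <- function(style = c("healthy", "mild", "moderate"),
                                 seed = 1L) {
  style <- match.arg(style)
  comp <- switch(style,
    healthy = data.frame(freq = c(2, 3.2, 4.4, 5.4), amp = c(0.9, 0.7, 0.5, 0.3)),
    mild = data.frame(freq = c(3.5, 5, 6.5, 8.5), amp = c(0.35, 0.3, 0.25, 0.15)),
    moderate = data.frame(freq = c(7.8, 8.1), amp = c(0.22, 0.08))
  )
  noise <- switch(style, healthy = 0.05, mild = 0.03, moderate = 0.01)
  surrogate_spec(components = comp, noise_mv = noise, seed = seed)
}

#' Generate a surrogate VF ECG
#'
#' Sum of sinusoids with optional linear amplitude and frequency drift plus
#' seeded broadband noise; bit-identical for identical specs.
#'
#' @param spec A [surrogate_spec()].
#' @return An `ecg_trace`.
#' @export
surrogate_vf_ecg <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  n <- round(spec$duration_s * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  x <- numeric(n)
  for (k in seq_len(nrow(spec$components))) {
    f0 <- spec$components$freq[k]
    a0 <- spec$components$amp[k]
    finst <- f0 + spec$freq_drift * t
    phase <- 2 * pi * cumsum(finst) / spec$fs
    x <- x + a0 * (1 + spec$amp_drift * t) * sin(phase + k)
  }
  if (spec$noise_mv > 0)
    x <- x + withr_seed(spec$seed, rnorm(n, sd = spec$noise_mv))
  ecg_trace(x, spec$fs, lead_name = "surrogate")
}

#' Phantom spiral-field specification
#'
#' @param nx,ny Grid size.
#' @param singularities `data.frame(x, y, chirality)` with positions in grid
#'   cells and chirality +1/-1; singularities must be at least 8 cells apart.
#' @param rotation_hz Rotation frequency (Hz, > 0).
#' @param wavelength Spiral wavelength (grid cells).
#' @return Object of class `phantom_spec`.
#' @export
phantom_field_spec <- function(nx = 100, ny = 100,
                               singularities = data.frame(x = 50, y = 50,
                                                          chirality = 1),
                               rotation_hz = 5, wavelength = 40) {
  if (rotation_hz <= 0) stop("rotation frequency must be > 0")
  s <- singularities
  if (nrow(s) > 1) {
    d <- as.matrix(stats::dist(s[, c("x", "y")]))
    diag(d) <- Inf
    if (min(d) < 8) stop("singularities closer than 8 grid cells")
  }
  structure(list(nx = nx, ny = ny, singularities = s,
                 rotation_hz = rotation_hz, wavelength = wavelength),
            class = "phantom_spec")
}

phantom_phase <- function(spec, t_ms) {
  X <- matrix(seq_len(spec$nx), spec$nx, spec$ny)
  Y <- matrix(seq_len(spec$ny), spec$nx, spec$ny, byrow = TRUE)
  ph <- 2 * pi * spec$rotation_hz * t_ms / 1000
  rmin <- NULL
  for (k in seq_len(nrow(spec$singularities))) {
    s <- spec$singularities[k, ]
    ph <- ph + s$chirality * atan2(Y - s$y, X - s$x)
    r <- sqrt((X - s$x)^2 + (Y - s$y)^2)
    rmin <- if (is.null(rmin)) r else pmin(rmin, r)
  }
  ph <- ph - 2 * pi * rmin / spec$wavelength
  atan2(sin(ph), cos(ph))
}

# smooth action-potential-shaped mapping from phase to potential (mV)
phase_to_vm <- function(phase) {
  -85 + 105 * ((1 + cos(phase)) / 2)^3
}

#' Phantom spiral movie with known singularity content
#'
#' Builds a membrane-potential movie from superposed Archimedean-spiral phase
#' fields mapped through a smooth action-potential-shaped profile spanning
#' -85 to +20 mV. The specified singularity positions and chiralities are the
#' ground truth carried in the result.
#'
#' @param spec A [phantom_field_spec()].
#' @param duration_ms Movie length (ms).
#' @param frame_dt Frame interval (ms).
#' @return A `sim_movie` with a `truth` field.
#' @export
phantom_spiral_movie <- function(spec, duration_ms = 400, frame_dt = 5) {
  stopifnot(inherits(spec, "phantom_spec"))
  times <- seq(0, duration_ms, by = frame_dt)
  frames <- vapply(times, function(t) {
    as.vector(phase_to_vm(phantom_phase(spec, t)))
  }, numeric(spec$nx * spec$ny))
  structure(list(frames = frames, frame_times = times,
                 nx = spec$nx, ny = spec$ny, dx_mm = 1,
                 truth = spec$singularities, spec = spec),
            class = "sim_movie")
}

#' Scenario descriptor grid
#'
#' The cross of the regional-ischaemia scenarios (control plus three
#' locations x two transmural extents) with the three remote-severity
#' protocols: 21 uniquely named descriptors.
#'
#' @return `data.frame` with `name`, `location`, `extent`, `protocol`.
#' @export
scenario_grid <- function() {
  base <- rbind(
    data.frame(location = "control", extent = NA_character_),
    expand.grid(location = c("anteroseptal", "lateral", "inferior"),
                extent = c("transmural", "subendocardial"),
                stringsAsFactors = FALSE)
  )
  out <- merge(base, data.frame(protocol = c("I", "II", "III")), by = NULL)
  out$name <- paste0(out$location,
                     ifelse(is.na(out$extent), "", paste0("-", out$extent)),
                     "-", out$protocol)
  out[order(out$protocol, out$location, out$extent),
      c("name", "location", "extent", "protocol")]
}
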