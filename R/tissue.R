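# 2D monodomain tissue layer: regional ischaemia geometry, remote-severity
# protocols, conductivity calibration, stimulation and pseudo-ECG electrodes.

#' Regional ischaemia specification
#'
#' Geometry of the ischaemic core zone and its lateral border zone on the 2D
#' sheet. `location` picks a stereotyped centre on the sheet; `extent`
#' distinguishes a full-thickness (`transmural`) disc from a half-disc
#' (`subendocardial`, the half toward the endocardial sheet edge). `control`
#' has no core or border cells.
#'
#' @param location One of `"anteroseptal"`, `"lateral"`, `"inferior"`,
#'   `"control"`.
#' @param extent `"transmural"` or `"subendocardial"`.
#' @param radius_mm Core radius (mm).
#' @param border_width_mm Lateral border-zone width (mm).
#' @param centre Optional `c(x, y)` in mm overriding the stereotyped centre.
#' @return Object of class `regional_ischaemia_spec`.
#' @export
regional_ischaemia_spec <- function(location = c("anteroseptal", "lateral",
                                                 "inferior", "control"),
                                    extent = c("transmural", "subendocardial"),
                                    radius_mm = 10, border_width_mm = 5,
                                    centre = NULL) {
  location <- match.arg(location)
  extent <- match.arg(extent)
  if (location != "control" && radius_mm <= 0) stop("radius must be > 0")
  structure(list(location = location, extent = extent, radius_mm = radius_mm,
                 border_width_mm = border_width_mm, centre = centre),
            class = "regional_ischaemia_spec")
}

#' Remote-myocardium severity protocol
#'
#' Time course of ischaemic severity in the remote myocardium: protocol I is
#' healthy throughout; II switches healthy to mild at the (first) switch time;
#' III starts mild and switches to moderate.
#'
#' @param tag `"I"`, `"II"` or `"III"`.
#' @param switch_time ms at which the severity changes (protocols II and III).
#' @return Object of class `severity_protocol` with `phases` (severity labels)
#'   and `times` (phase start times, first is 0).
#' @export
severity_protocol <- function(tag = c("I", "II", "III"), switch_time = NULL) {
  tag <- match.arg(tag)
  def <- switch(tag,
    I   = list(phases = "healthy", times = 0),
    II  = list(phases = c("healthy", "mild"), times = c(0, 6000)),
    III = list(phases = c("mild", "moderate"), times = c(0, 12000))
  )
  if (!is.null(switch_time) && length(def$phases) == 2)
    def$times[2] <- switch_time
  structure(list(tag = tag, phases = def$phases, times = def$times),
            class = "severity_protocol")
}

# per-cell parameter matrix for one remote severity phase
tissue_param_matrix <- function(tissue, remote_severity) {
  ct <- as.vector(tissue$celltype)
  w <- as.vector(tissue$w_core)
  core_cfg <- tissue$core_config
  rem_cfg <- ischaemia_config(remote_severity)
  npar <- length(vfib_par_names)
  out <- matrix(0, npar, length(ct))
  for (k in seq_along(cell_types())) {
    idx <- ct == k
    if (!any(idx)) next
    base_core <- make_cell_model(cell_types()[k], core_cfg, tissue$delta)$parameters
    base_rem <- make_cell_model(cell_types()[k], rem_cfg, tissue$delta)$parameters
    # linear interpolation of the parameter table by core weight
    out[, idx] <- outer(unname(base_core), w[idx]) +
      outer(unname(base_rem), 1 - w[idx])
  }
  rownames(out) <- vfib_par_names
  out
}

#' Build a 2D tissue grid with regional ischaemia
#'
#' Core cells carry the (moderate) core ischaemia configuration, remote cells
#' the protocol's current severity, and border cells parameters linearly
#' interpolated between core and remote values by Euclidean distance across
#' the border width. Cell types are laid out in transmural bands (50%
#' endocardial, 30% mid-myocardial, 20% epicardial along y).
#'
#' @param spec A [regional_ischaemia_spec()].
#' @param protocol A [severity_protocol()].
#' @param nx,ny Grid size in cells (at least 50 x 50).
#' @param dx_mm Grid spacing (mm).
#' @param D_long Longitudinal diffusivity (cm^2/ms); the package default
#'   reproduces a 65 cm/s planar wave for the healthy baseline model.
#' @param D_ratio Transverse-to-longitudinal diffusivity ratio.
#' @param fibre_angle Fibre direction (radians, from the x axis).
#' @param delta [variant_delta()] applied to every cell (the VF-optimised
#'   variant by default, as in the fibrillation simulations).
#' @param core_config Ischaemia configuration of the core zone.
#' @param conductivity_scale Global scale on the diffusivity tensor (the
#'   fibrillation runs use the reduced-conductivity factor, see
#'   [conductivity_scale_for_cv_ratio()]).
#' @return Object of class `tissue_grid`.
#' @export
build_tissue <- function(spec, protocol = severity_protocol("I"),
                         nx = 200, ny = 200, dx_mm = 0.25,
                         D_long = vfib_default_conductivity(),
                         D_ratio = (50 / 65)^2, fibre_angle = 0,
                         delta = vf_variant_delta(),
                         core_config = ischaemia_config("moderate"),
                         conductivity_scale = 1) {
  stopifnot(inherits(spec, "regional_ischaemia_spec"),
            inherits(protocol, "severity_protocol"))
  if (nx < 50 || ny < 50) stop("grid must be at least 50 x 50 cells")
  Lx <- nx * dx_mm
  Ly <- ny * dx_mm
  if (spec$location != "control" &&
      spec$border_width_mm > min(Lx, Ly)) stop("border width exceeds grid")
  xc <- (seq_len(nx) - 0.5) * dx_mm
  yc <- (seq_len(ny) - 0.5) * dx_mm
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  centre <- spec$centre %||% switch(spec$location,
    anteroseptal = c(0.30 * Lx, 0.65 * Ly),
    lateral      = c(0.75 * Lx, 0.55 * Ly),
    inferior     = c(0.50 * Lx, 0.25 * Ly),
    control      = c(NA, NA)
  )
  if (spec$location == "control") {
    d_core <- matrix(Inf, nx, ny)
  } else {
    d_core <- sqrt((X - centre[1])^2 + (Y - centre[2])^2) - spec$radius_mm
    if (spec$extent == "subendocardial") {
      # only the half toward the endocardial edge (low y) is occluded
      d_half <- Y - centre[2]
      d_core <- pmax(d_core, d_half)
    }
  }
  w_core <- pmin(1, pmax(0, 1 - d_core / spec$border_width_mm))
  region <- matrix("remote", nx, ny)
  region[d_core <= 0] <- "core"
  region[d_core > 0 & w_core > 0] <- "border"
  # transmural bands along y: endo (bottom 50%), mid (30%), epi (top 20%)
  mix <- transmural_mix()
  yfrac <- (matrix(seq_len(ny), nx, ny, byrow = TRUE) - 0.5) / ny
  celltype <- matrix(1L, nx, ny)
  celltype[yfrac >= mix[1]] <- 2L
  celltype[yfrac >= mix[1] + mix[2]] <- 3L

  th <- fibre_angle
  DL <- D_long * conductivity_scale
  DT <- D_long * D_ratio * conductivity_scale
  structure(list(
    nx = nx, ny = ny, dx_mm = dx_mm,
    Dxx = DL * cos(th)^2 + DT * sin(th)^2,
    Dyy = DL * sin(th)^2 + DT * cos(th)^2,
    Dxy = (DL - DT) * sin(th) * cos(th),
    fibre_angle = th, D_long = DL, D_ratio = D_ratio,
    region = region, w_core = w_core, celltype = celltype,
    protocol = protocol, spec = spec, delta = delta,
    core_config = core_config
  ), class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat("<tissue_grid>", x$nx, "x", x$ny, "cells @", x$dx_mm, "mm |",
      x$spec$location, x$spec$extent, "| protocol", x$protocol$tag, "\n")
  cat("  regions: core", sum(x$region == "core"), "border",
      sum(x$region == "border"), "remote", sum(x$region == "remote"), "\n")
  invisible(x)
}

# Default longitudinal diffusivity (cm^2/ms): calibrated so a planar wave in
# the healthy baseline endocardial strand travels at 65 cm/s (dx = 0.25 mm,
# dt = 0.02 ms). Recompute with calibrate_conductivity().
#' Package default longitudinal diffusivity
#' @return Diffusivity in cm^2/ms.
#' @export
vfib_default_conductivity <- function() 0.00209026

#' Measure planar conduction velocity on a 1D strand
#'
#' Stimulates the first cells of a uniform strand and returns the conduction
#' velocity from a linear fit of activation time against distance over the
#' central half of the strand.
#'
#' @param model An `ionic_model` (applied uniformly).
#' @param D Diffusivity (cm^2/ms).
#' @param n_cells Strand length in cells.
#' @param dx_mm Spacing (mm).
#' @param dt Time step (ms).
#' @param stim_amp,stim_dur Stimulus strength (uA/uF) and duration (ms).
#' @return Conduction velocity in cm/s (`NA` if the wave fails to propagate).
#' @export
strand_cv <- function(model, D, n_cells = 120, dx_mm = 0.25, dt = 0.02,
                      stim_amp = 30, stim_dur = 2) {
  stopifnot(inherits(model, "ionic_model"))
  dx_cm <- dx_mm / 10
  rs <- resting_state(model)
  y0 <- matrix(rs, length(rs), n_cells)
  par <- matrix(unname(model$parameters), length(model$parameters), n_cells)
  stims <- list(list(t0 = 2, dur = stim_dur, amp = stim_amp, cells = 1:4))
  dur <- 20 + n_cells * dx_cm / 0.02 # generous: slowest plausible 20 cm/s
  res <- monodomain_cpp(n_cells, 1L, dx_cm, rep(D, n_cells), rep(D, n_cells),
                        rep(0, n_cells), list(par), 0, y0, stims,
                        dur, dt, dur, FALSE)
  act <- res$activation_times
  i1 <- round(n_cells * 0.25)
  i2 <- round(n_cells * 0.75)
  sel <- i1:i2
  if (any(is.na(act[sel]))) return(NA_real_)
  fit <- stats::lm(act[sel] ~ sel)
  slope <- unname(stats::coef(fit)[2]) # ms per cell
  if (!is.finite(slope) || slope <= 0) return(NA_real_)
  (dx_cm / slope) * 1000 # cm/s
}

#' Calibrate diffusivity to a target conduction velocity
#'
#' Deterministic fixed-point search exploiting CV proportional to the square
#' root of the diffusivity; converges to the target within `tol` (relative).
#'
#' @param model An `ionic_model`.
#' @param target_cv Target conduction velocity (cm/s).
#' @param D0 Starting diffusivity (cm^2/ms).
#' @param tol Relative tolerance on the achieved CV.
#' @param max_iter Iteration cap.
#' @inheritParams strand_cv
#' @return List with `D` (calibrated diffusivity) and `cv` (achieved cm/s).
#' @export
calibrate_conductivity <- function(model, target_cv = 65, D0 = 0.001,
                                   tol = 0.01, max_iter = 12,
                                   n_cells = 120, dx_mm = 0.25, dt = 0.02) {
  if (target_cv <= 0) stop("target_cv must be > 0")
  D <- D0
  for (it in seq_len(max_iter)) {
    cv <- strand_cv(model, D, n_cells = n_cells, dx_mm = dx_mm, dt = dt)
    if (is.na(cv)) {
      D <- D * 4
      if (it == max_iter) stop("no propagation at any tested conductivity")
      next
    }
    if (abs(cv - target_cv) / target_cv < tol)
      return(list(D = D, cv = cv))
    D <- D * (target_cv / cv)^2
  }
  stop("conductivity calibration did not converge")
}

#' Conductivity scale yielding a target CV ratio
#'
#' Finds the multiplicative diffusivity scale at which the given model's
#' planar CV equals `ratio` times its CV at the unscaled diffusivity (for the
#' reduced-conductivity fibrillation substrate the target is 0.8).
#'
#' @param model An `ionic_model`.
#' @param D Unscaled diffusivity (cm^2/ms).
#' @param ratio Target CV ratio (0 < ratio <= 1).
#' @param tol Relative tolerance.
#' @inheritParams strand_cv
#' @return List with `scale`, `cv` (achieved) and `cv_ref` (unscaled CV).
#' @export
conductivity_scale_for_cv_ratio <- function(model, D, ratio = 0.8, tol = 0.005,
                                            n_cells = 120, dx_mm = 0.25,
                                            dt = 0.02) {
  cv_ref <- strand_cv(model, D, n_cells = n_cells, dx_mm = dx_mm, dt = dt)
  if (is.na(cv_ref)) stop("reference strand does not propagate")
  target <- ratio * cv_ref
  s <- ratio^2
  for (it in 1:10) {
    cv <- strand_cv(model, D * s, n_cells = n_cells, dx_mm = dx_mm, dt = dt)
    if (is.na(cv)) stop("scaled strand does not propagate")
    if (abs(cv - target) / target < tol)
      return(list(scale = s, cv = cv, cv_ref = cv_ref))
    s <- s * (target / cv)^2
  }
  stop("conductivity scaling did not converge")
}

# ---- stimulation and simulation -----------------------------------------------

cells_index <- function(tissue, mask) which(as.vector(mask))

#' Edge stimulus event
#'
#' @param tissue A `tissue_grid`.
#' @param side One of `"left"`, `"right"`, `"bottom"`, `"top"`.
#' @param width_mm Depth of the stimulated band (mm).
#' @param t0 Onset (ms); `dur`, `amp` as in the cell stimulus.
#' @return Stimulus event list for [run_monodomain()].
#' @export
edge_stimulus <- function(tissue, side = "left", width_mm = 1, t0 = 0,
                          dur = 2, amp = 30) {
  n <- max(1L, round(width_mm / tissue$dx_mm))
  ix <- matrix(seq_len(tissue$nx), tissue$nx, tissue$ny)
  iy <- matrix(seq_len(tissue$ny), tissue$nx, tissue$ny, byrow = TRUE)
  mask <- switch(side,
    left = ix <= n, right = ix > tissue$nx - n,
    bottom = iy <= n, top = iy > tissue$ny - n,
    stop("unknown side"))
  list(t0 = t0, dur = dur, amp = amp, cells = cells_index(tissue, mask))
}

#' Half-plane (cross-field) stimulus event
#'
#' Stimulates the half of the sheet below the horizontal midline, the classic
#' S2 geometry for cross-field spiral initiation.
#' @inheritParams edge_stimulus
#' @export
half_plane_stimulus <- function(tissue, t0, dur = 2, amp = 30) {
  iy <- matrix(seq_len(tissue$ny), tissue$nx, tissue$ny, byrow = TRUE)
  list(t0 = t0, dur = dur, amp = amp,
       cells = cells_index(tissue, iy <= tissue$ny / 2))
}

tissue_initial_state <- function(tissue) {
  ncell <- tissue$nx * tissue$ny
  y0 <- matrix(0, length(vfib_init_state), ncell)
  rem_cfg <- ischaemia_config(tissue$protocol$phases[1])
  for (k in seq_along(cell_types())) {
    for (reg in c("core", "other")) {
      idx <- if (reg == "core")
        as.vector(tissue$celltype) == k & as.vector(tissue$w_core) >= 0.5
      else
        as.vector(tissue$celltype) == k & as.vector(tissue$w_core) < 0.5
      if (!any(idx)) next
      cfg <- if (reg == "core") tissue$core_config else rem_cfg
      m <- make_cell_model(cell_types()[k], cfg, tissue$delta)
      y0[, idx] <- resting_state(m, duration = 3000)
    }
  }
  y0
}

#' Run a monodomain tissue simulation
#'
#' Operator-split explicit integration (Rush-Larsen gating, forward-Euler
#' reaction, flux-form finite-difference diffusion with no-flux boundaries).
#' Remote-cell parameters switch exactly at the protocol's phase times. The
#' run is deterministic; identical inputs give bit-identical movies.
#'
#' @param tissue A `tissue_grid`.
#' @param stimuli List of stimulus events (see [edge_stimulus()]).
#' @param duration ms.
#' @param dt Time step (ms); must satisfy the explicit diffusion stability
#'   bound `dt <= dx^2 / (4 Dmax)`.
#' @param frame_dt Frame interval of the recorded movie (ms).
#' @param init Optional initial state matrix (defaults to per-region rest).
#' @param record_frames Set `FALSE` to skip movie frames.
#' @return Object of class `sim_movie`: `frames` (cells x frames),
#'   `frame_times`, grid geometry, `activation_times`, `final_state`.
#' @export
run_monodomain <- function(tissue, stimuli, duration, dt = 0.02, frame_dt = 2,
                           init = NULL, record_frames = TRUE) {
  stopifnot(inherits(tissue, "tissue_grid"))
  ncell <- tissue$nx * tissue$ny
  dx_cm <- tissue$dx_mm / 10
  Dmax <- max(tissue$Dxx, tissue$Dyy)
  if (dt > dx_cm^2 / (4 * Dmax))
    stop(sprintf("dt = %g violates the diffusion stability bound %.4g ms",
                 dt, dx_cm^2 / (4 * Dmax)))
  epochs <- lapply(tissue$protocol$phases,
                   function(ph) tissue_param_matrix(tissue, ph))
  y0 <- init %||% tissue_initial_state(tissue)
  res <- monodomain_cpp(tissue$nx, tissue$ny, dx_cm,
                        rep(tissue$Dxx, ncell), rep(tissue$Dyy, ncell),
                        rep(tissue$Dxy, ncell),
                        epochs, tissue$protocol$times, y0, stimuli,
                        duration, dt, frame_dt, record_frames)
  if (res$diverged)
    stop(sprintf("tissue solver divergence at t = %.2f ms (cell %d)",
                 res$t_fail, res$cell_fail))
  structure(list(frames = res$frames, frame_times = res$frame_times,
                 nx = tissue$nx, ny = tissue$ny, dx_mm = tissue$dx_mm,
                 activation_times = res$activation_times,
                 final_state = res$final_state,
                 stimuli = stimuli, tissue = tissue),
            class = "sim_movie")
}

#' @export
print.sim_movie <- function(x, ...) {
  cat("<sim_movie>", x$nx, "x", x$ny, "cells,", ncol(x$frames), "frames,",
      sprintf("%.0f ms\n", max(x$frame_times)))
  invisible(x)
}

#' Extract one frame of a movie as a matrix
#' @param movie A `sim_movie`.
#' @param i Frame index.
#' @return nx x ny matrix of membrane potential (mV).
#' @export
movie_frame <- function(movie, i) {
  matrix(movie$frames[, i], movie$nx, movie$ny)
}

#' Induce re-entry in a tissue sheet
#'
#' `ramp` applies the VF-induction ramp at the left edge and then stops
#' pacing; `cross_field` applies one edge beat followed by a premature
#' half-plane stimulus at the given coupling interval. Failure to induce
#' re-entry is a valid outcome; inspect the movie with [ps_timeseries()].
#'
#' @param tissue A `tissue_grid`.
#' @param method `"ramp"` or `"cross_field"`.
#' @param duration Total simulated time (ms).
#' @param coupling_ms S1-S2 interval for the cross-field method.
#' @param origin First-stimulus time (ms).
#' @param dt,frame_dt Integration and frame steps (ms).
#' @return A `sim_movie`.
#' @export
induce_reentry <- function(tissue, method = c("ramp", "cross_field"),
                           duration = NULL, coupling_ms = 250, origin = 10,
                           dt = 0.02, frame_dt = 2) {
  method <- match.arg(method)
  if (method == "ramp") {
    sch <- ramp_pacing_schedule(origin = origin)
    stims <- lapply(sch$times, function(t0)
      edge_stimulus(tissue, "left", t0 = t0, dur = 2, amp = 30))
    duration <- duration %||% (max(sch$times) + 2000)
  } else {
    stims <- list(edge_stimulus(tissue, "left", t0 = origin, dur = 2, amp = 30),
                  half_plane_stimulus(tissue, t0 = origin + coupling_ms))
    duration <- duration %||% (origin + coupling_ms + 1500)
  }
  run_monodomain(tissue, stims, duration, dt = dt, frame_dt = frame_dt)
}

# ---- electrodes and pseudo-ECG ------------------------------------------------

#' Named bipolar electrode pairs around the sheet
#'
#' Four defibrillation-pad-like bipolar pairs at distinct angular positions
#' around the tissue sheet, plus a precordial-like pair over the centre, all
#' at a configurable off-plane distance.
#'
#' @param tissue A `tissue_grid` (for the sheet extent).
#' @param distance_mm Off-plane electrode distance (mm).
#' @return Object of class `electrode_set`: named list of pairs, each with
#'   `pos` and `neg` electrode coordinates `c(x, y, z)` in mm.
#' @export
electrode_set <- function(tissue, distance_mm = 20) {
  L <- c(tissue$nx, tissue$ny) * tissue$dx_mm
  cx <- L[1] / 2
  cy <- L[2] / 2
  z <- distance_mm
  p <- function(fx, fy, zz = z) c(fx * L[1], fy * L[2], zz)
  pairs <- list(
    `apex-anterior`      = list(pos = p(0.15, 0.15), neg = p(0.60, 1.10)),
    `anterior-lateral`   = list(pos = p(0.60, 1.10), neg = p(1.10, 0.50)),
    `apex-posterior`     = list(pos = p(0.15, 0.15), neg = p(0.60, -0.10, 2 * z)),
    `anterior-posterior` = list(pos = p(0.60, 1.10), neg = p(0.60, -0.10, 2 * z)),
    precordial           = list(pos = c(cx, cy, z / 2), neg = p(3, 3, 5 * z))
  )
  structure(list(pairs = pairs, distance_mm = distance_mm), class = "electrode_set")
}

#' Infinite-medium pseudo-ECG at bipolar electrode pairs
#'
#' Unipolar potentials are computed as the infinite-medium integral of
#' `-grad(Vm) . grad(1/r)` over the sheet, weighted by the local conductivity
#' scale; each bipolar trace is the positive minus the negative pole, scaled
#' to mV by `gain`.
#'
#' @param movie A `sim_movie`.
#' @param electrodes An [electrode_set()].
#' @param gain Output scale (mV per computed unit).
#' @param conductivity Optional per-cell conductivity weights (defaults to 1).
#' @return Named list of `ecg_trace` objects (sampling rate = frame rate).
#' @export
pseudo_ecg <- function(movie, electrodes = electrode_set(movie$tissue),
                       gain = 1, conductivity = NULL) {
  stopifnot(inherits(movie, "sim_movie"), inherits(electrodes, "electrode_set"))
  ncell <- movie$nx * movie$ny
  cond <- conductivity %||% rep(1, ncell)
  poles <- do.call(rbind, lapply(electrodes$pairs, function(pr) rbind(pr$pos, pr$neg)))
  if (length(movie$frame_times) < 2) stop("movie too short for an ECG")
  fs <- 1000 / diff(movie$frame_times[1:2])
  phi <- pseudo_ecg_cpp(movie$frames, movie$nx, movie$ny, movie$dx_mm,
                        poles, cond)
  out <- list()
  for (i in seq_along(electrodes$pairs)) {
    lead <- (phi[2 * i - 1, ] - phi[2 * i, ]) * gain
    out[[names(electrodes$pairs)[i]]] <-
      ecg_trace(lead, fs, lead_name = names(electrodes$pairs)[i])
  }
  out
}
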