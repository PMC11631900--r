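#' Construct a ventricular cell model
#'
#' Builds the parameter table of the reduced human ventricular ionic model for
#' a given transmural cell type, ischaemia configuration and sodium-current
#' variant delta. The baseline table is transformed multiplicatively: cell-type
#' factors, then the variant delta, then the ischaemia modifiers. With the
#' identity delta and a healthy configuration the baseline table is returned
#' unchanged.
#'
#' @param cell_type One of [cell_types()].
#' @param ischaemia An [ischaemia_config()].
#' @param delta A [variant_delta()].
#' @param iks_scale Apicobasal delayed-rectifier factor (1 = base;
#'   [apicobasal_iks_scale()] = apex).
#' @return An object of class `ionic_model`: list with `parameters` (named
#'   numeric vector), `cell_type`, `ischaemia`, `delta` and `state0`.
#' @export
make_cell_model <- function(cell_type = "endocardial",
                            ischaemia = ischaemia_config("healthy"),
                            delta = identity_delta(),
                            iks_scale = 1) {
  if (!cell_type %in% cell_types())
    stop("unknown cell type: ", cell_type)
  if (!inherits(delta, "variant_delta")) stop("delta must be a variant_delta")
  if (iks_scale <= 0) stop("iks_scale must be > 0")
  p <- vfib_base_params
  fac <- vfib_celltype_factors[[cell_type]]
  p["g_K"] <- p["g_K"] * fac["g_K"] * iks_scale
  p["g_si"] <- p["g_si"] * fac["g_si"]
  p["tau_h_scale"] <- p["tau_h_scale"] * delta$tau_h_scale
  p["tau_j_scale"] <- p["tau_j_scale"] * delta$tau_j_scale
  p["tau_hL_scale"] <- p["tau_hL_scale"] * delta$tau_hL_scale
  p["g_Na"] <- p["g_Na"] * delta$g_Na_scale
  p["g_NaL"] <- p["g_NaL"] * delta$g_NaL_scale
  if (any(p[c("g_Na", "g_NaL", "g_si", "g_K", "g_K1")] <= 0))
    stop("non-physical (<= 0) conductance")
  m <- structure(list(parameters = p, cell_type = cell_type,
                      ischaemia = ischaemia_config("healthy"),
                      delta = delta, state0 = vfib_init_state),
                 class = "ionic_model")
  apply_ischaemia(m, ischaemia)
}

#' Apply an ischaemia configuration to a cell model
#'
#' Sets extracellular potassium, the I_K(ATP) activation fraction and the
#' acidosis scales on the fast sodium and slow inward conductances. A healthy
#' configuration returns a model with parameters bit-identical to the input.
#'
#' @param model An `ionic_model`.
#' @param ischaemia An [ischaemia_config()].
#' @return The modified `ionic_model`.
#' @export
apply_ischaemia <- function(model, ischaemia) {
  stopifnot(inherits(model, "ionic_model"))
  if (!inherits(ischaemia, "ischaemia_config"))
    stop("ischaemia must be an ischaemia_config")
  p <- model$parameters
  if (ischaemia$severity != "healthy" ||
      ischaemia$extracellular_potassium != vfib_base_params[["Ko"]] ||
      ischaemia$katp_activation != 0 ||
      ischaemia$sodium_current_scale != 1 ||
      ischaemia$calcium_current_scale != 1) {
    p["Ko"] <- ischaemia$extracellular_potassium
    p["katp_frac"] <- ischaemia$katp_activation
    p["g_Na"] <- p["g_Na"] * ischaemia$sodium_current_scale
    p["g_si"] <- p["g_si"] * ischaemia$calcium_current_scale
  }
  model$parameters <- p
  model$ischaemia <- ischaemia
  model
}

#' Pacing schedule
#'
#' An ordered list of (cycle length, beat count) segments expanded into
#' stimulus times from a configurable origin.
#'
#' @param cycle_lengths Cycle lengths in ms, one per segment.
#' @param beat_counts Number of beats per segment.
#' @param origin Time of the first stimulus (ms).
#' @param amplitude Stimulus amplitude (uA/uF, depolarising positive).
#' @param stim_duration Stimulus duration (ms).
#' @return An object of class `pacing_schedule` with the expanded, strictly
#'   increasing stimulus `times`.
#' @export
pacing_schedule <- function(cycle_lengths, beat_counts, origin = 0,
                            amplitude = 50, stim_duration = 1) {
  if (length(cycle_lengths) != length(beat_counts))
    stop("cycle_lengths and beat_counts must have equal length")
  if (any(cycle_lengths <= 0)) stop("cycle lengths must be positive")
  if (any(beat_counts < 1)) stop("beat counts must be >= 1")
  intervals <- rep(cycle_lengths, beat_counts)
  times <- origin + c(0, cumsum(intervals[-length(intervals)]))
  structure(list(segments = data.frame(cycle_length = cycle_lengths,
                                       beat_count = as.integer(beat_counts)),
                 times = times, origin = origin, amplitude = amplitude,
                 stim_duration = stim_duration,
                 span = sum(intervals)),
            class = "pacing_schedule")
}

#' VF-induction ramp pacing schedule
#'
#' The fixed ramp used to induce fibrillation: 2 beats at a cycle length of
#' 350 ms, then 3 x 325 ms, 5 x 300 ms, 5 x 275 ms and 6 x 250 ms, spanning
#' approximately 6 s.
#'
#' @inheritParams pacing_schedule
#' @return A `pacing_schedule`.
#' @export
ramp_pacing_schedule <- function(origin = 0, amplitude = 50, stim_duration = 1) {
  pacing_schedule(c(350, 325, 300, 275, 250), c(2, 3, 5, 5, 6),
                  origin = origin, amplitude = amplitude,
                  stim_duration = stim_duration)
}

#' Simulate a single cell
#'
#' Integrates the ionic model with a Rush-Larsen gating update and forward
#' Euler for potential and calcium at a fixed step. The final state is
#' returned for warm-starting tissue simulations. Solver divergence (potential
#' outside \[-150, 100\] mV) aborts with the failure time.
#'
#' @param model An `ionic_model`.
#' @param schedule A `pacing_schedule`, or `NULL` for an unstimulated run.
#' @param duration Total simulated time (ms); defaults to the schedule span
#'   plus one final cycle length.
#' @param dt Integration step (ms).
#' @param record_dt Output sampling interval (ms).
#' @param init Initial state vector (defaults to the model's resting state).
#' @return An object of class `ap_trace`: `time` (ms), `Vm` (mV), `Cai` (uM),
#'   `stim_times`, `final_state`.
#' @export
simulate_cell <- function(model, schedule = NULL, duration = NULL,
                          dt = 0.01, record_dt = 0.1, init = NULL) {
  stopifnot(inherits(model, "ionic_model"))
  p <- model$parameters
  if (is.null(schedule)) {
    stim_times <- numeric(0)
    if (is.null(duration)) stop("duration required when there is no schedule")
  } else {
    stopifnot(inherits(schedule, "pacing_schedule"))
    stim_times <- schedule$times
    p["stim_amp"] <- schedule$amplitude
    p["stim_dur"] <- schedule$stim_duration
    if (is.null(duration))
      duration <- schedule$origin + schedule$span
    if (duration < max(stim_times) + p["stim_dur"])
      stop("duration does not cover the pacing schedule")
  }
  y0 <- init %||% model$state0
  res <- cell_sim_cpp(unname(p), unname(y0), stim_times, duration, dt, record_dt)
  if (res$diverged)
    stop(sprintf("solver divergence at t = %.3f ms", res$t_fail))
  structure(list(time = res$time, Vm = res$Vm, Cai = res$Cai * 1000,
                 stim_times = stim_times, final_state = res$final_state,
                 record_dt = record_dt),
            class = "ap_trace")
}

#' Relax a cell model to rest
#'
#' Runs the model without stimulation and returns the final state, which can
#' be passed as `init` to [simulate_cell()].
#'
#' @param model An `ionic_model`.
#' @param duration Relaxation time (ms).
#' @param dt Integration step (ms).
#' @return Numeric state vector.
#' @export
resting_state <- function(model, duration = 5000, dt = 0.02) {
  res <- cell_sim_cpp(unname(model$parameters), unname(model$state0),
                      numeric(0), duration, dt, duration)
  res$final_state
}

#' Action potential duration per beat
#'
#' For each stimulated beat, the activation time is the time of maximum
#' upstroke rate (dV/dt) and the duration runs from activation to the crossing
#' of the given repolarisation fraction between the beat peak and the beat
#' baseline (the pre-stimulus potential of that beat). Beats that fail to
#' repolarise to the threshold before the next stimulus are flagged and their
#' duration is `NA`.
#'
#' @param trace An `ap_trace` with at least one stimulated beat.
#' @param repolarisation_percent Repolarisation level (e.g. 90 for APD90).
#' @return `data.frame` with one row per beat: `beat`, `t_stim`, `t_act`,
#'   `peak`, `baseline`, `apd`, `repolarised`.
#' @export
apd <- function(trace, repolarisation_percent = 90) {
  stopifnot(inherits(trace, "ap_trace"))
  st <- trace$stim_times
  if (length(st) == 0) stop("no stimulated beat in trace")
  frac <- repolarisation_percent / 100
  t <- trace$time
  v <- trace$Vm
  ends <- c(st[-1], max(t) + trace$record_dt)
  out <- lapply(seq_along(st), function(k) {
    sel <- t >= st[k] & t < ends[k]
    if (sum(sel) < 3) return(NULL)
    tt <- t[sel]; vv <- v[sel]
    ibase <- which(t < st[k])
    baseline <- if (length(ibase)) v[max(ibase)] else vv[1]
    dv <- diff(vv) / diff(tt)
    iact <- which.max(dv)
    t_act <- tt[iact]
    ipk <- which.max(vv)
    peak <- vv[ipk]
    thr <- peak - frac * (peak - baseline)
    below <- which(vv < thr & seq_along(vv) > ipk)
    if (length(below) == 0) {
      return(data.frame(beat = k, t_stim = st[k], t_act = t_act, peak = peak,
                        baseline = baseline, apd = NA_real_,
                        repolarised = FALSE))
    }
    i2 <- below[1]; i1 <- i2 - 1
    t_cross <- tt[i1] + (thr - vv[i1]) / (vv[i2] - vv[i1]) * (tt[i2] - tt[i1])
    data.frame(beat = k, t_stim = st[k], t_act = t_act, peak = peak,
               baseline = baseline, apd = t_cross - t_act, repolarised = TRUE)
  })
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) stop("no analysable beat in trace")
  res
}

#' @export
print.ionic_model <- function(x, ...) {
  cat("<ionic_model>", x$cell_type, "| severity:", x$ischaemia$severity,
      "| Ko =", x$parameters[["Ko"]], "mM\n")
  d <- x$delta
  if (any(unlist(d) != 1))
    cat("  delta: tau_h x", d$tau_h_scale, ", tau_hL x", d$tau_hL_scale,
        ", g_Na x", d$g_Na_scale, "\n")
  invisible(x)
}

#' @export
print.ap_trace <- function(x, ...) {
  cat("<ap_trace>", length(x$time), "samples,",
      sprintf("%.0f ms, %d stimuli\n", max(x$time), length(x$stim_times)))
  invisible(x)
}

#' @export
plot.ap_trace <- function(x, ...) {
  graphics::plot(x$time, x$Vm, type = "l", xlab = "time (ms)",
                 ylab = "Vm (mV)", ...)
  invisible(x)
}
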