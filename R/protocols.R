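# Restitution protocols, alternans quantification and the population-of-models
# calibration cascade.

capture_ok <- function(trace, stim_time, window = 50, threshold = 0) {
  sel <- trace$time >= stim_time & trace$time <= stim_time + window
  any(trace$Vm[sel] > threshold)
}

new_restitution_curve <- function(df, protocol, alternans = NA_real_) {
  df <- df[order(df$di), ]
  rownames(df) <- NULL
  structure(list(points = df, protocol = protocol, alternans = alternans),
            class = "restitution_curve")
}

#' @export
print.restitution_curve <- function(x, ...) {
  cat("<restitution_curve>", x$protocol, "-", nrow(x$points), "points")
  if (!is.na(x$alternans)) cat(sprintf(", alternans %.2f ms", x$alternans))
  cat("\n")
  invisible(x)
}

#' @export
plot.restitution_curve <- function(x, ...) {
  graphics::plot(x$points$di, x$points$apd90, xlab = "DI (ms)",
                 ylab = "APD90 (ms)", ...)
  invisible(x)
}

#' S1S2 restitution protocol
#'
#' Paces the model with `n_s1` beats at `s1_cl`, then applies a single
#' premature stimulus at each coupling interval in `s2_list`. One point
#' (diastolic interval, APD90) is produced per captured S2 beat; a beat
#' captures when its peak exceeds 0 mV within 50 ms of the stimulus.
#' Around the shortest captured coupling interval the sweep is refined with
#' step `refine_step` to resolve the steep end of the curve.
#'
#' @param model An `ionic_model`.
#' @param s1_cl S1 cycle length (ms).
#' @param s2_list Coupling intervals to test (ms), each `<= s1_cl`.
#' @param n_s1 Number of S1 beats before the premature stimulus.
#' @param refine_step Refinement step near capture failure (ms); `NA` disables.
#' @param dt,record_dt Integration and output steps (ms).
#' @return A `restitution_curve` with columns `s2`, `di`, `apd90`.
#' @export
s1s2_restitution <- function(model, s1_cl = 600,
                             s2_list = seq(200, 600, by = 10),
                             n_s1 = 10, refine_step = 2,
                             dt = 0.01, record_dt = 0.1) {
  if (any(s2_list > s1_cl)) stop("S2 intervals must not exceed the S1 cycle length")
  rs <- resting_state(model)
  pre <- simulate_cell(model, pacing_schedule(s1_cl, n_s1 - 1),
                       duration = (n_s1 - 1) * s1_cl, init = rs,
                       dt = dt, record_dt = 0.5)
  st <- pre$final_state
  # reference run: the last S1 alone, to locate its APD90 crossing
  ref <- simulate_cell(model, pacing_schedule(s1_cl, 1), duration = s1_cl,
                       init = st, dt = dt, record_dt = record_dt)
  aref <- apd(ref)
  if (!aref$repolarised[1]) stop("S1 beat does not repolarise; no restitution curve")
  t_rep1 <- aref$t_act[1] + aref$apd[1]

  probe <- function(s2) {
    sch <- pacing_schedule(c(s2, s1_cl), c(1, 1))
    tr <- simulate_cell(model, sch, duration = s2 + s1_cl, init = st,
                        dt = dt, record_dt = record_dt)
    if (!capture_ok(tr, s2)) return(NULL)
    a <- apd(tr)
    if (nrow(a) < 2 || !a$repolarised[2] || is.na(a$apd[2])) return(NULL)
    di <- a$t_act[2] - t_rep1
    if (di <= 0) return(NULL)
    data.frame(s2 = s2, di = di, apd90 = a$apd[2])
  }
  s2s <- sort(s2_list)
  rows <- lapply(s2s, probe)
  got <- !vapply(rows, is.null, logical(1))
  if (!any(got)) stop("no captured S2 beat; empty restitution curve")
  s2_min <- min(s2s[got])
  if (!is.na(refine_step) && refine_step > 0) {
    fine <- setdiff(seq(max(min(s2s), s2_min - 10), s2_min + 10, by = refine_step), s2s)
    rows <- c(rows, lapply(fine, probe))
  }
  df <- do.call(rbind, rows)
  new_restitution_curve(df, "S1S2")
}

#' Dynamic restitution protocol
#'
#' Paces the model for `beats_per_cl` beats at each cycle length of the sweep,
#' carrying the state from one cycle length to the next. Per cycle length the
#' APD90 of the last two beats is recorded; the alternans amplitude is their
#' absolute difference, maximised over the sweep. Cycle lengths that lose 1:1
#' capture are recorded and excluded from the curve.
#'
#' @param model An `ionic_model`.
#' @param cl_sweep Cycle lengths (ms), typically decreasing.
#' @param beats_per_cl Beats per cycle length (`>= 2`).
#' @param dt,record_dt Integration and output steps (ms).
#' @return A `restitution_curve` (protocol `"dynamic"`) whose `alternans`
#'   field is the maximal alternans amplitude; `lost_capture` attribute lists
#'   cycle lengths without 1:1 capture.
#' @export
dynamic_restitution <- function(model, cl_sweep = seq(600, 220, by = -20),
                                beats_per_cl = 50, dt = 0.01, record_dt = 0.25) {
  if (beats_per_cl < 2) stop("beats_per_cl must be >= 2")
  st <- resting_state(model)
  pts <- NULL
  lost <- numeric(0)
  alt <- 0
  for (cl in cl_sweep) {
    tr <- simulate_cell(model, pacing_schedule(cl, beats_per_cl),
                        duration = cl * beats_per_cl, init = st,
                        dt = dt, record_dt = record_dt)
    st <- tr$final_state
    n <- beats_per_cl
    stim_last2 <- tr$stim_times[c(n - 1, n)]
    ok <- all(vapply(stim_last2, function(s) capture_ok(tr, s), logical(1)))
    a <- apd(tr)
    a2 <- a[a$beat %in% c(n - 1, n), ]
    if (!ok || nrow(a2) < 2 || any(!a2$repolarised)) {
      lost <- c(lost, cl)
      next
    }
    alt <- max(alt, abs(diff(a2$apd)))
    di <- cl - a2$apd[1]
    pts <- rbind(pts, data.frame(cl = cl, di = di, apd90 = a2$apd[2]))
  }
  if (is.null(pts)) stop("no cycle length maintained 1:1 capture")
  out <- new_restitution_curve(pts, "dynamic", alternans = alt)
  attr(out, "lost_capture") <- lost
  out
}

#' Maximal restitution slope on either side of a diastolic-interval split
#'
#' Maximal finite-difference slope of APD90 vs DI between adjacent curve
#' points, computed separately for pair midpoints above and below `di_split`.
#' A side with fewer than two points yields `NA`.
#'
#' @param curve A `restitution_curve`.
#' @param di_split Split value (ms).
#' @return Named numeric `c(above = , below = )`.
#' @export
max_restitution_slope <- function(curve, di_split = 280) {
  stopifnot(inherits(curve, "restitution_curve"))
  df <- curve$points[order(curve$points$di), ]
  if (anyDuplicated(df$di)) stop("duplicate diastolic intervals in curve")
  if (nrow(df) < 2) return(c(above = NA_real_, below = NA_real_))
  sl <- diff(df$apd90) / diff(df$di)
  mid <- (df$di[-1] + df$di[-nrow(df)]) / 2
  pick <- function(s) if (length(s)) max(s) else NA_real_
  c(above = pick(sl[mid > di_split]), below = pick(sl[mid < di_split]))
}

# ---- population of models -----------------------------------------------------

#' Population specification for Latin hypercube sampling
#'
#' Named multiplicative scale ranges over model parameters; defaults span the
#' current conductances and inactivation time constants of the fast and late
#' sodium, slow inward calcium and delayed rectifier currents.
#'
#' @param size Number of members.
#' @param ranges Named list of `c(lo, hi)` scale ranges.
#' @param seed Integer seed making the sample reproducible.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(size = 1000,
                            ranges = list(
                              g_Na = c(0.5, 2), g_NaL = c(0.5, 2),
                              g_si = c(0.5, 2), g_K = c(0.5, 2),
                              tau_h_scale = c(0.5, 2), tau_j_scale = c(0.5, 2),
                              tau_hL_scale = c(0.5, 2), tau_f_scale = c(0.5, 2)
                            ),
                            seed = 1L) {
  if (size < 1) stop("size must be >= 1")
  ok <- vapply(ranges, function(r) length(r) == 2 && r[1] < r[2], logical(1))
  if (!all(ok)) stop("every range must satisfy lo < hi")
  if (!all(names(ranges) %in% vfib_par_names))
    stop("unknown parameter in ranges: ",
         paste(setdiff(names(ranges), vfib_par_names), collapse = ", "))
  structure(list(size = as.integer(size), ranges = ranges, seed = as.integer(seed)),
            class = "population_spec")
}

#' Latin hypercube population of model variants
#'
#' Draws `spec$size` members by Latin hypercube sampling: for every factor the
#' samples occupy each of the `size` equal-probability strata of its range
#' exactly once. Members are multiplicative scalings of the base model.
#'
#' @param spec A [population_spec()].
#' @param base An `ionic_model` the scales are applied to.
#' @return An object of class `model_population` with a `members` data frame
#'   (one row per member, one column per factor).
#' @export
lhs_population <- function(spec, base = make_cell_model()) {
  stopifnot(inherits(spec, "population_spec"), inherits(base, "ionic_model"))
  k <- length(spec$ranges)
  u <- withr_seed(spec$seed, lhs::randomLHS(spec$size, k))
  mem <- as.data.frame(u)
  names(mem) <- names(spec$ranges)
  for (nm in names(spec$ranges)) {
    r <- spec$ranges[[nm]]
    mem[[nm]] <- r[1] + mem[[nm]] * (r[2] - r[1])
  }
  structure(list(members = mem, spec = spec, base = base),
            class = "model_population")
}

# evaluate an expression under a temporary RNG seed without disturbing the
# caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @export
print.model_population <- function(x, ...) {
  cat("<model_population>", nrow(x$members), "members x",
      ncol(x$members), "factors\n")
  invisible(x)
}

#' Materialise one population member as a cell model
#'
#' @param population A `model_population`.
#' @param i Member index.
#' @return An `ionic_model` with the member's factor scales applied.
#' @export
population_model <- function(population, i) {
  stopifnot(inherits(population, "model_population"))
  m <- population$base
  row <- population$members[i, , drop = FALSE]
  for (nm in names(row)) m$parameters[nm] <- m$parameters[nm] * row[[nm]]
  m
}

#' Default biomarker evaluators for population calibration
#'
#' Each evaluator paces the model to quasi-steady state at 2 Hz and extracts
#' one biomarker. Used by [calibrate_population()]; the evaluator names must
#' cover the names of the calibration ranges.
#'
#' @param n_beats Beats of 2 Hz pacing before measurement.
#' @param cl Cycle length (ms).
#' @param dt Integration step (ms).
#' @return Named list of functions `model -> numeric`.
#' @export
default_biomarker_evaluators <- function(n_beats = 8, cl = 500, dt = 0.02) {
  pace <- function(model) {
    rs <- resting_state(model, duration = 2000)
    simulate_cell(model, pacing_schedule(cl, n_beats), duration = cl * n_beats,
                  init = rs, dt = dt, record_dt = 0.25)
  }
  list(
    apd90 = function(model) {
      a <- apd(pace(model))
      a$apd[nrow(a)]
    },
    apd50 = function(model) {
      a <- apd(pace(model), repolarisation_percent = 50)
      a$apd[nrow(a)]
    },
    peak_vm = function(model) {
      tr <- pace(model)
      a <- apd(tr)
      a$peak[nrow(a)]
    },
    rest_vm = function(model) {
      tr <- pace(model)
      a <- apd(tr)
      a$baseline[nrow(a)]
    },
    cat_amplitude = function(model) { # uM
      tr <- pace(model)
      last <- tr$stim_times[length(tr$stim_times)]
      sel <- tr$time >= last
      diff(range(tr$Cai[sel]))
    }
  )
}

#' Two-stage population calibration
#'
#' Stage 1 keeps members whose healthy biomarkers all fall inside
#' `healthy_ranges`; stage 2 keeps, of those, members whose biomarkers under
#' the ischaemic configuration fall inside `ischaemia_ranges`. Per-member,
#' per-stage flags are always returned.
#'
#' @param population A `model_population`.
#' @param healthy_ranges,ischaemia_ranges Named lists of `c(lo, hi)`.
#' @param evaluators Named list of biomarker functions; must define one per
#'   range name (configuration error otherwise).
#' @param ischaemia The ischaemic configuration used in stage 2.
#' @return `data.frame` with biomarker columns and logical `stage1`, `stage2`.
#' @export
calibrate_population <- function(population, healthy_ranges, ischaemia_ranges,
                                 evaluators = default_biomarker_evaluators(),
                                 ischaemia = ischaemia_config("moderate")) {
  stopifnot(inherits(population, "model_population"))
  need <- union(names(healthy_ranges), names(ischaemia_ranges))
  missing_ev <- setdiff(need, names(evaluators))
  if (length(missing_ev))
    stop("missing biomarker evaluator for: ", paste(missing_ev, collapse = ", "))
  n <- nrow(population$members)
  res <- data.frame(member = seq_len(n))
  in_range <- function(v, r) !is.na(v) & v >= r[1] & v <= r[2]

  stage1 <- rep(TRUE, n)
  for (nm in names(healthy_ranges)) {
    v <- vapply(seq_len(n), function(i) {
      m <- population_model(population, i)
      tryCatch(evaluators[[nm]](m), error = function(e) NA_real_)
    }, numeric(1))
    res[[paste0("healthy_", nm)]] <- v
    stage1 <- stage1 & in_range(v, healthy_ranges[[nm]])
  }
  res$stage1 <- stage1
  stage2 <- stage1
  for (nm in names(ischaemia_ranges)) {
    v <- rep(NA_real_, n)
    idx <- which(stage1)
    v[idx] <- vapply(idx, function(i) {
      m <- apply_ischaemia(population_model(population, i), ischaemia)
      tryCatch(evaluators[[nm]](m), error = function(e) NA_real_)
    }, numeric(1))
    res[[paste0("ischaemic_", nm)]] <- v
    stage2 <- stage2 & in_range(v, ischaemia_ranges[[nm]])
  }
  res$stage2 <- stage2
  res
}

#' Rank population members by restitution steepness and pick a VF candidate
#'
#' Ranks members by maximal S1S2 restitution slope and returns the top `k`.
#' The final pick is the member with the greatest alternans amplitude among
#' the `k`, excluding members flagged with repolarisation abnormalities.
#'
#' @param slopes Numeric vector: maximal restitution slope per member.
#' @param k Number of members to retain.
#' @param alternans Numeric vector: alternans amplitude per member.
#' @param abnormal Logical vector: repolarisation-abnormality flag per member.
#' @return List with `ranked` (indices of the top `k`, steepest first) and
#'   `pick` (single index or `NA` if all candidates are abnormal).
#' @export
select_vf_candidates <- function(slopes, k, alternans = NULL, abnormal = NULL) {
  n <- length(slopes)
  if (k > n) {
    warning("k exceeds population size; returning all members")
    k <- n
  }
  ord <- order(slopes, decreasing = TRUE)
  ranked <- ord[seq_len(k)]
  pick <- NA_integer_
  if (!is.null(alternans)) {
    cand <- ranked
    if (!is.null(abnormal)) cand <- cand[!abnormal[cand]]
    if (length(cand)) pick <- cand[which.max(alternans[cand])]
  }
  list(ranked = ranked, pick = pick)
}

#' Detect repolarisation abnormalities in a paced trace
#'
#' Flags a beat when a secondary depolarising deflection occurs during
#' repolarisation, or when the beat fails to repolarise below the
#' repolarisation fraction before the next stimulus. A secondary deflection
#' is a rise of more than `rise_mv` following a local voltage minimum inside
#' the repolarisation window; the first `search_start_fraction` of each beat
#' is excluded because the normal phase-1 notch/dome morphology contains a
#' physiological secondary rise.
#'
#' @param trace An `ap_trace`.
#' @param rise_mv mV; minimum prominence of a secondary deflection.
#' @param repol_fraction Fraction of repolarisation that must be reached.
#' @param search_start_fraction Fraction of the APD after which the
#'   secondary-upstroke search begins.
#' @return List with `abnormal` (logical) and `locations` (times in ms).
#' @export
detect_repolarisation_abnormality <- function(trace, rise_mv = 2,
                                              repol_fraction = 0.9,
                                              search_start_fraction = 0.25) {
  stopifnot(inherits(trace, "ap_trace"))
  a <- apd(trace, repolarisation_percent = repol_fraction * 100)
  st <- trace$stim_times
  ends <- c(st[-1], max(trace$time) + trace$record_dt)
  locs <- numeric(0)
  for (k in seq_len(nrow(a))) {
    if (!a$repolarised[k]) {
      locs <- c(locs, a$t_stim[k])
      next
    }
    t_end <- a$t_act[k] + a$apd[k]
    sel <- trace$time > a$t_act[k] + search_start_fraction * a$apd[k] &
      trace$time < min(t_end, ends[k])
    tt <- trace$time[sel]
    vv <- trace$Vm[sel]
    if (length(tt) < 4) next
    dv <- diff(vv)
    # local minima strictly inside the window (the dome still rising at the
    # window edge has no preceding negative slope and cannot trigger)
    lmin <- which(dv[-1] > 0 & dv[-length(dv)] <= 0) + 1
    for (i0 in lmin) {
      rise <- vv[i0:length(vv)] - vv[i0]
      j <- which(rise > rise_mv)
      if (length(j)) {
        locs <- c(locs, tt[i0 + j[1] - 1])
        break
      }
    }
  }
  list(abnormal = length(locs) > 0, locations = locs)
}
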