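# Windowed marker/PS tables, VT/VF outcome classification, severity-stratified
# range summaries with onset exclusion, and clinical threshold flags.

#' Severity labels and onset flags for analysis windows
#'
#' The severity label of a window is the remote-myocardium severity at the
#' window midpoint; the onset flag marks the first window whose start follows
#' the final induction stimulus.
#'
#' @param windows List/matrix of `c(start, end)` times (ms).
#' @param protocol A [severity_protocol()].
#' @param last_stimulus_ms Time of the final induction stimulus.
#' @return `data.frame` with `window`, `severity`, `onset`.
#' @export
window_labels <- function(windows, protocol, last_stimulus_ms) {
  if (is.matrix(windows)) windows <- split(windows, row(windows)[, 1])
  mids <- vapply(windows, function(w) mean(w[1:2]), numeric(1))
  starts <- vapply(windows, function(w) w[1], numeric(1))
  sev <- vapply(mids, function(m) {
    ph <- findInterval(m, protocol$times)
    protocol$phases[max(1, ph)]
  }, character(1))
  onset <- rep(FALSE, length(windows))
  post <- which(starts >= last_stimulus_ms)
  if (length(post)) onset[post[1]] <- TRUE
  data.frame(window = seq_along(windows), severity = sev, onset = onset)
}

#' Assemble the per-window marker table
#'
#' One row per (lead, window) with AMSA, median slope, dominant frequency, the
#' phase-singularity count at the window midpoint (lead-independent), the
#' severity label and the onset flag.
#'
#' @param leads Named list of `ecg_trace` objects.
#' @param ps A `ps_series` from [ps_timeseries()] (or `NULL`).
#' @param windows List/matrix of `c(start, end)` times (ms).
#' @param labels `data.frame` from [window_labels()] (or `NULL` for unlabelled
#'   rows).
#' @param band AMSA/DF analysis band (Hz).
#' @return `data.frame`: `lead`, `window`, `amsa`, `median_slope`,
#'   `dominant_frequency`, `ps`, `severity`, `onset`.
#' @export
window_markers <- function(leads, ps = NULL, windows, labels = NULL,
                           band = c(2, 48)) {
  if (is.matrix(windows)) windows <- split(windows, row(windows)[, 1])
  nw <- length(windows)
  if (!is.null(ps) && nrow(ps$counts) != nw)
    stop("window count mismatch between markers and PS series")
  if (!is.null(labels) && nrow(labels) != nw)
    stop("window count mismatch between markers and labels")
  if (!length(leads))
    return(data.frame(lead = character(0), window = integer(0),
                      amsa = numeric(0), median_slope = numeric(0),
                      dominant_frequency = numeric(0), ps = integer(0),
                      severity = character(0), onset = logical(0)))
  rows <- list()
  for (nm in names(leads)) {
    sw <- preprocess(leads[[nm]], windows)
    for (i in seq_len(nw)) {
      rows[[length(rows) + 1]] <- data.frame(
        lead = nm, window = i,
        amsa = amsa(sw[[i]], band),
        median_slope = median_slope(sw[[i]]),
        dominant_frequency = dominant_frequency(sw[[i]], band),
        ps = if (is.null(ps)) NA_integer_ else ps$counts$n[i],
        severity = if (is.null(labels)) NA_character_ else labels$severity[i],
        onset = if (is.null(labels)) NA else labels$onset[i])
    }
  }
  do.call(rbind, rows)
}

#' Classify the arrhythmic outcome after induction
#'
#' Electrical activity is judged after the last stimulated beat has had time
#' to repolarise (`grace_ms` after the final stimulus). With a movie, activity
#' means any cell above `vm_threshold`; with an ECG trace, absolute amplitude
#' above `amp_fraction` of the post-pacing peak. `none`: no activity beyond
#' the grace period; `transient`: activity ends before the record does;
#' `persistent`: activity continues to the end.
#'
#' @param x A `sim_movie` or `ecg_trace`.
#' @param last_stimulus_ms Time of the final induction stimulus (ms).
#' @param vm_threshold mV (movie mode).
#' @param amp_fraction Fraction of the post-pacing peak (ECG mode).
#' @param grace_ms Repolarisation allowance after the last stimulus.
#' @return Object of class `vf_outcome`: list with `outcome` and
#'   `termination_ms` (`NA` unless transient).
#' @export
classify_vf_outcome <- function(x, last_stimulus_ms, vm_threshold = -40,
                                amp_fraction = 0.1, grace_ms = 600) {
  if (inherits(x, "sim_movie")) {
    times <- x$frame_times
    if (max(times) <= last_stimulus_ms)
      stop("record ends during pacing")
    active <- apply(x$frames, 2, function(v) any(v > vm_threshold))
  } else if (inherits(x, "ecg_trace")) {
    times <- (seq_along(x$samples) - 1) / x$fs * 1000
    if (max(times) <= last_stimulus_ms)
      stop("record ends during pacing")
    post <- abs(x$samples[times > last_stimulus_ms])
    pk <- max(post)
    active <- abs(x$samples) > amp_fraction * pk
  } else stop("x must be a sim_movie or ecg_trace")
  cut <- last_stimulus_ms + grace_ms
  act_times <- times[active]
  act_times <- act_times[act_times > cut]
  end <- max(times)
  dt_rec <- if (length(times) > 1) diff(times[1:2]) else 0
  if (!length(act_times)) {
    out <- list(outcome = "none", termination_ms = NA_real_)
  } else if (max(act_times) >= end - 2 * dt_rec) {
    out <- list(outcome = "persistent", termination_ms = NA_real_)
  } else {
    out <- list(outcome = "transient", termination_ms = max(act_times))
  }
  structure(out, class = "vf_outcome")
}

#' @export
print.vf_outcome <- function(x, ...) {
  cat("<vf_outcome>", x$outcome)
  if (!is.na(x$termination_ms)) cat(sprintf(" (terminated %.0f ms)", x$termination_ms))
  cat("\n")
  invisible(x)
}

#' Severity-stratified marker ranges
#'
#' Per severity label, the `[min, max]` range of each marker and of the PS
#' count over the included windows; onset-flagged rows are excluded when
#' `exclude_onset` is `TRUE`. Severity groups with no included rows are
#' absent from the output.
#'
#' @param table Marker table from [window_markers()].
#' @param exclude_onset Drop onset rows before computing ranges.
#' @return Object of class `stratified_summary`: `data.frame` with one row per
#'   (severity, marker): `severity`, `marker`, `lo`, `hi`, `n`; the excluded
#'   windows are recorded in the `excluded` attribute.
#' @export
stratify_by_severity <- function(table, exclude_onset = TRUE) {
  if (!all(c("severity", "onset") %in% names(table)))
    stop("table rows must be labelled")
  excluded <- table[exclude_onset & table$onset, , drop = FALSE]
  inc <- table[!(exclude_onset & table$onset), , drop = FALSE]
  markers <- intersect(c("amsa", "median_slope", "dominant_frequency", "ps"),
                       names(inc))
  rows <- list()
  for (sev in unique(inc$severity)) {
    sub <- inc[inc$severity == sev, , drop = FALSE]
    for (mk in markers) {
      v <- sub[[mk]]
      v <- v[!is.na(v)]
      if (!length(v)) next
      rows[[length(rows) + 1]] <- data.frame(
        severity = sev, marker = mk, lo = min(v), hi = max(v), n = length(v))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  class(out) <- c("stratified_summary", class(out))
  out
}

#' Clinical threshold flags for defibrillation markers
#'
#' Marks each row favourable when the marker is at or above its clinical
#' reference value (AMSA 15.5 mV Hz; median slope 2.6 mV/s).
#'
#' @param markers Marker table (needs `amsa` and `median_slope` columns) or a
#'   list with those fields.
#' @param amsa_threshold mV Hz.
#' @param ms_threshold mV/s.
#' @return `data.frame` with logical `amsa_favourable`, `ms_favourable`.
#' @export
threshold_flags <- function(markers, amsa_threshold = 15.5, ms_threshold = 2.6) {
  if (amsa_threshold <= 0 || ms_threshold <= 0) stop("thresholds must be > 0")
  data.frame(amsa_favourable = markers$amsa >= amsa_threshold,
             ms_favourable = markers$median_slope >= ms_threshold)
}

#' Write / read a marker table as delimited text
#' @param table Marker table.
#' @param path File path.
#' @export
write_marker_table <- function(table, path) {
  write.table(table, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
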