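# VF waveform quantification: resampling, windowing, AMSA, dominant
# frequency, median slope, amplitude normalisation, spectrogram.

#' ECG trace container
#'
#' @param samples Numeric samples (mV).
#' @param fs Sampling rate (Hz).
#' @param lead_name Lead label.
#' @return Object of class `ecg_trace`.
#' @export
ecg_trace <- function(samples, fs, lead_name = "lead") {
  if (fs <= 0) stop("sampling rate must be > 0")
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), fs = fs, lead = lead_name),
            class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> %s: %d samples @ %g Hz (%.2f s)\n",
              x$lead, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
plot.ecg_trace <- function(x, ...) {
  t <- seq_along(x$samples) / x$fs
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = sprintf("%s (mV)", x$lead), ...)
  invisible(x)
}

#' Tukey (tapered-cosine) window
#' @param n Window length.
#' @param alpha Taper fraction.
#' @return Numeric vector of weights.
#' @export
tukey_window <- function(n, alpha = 0.2) {
  if (alpha <= 0) return(rep(1, n))
  if (alpha >= 1) return(0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))))
  w <- rep(1, n)
  k <- 0:(n - 1)
  edge <- alpha * (n - 1) / 2
  lo <- k < edge
  hi <- k > (n - 1) * (1 - alpha / 2)
  w[lo] <- 0.5 * (1 + cos(pi * (k[lo] / edge - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((k[hi] - (n - 1) * (1 - alpha / 2)) / edge)))
  w
}

#' Extract resampled, tapered analysis windows from an ECG trace
#'
#' Each requested time interval is resampled to `fs_out` (polyphase
#' anti-aliased resampling), cut to exactly `n` samples, mean-removed, and a
#' Tukey taper is attached for the spectral computations. The untapered
#' segment is kept for the median-slope marker.
#'
#' @param trace An [ecg_trace()].
#' @param windows Either a two-column matrix / list of `c(start, end)` times
#'   in ms, or `NULL` to tile the record with non-overlapping windows.
#' @param fs_out Analysis sampling rate (Hz).
#' @param n Window length in samples.
#' @param tukey_alpha Taper fraction.
#' @return List of objects of class `spectral_window` (fields: `samples`
#'   untapered mean-removed, `tapered`, `fs`, `start_ms`, `end_ms`, `id`).
#' @export
preprocess <- function(trace, windows = NULL, fs_out = 250, n = 512,
                       tukey_alpha = 0.2) {
  stopifnot(inherits(trace, "ecg_trace"))
  need_ms <- n / fs_out * 1000
  total_ms <- length(trace$samples) / trace$fs * 1000
  if (is.null(windows)) {
    starts <- seq(0, total_ms - need_ms, by = need_ms)
    if (!length(starts)) stop("record shorter than one analysis window")
    windows <- lapply(starts, function(s) c(s, s + need_ms))
  }
  if (is.matrix(windows)) windows <- split(windows, row(windows)[, 1])
  taper <- tukey_window(n, tukey_alpha)
  out <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (w[2] - w[1] < need_ms - 1e-9)
      stop(sprintf("window %d (%g-%g ms) shorter than the %d-sample analysis length (%.0f ms)",
                   i, w[1], w[2], n, need_ms))
    if (w[1] < 0 || w[2] > total_ms + 1e-9)
      stop(sprintf("window %d outside the record", i))
    i0 <- max(1, floor(w[1] / 1000 * trace$fs) + 1)
    i1 <- min(length(trace$samples), ceiling(w[2] / 1000 * trace$fs))
    seg <- trace$samples[i0:i1]
    res <- resample_signal(seg, trace$fs, fs_out)
    if (length(res) < n)
      stop(sprintf("window %d yields %d < %d samples after resampling",
                   i, length(res), n))
    res <- res[1:n]
    res <- res - mean(res)
    out[[i]] <- structure(list(samples = res, tapered = res * taper,
                               fs = fs_out, start_ms = w[1], end_ms = w[2],
                               taper_alpha = tukey_alpha, id = i),
                          class = "spectral_window")
  }
  out
}

# rational anti-aliased resampling: zero-stuff upsample by p, linear-phase
# FIR low-pass (signal::fir1) with the exact (N-1)/2 group delay removed,
# then decimate by q; reflective padding suppresses edge transients
resample_signal <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  fr <- gsub("/", " ", as.character(MASS::fractions(fs_out / fs_in)))
  pq <- as.numeric(strsplit(fr, " ")[[1]])
  if (length(pq) == 1) pq <- c(pq, 1)
  p <- pq[1]; q <- pq[2]
  ntaps <- 20 * max(p, q) + 1                    # odd: integer group delay
  h <- signal::fir1(ntaps - 1, 1 / max(p, q)) * p
  pad <- min(length(x), ceiling(ntaps / p) + 10)
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[length(x) - seq_len(pad) + 1]))
  up <- numeric(length(xp) * p)
  up[seq(1, length(up), by = p)] <- xp
  yf <- stats::filter(c(up, numeric(ntaps)), h, method = "convolution",
                      sides = 1)
  delay <- (ntaps - 1) / 2
  yf <- yf[(delay + 1):(delay + length(up))]     # remove FIR group delay
  n_out <- floor(length(x) * p / q)
  idx0 <- pad * p                                 # samples from the left pad
  yf[idx0 + seq(1, by = q, length.out = n_out)]
}

#' One-sided amplitude spectrum of an analysis window
#'
#' Normalised so that a full-scale in-band sinusoid of amplitude A mV gives a
#' peak bin of amplitude A (two-sided to one-sided factor 2/N applied).
#'
#' @param window A `spectral_window`.
#' @return `data.frame` with `frequency` (Hz) and `amplitude` (mV).
#' @export
amplitude_spectrum <- function(window) {
  stopifnot(inherits(window, "spectral_window"))
  n <- length(window$tapered)
  X <- fft(window$tapered)
  half <- seq_len(floor(n / 2))
  data.frame(frequency = (half - 1) * window$fs / n,
             amplitude = 2 * Mod(X[half]) / n)
}

#' Amplitude spectrum area (AMSA)
#'
#' Sum over in-band spectral bins of amplitude times frequency (mV Hz).
#'
#' @param window A `spectral_window`.
#' @param band Frequency band `c(lo, hi)` in Hz.
#' @return AMSA in mV Hz.
#' @export
amsa <- function(window, band = c(2, 48)) {
  sp <- amplitude_spectrum(window)
  if (band[1] >= band[2]) stop("empty analysis band")
  if (band[2] > window$fs / 2) stop("band exceeds the Nyquist frequency")
  sel <- sp$frequency >= band[1] & sp$frequency <= band[2]
  if (!any(sel)) stop("no spectral bins inside the band")
  sum(sp$amplitude[sel] * sp$frequency[sel])
}

#' Dominant frequency
#'
#' Frequency of the maximal in-band amplitude bin.
#' @inheritParams amsa
#' @return Hz.
#' @export
dominant_frequency <- function(window, band = c(2, 48)) {
  sp <- amplitude_spectrum(window)
  if (band[1] >= band[2]) stop("empty analysis band")
  sel <- sp$frequency >= band[1] & sp$frequency <= band[2]
  if (!any(sel)) stop("no spectral bins inside the band")
  spb <- sp[sel, ]
  spb$frequency[which.max(spb$amplitude)]
}

#' Median slope (MS)
#'
#' Median absolute first difference of the resampled, untapered window,
#' scaled by the sampling rate (mV/s).
#' @param window A `spectral_window`.
#' @return mV/s.
#' @export
median_slope <- function(window) {
  stopifnot(inherits(window, "spectral_window"))
  x <- window$samples
  if (length(x) < 2) stop("window too short")
  median(abs(diff(x))) * window$fs
}

#' Normalise an ECG trace to a target peak amplitude
#'
#' Scales the signal so its peak absolute amplitude over the given segment
#' equals `target_peak`; the applied gain is returned.
#'
#' @param trace An `ecg_trace`.
#' @param target_peak mV.
#' @param segment_ms Optional `c(start, end)` (ms) over which the peak is
#'   taken (e.g. the fibrillation segment); default whole record.
#' @return List with `trace` (scaled) and `gain`.
#' @export
normalise_amplitude <- function(trace, target_peak = 1, segment_ms = NULL) {
  stopifnot(inherits(trace, "ecg_trace"))
  x <- trace$samples
  if (!is.null(segment_ms)) {
    i0 <- max(1, floor(segment_ms[1] / 1000 * trace$fs) + 1)
    i1 <- min(length(x), ceiling(segment_ms[2] / 1000 * trace$fs))
    seg <- x[i0:i1]
  } else seg <- x
  pk <- max(abs(seg))
  if (pk == 0) stop("zero signal cannot be normalised")
  gain <- target_peak / pk
  list(trace = ecg_trace(x * gain, trace$fs, trace$lead), gain = gain)
}

#' Short-time amplitude spectrogram
#'
#' Successive windows with the same taper and normalisation as [amsa()].
#'
#' @param trace An `ecg_trace`.
#' @param n Window length (samples at `fs_out`).
#' @param stride_ms Hop between window starts (ms); default non-overlapping.
#' @param fs_out Analysis rate (Hz).
#' @param tukey_alpha Taper fraction.
#' @return List with `times` (window centres, ms), `frequency` (Hz) and
#'   `amplitude` (frequency x time matrix, mV), plus the windows used.
#' @export
spectrogram <- function(trace, n = 512, stride_ms = NULL, fs_out = 250,
                        tukey_alpha = 0.2) {
  win_ms <- n / fs_out * 1000
  stride_ms <- stride_ms %||% win_ms
  total_ms <- length(trace$samples) / trace$fs * 1000
  if (total_ms < win_ms) stop("record shorter than one window")
  starts <- seq(0, total_ms - win_ms, by = stride_ms)
  wins <- lapply(starts, function(s) c(s, s + win_ms))
  sw <- preprocess(trace, wins, fs_out = fs_out, n = n,
                   tukey_alpha = tukey_alpha)
  sps <- lapply(sw, amplitude_spectrum)
  list(times = starts + win_ms / 2,
       frequency = sps[[1]]$frequency,
       amplitude = vapply(sps, function(s) s$amplitude,
                          numeric(nrow(sps[[1]]))),
       windows = sw)
}

#' Read an ECG trace from columnar text
#'
#' Expects a header line and columns `time_ms` followed by one column per
#' lead (mV); the sampling rate is inferred from the time column.
#' @param path File path.
#' @param lead Lead column to read (name or index after time).
#' @return An `ecg_trace`.
#' @export
read_ecg_trace <- function(path, lead = 1) {
  d <- read.table(path, header = TRUE)
  dtms <- diff(d[[1]][1:2])
  col <- if (is.character(lead)) lead else colnames(d)[lead + 1]
  ecg_trace(d[[col]], fs = 1000 / dtms, lead_name = col)
}

#' Write ECG traces as columnar text
#' @param traces Named list of `ecg_trace` (equal length and rate).
#' @param path File path.
#' @export
write_ecg_traces <- function(traces, path) {
  fs <- traces[[1]]$fs
  n <- length(traces[[1]]$samples)
  d <- data.frame(time_ms = (seq_len(n) - 1) / fs * 1000)
  for (nm in names(traces)) d[[make.names(nm)]] <- traces[[nm]]$samples
  write.table(d, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
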