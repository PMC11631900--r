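# Phase-singularity detection: dual-isoline intersection criterion with an
# independent phase-winding oracle.

contour_segments <- function(field, level) {
  nx <- nrow(field)
  ny <- ncol(field)
  cl <- grDevices::contourLines(x = seq_len(nx), y = seq_len(ny),
                                z = field, levels = level)
  if (!length(cl)) return(NULL)
  segs <- lapply(cl, function(p) {
    n <- length(p$x)
    if (n < 2) return(NULL)
    cbind(x0 = p$x[-n], y0 = p$y[-n], x1 = p$x[-1], y1 = p$y[-1])
  })
  do.call(rbind, segs)
}

# intersections of one segment with a set of segments (2x2 linear solve)
seg_intersections <- function(s, B) {
  dx1 <- s[3] - s[1]; dy1 <- s[4] - s[2]
  dx2 <- B[, 3] - B[, 1]; dy2 <- B[, 4] - B[, 2]
  den <- dx1 * dy2 - dy1 * dx2
  ok <- abs(den) > 1e-12
  if (!any(ok)) return(NULL)
  rx <- B[ok, 1] - s[1]; ry <- B[ok, 2] - s[2]
  t <- (rx * dy2[ok] - ry * dx2[ok]) / den[ok]
  u <- (rx * dy1 - ry * dx1) / den[ok]
  hit <- t >= 0 & t <= 1 & u >= 0 & u <= 1
  if (!any(hit)) return(NULL)
  cbind(x = s[1] + t[hit] * dx1, y = s[2] + t[hit] * dy1)
}

grad_at <- function(field, x, y) {
  nx <- nrow(field)
  ny <- ncol(field)
  i <- min(max(round(x), 2), nx - 1)
  j <- min(max(round(y), 2), ny - 1)
  c(gx = (field[i + 1, j] - field[i - 1, j]) / 2,
    gy = (field[i, j + 1] - field[i, j - 1]) / 2)
}

#' Detect phase singularities from two isolines
#'
#' A phase singularity is marked at every intersection of the membrane
#' potential isoline (`vm_iso`) with the rate-of-change isoline (`dvdt_iso`);
#' these are the points where activation and recovery fronts meet. Chirality
#' is the rotation sense of the local activation pattern, computed as the sign
#' of the Jacobian determinant of the two fields; note this determinant is
#' degenerate when potential and rate are functions of one underlying scalar
#' (as in idealised rotating phase fields), in which case use
#' [phase_winding_ps()] for chirality. Intersections closer than
#' `merge_dist` grid cells are merged.
#'
#' @param vm_frame Membrane potential matrix (mV).
#' @param dvdt_frame Time derivative matrix (mV/ms), central-differenced.
#' @param vm_iso Potential isovalue (mV).
#' @param dvdt_iso Rate isovalue (mV/ms).
#' @param merge_dist Merge radius (grid cells).
#' @return `data.frame` with `x`, `y` (grid coordinates) and `chirality`
#'   (+1/-1); zero rows if none found or the fields are degenerate.
#' @export
detect_ps <- function(vm_frame, dvdt_frame, vm_iso = -40, dvdt_iso = -2,
                      merge_dist = 2) {
  stopifnot(all(dim(vm_frame) == dim(dvdt_frame)))
  empty <- data.frame(x = numeric(0), y = numeric(0), chirality = numeric(0))
  if (diff(range(vm_frame)) < 1e-9 || diff(range(dvdt_frame)) < 1e-9)
    return(empty)
  if (vm_iso <= min(vm_frame) || vm_iso >= max(vm_frame)) return(empty)
  if (dvdt_iso <= min(dvdt_frame) || dvdt_iso >= max(dvdt_frame)) return(empty)
  A <- contour_segments(vm_frame, vm_iso)
  B <- contour_segments(dvdt_frame, dvdt_iso)
  if (is.null(A) || is.null(B)) return(empty)
  pts <- NULL
  # bounding-box prefilter on the dvdt segments
  bx0 <- pmin(B[, 1], B[, 3]); bx1 <- pmax(B[, 1], B[, 3])
  by0 <- pmin(B[, 2], B[, 4]); by1 <- pmax(B[, 2], B[, 4])
  for (k in seq_len(nrow(A))) {
    s <- A[k, ]
    cand <- bx1 >= min(s[1], s[3]) & bx0 <= max(s[1], s[3]) &
            by1 >= min(s[2], s[4]) & by0 <= max(s[2], s[4])
    if (!any(cand)) next
    hit <- seg_intersections(s, B[cand, , drop = FALSE])
    if (!is.null(hit)) pts <- rbind(pts, hit)
  }
  if (is.null(pts)) return(empty)
  # merge nearby intersections (contour pixelation duplicates crossings)
  keep <- rep(TRUE, nrow(pts))
  for (k in seq_len(nrow(pts))) {
    if (!keep[k]) next
    d2 <- (pts[, 1] - pts[k, 1])^2 + (pts[, 2] - pts[k, 2])^2
    dup <- which(d2 < merge_dist^2)
    keep[setdiff(dup, k)] <- FALSE
  }
  pts <- pts[keep, , drop = FALSE]
  chir <- vapply(seq_len(nrow(pts)), function(k) {
    g1 <- grad_at(vm_frame, pts[k, 1], pts[k, 2])
    g2 <- grad_at(dvdt_frame, pts[k, 1], pts[k, 2])
    s <- g1[1] * g2[2] - g1[2] * g2[1]
    if (s >= 0) 1 else -1
  }, numeric(1))
  data.frame(x = pts[, 1], y = pts[, 2], chirality = chir)
}

#' Phase-winding singularity detector (oracle)
#'
#' Marks every grid plaquette whose summed, wrapped phase difference around
#' the four edges equals +-2 pi; the winding sign is the chirality. This is
#' the independent cross-check for [detect_ps()].
#'
#' @param phase_frame Matrix of phases in (-pi, pi].
#' @return `data.frame` with `x`, `y` (plaquette centres) and `chirality`.
#' @export
phase_winding_ps <- function(phase_frame) {
  nx <- nrow(phase_frame)
  ny <- ncol(phase_frame)
  wrap <- function(a) atan2(sin(a), cos(a))
  p00 <- phase_frame[-nx, -ny]
  p10 <- phase_frame[-1, -ny]
  p11 <- phase_frame[-1, -1]
  p01 <- phase_frame[-nx, -1]
  w <- wrap(p10 - p00) + wrap(p11 - p10) + wrap(p01 - p11) + wrap(p00 - p01)
  idx <- which(abs(w) > pi) # winding is 0 or +-2pi up to rounding
  data.frame(x = row(w)[idx] + 0.5, y = col(w)[idx] + 0.5,
             chirality = sign(w[idx]))
}

#' Per-pixel activation phase from the analytic signal
#'
#' Phase of the Hilbert analytic signal of each pixel's mean-subtracted
#' membrane-potential time course; used only to feed the phase-winding oracle.
#'
#' @param movie A `sim_movie`.
#' @return Matrix (cells x frames) of phases in (-pi, pi].
#' @export
analytic_phase <- function(movie) {
  X <- movie$frames
  n <- ncol(X)
  if (n < 4) stop("movie too short for an analytic signal")
  X <- X - rowMeans(X)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  ph <- t(apply(X, 1, function(x) {
    z <- fft(fft(x) * h, inverse = TRUE) / n
    Arg(z)
  }))
  ph
}

#' Phase-singularity counts at analysis-window midpoints
#'
#' Runs [detect_ps()] on the movie frame nearest the midpoint of each time
#' window, with the rate frame computed by central time differences.
#'
#' @param movie A `sim_movie`.
#' @param windows List/matrix of `c(start, end)` times (ms).
#' @param vm_iso,dvdt_iso Isovalues (mV, mV/ms).
#' @return Object of class `ps_series`: `data.frame` `counts` (one row per
#'   window: `time`, `n`, `missing`) and list `points` of per-window records.
#' @export
ps_timeseries <- function(movie, windows, vm_iso = -40, dvdt_iso = -2) {
  stopifnot(inherits(movie, "sim_movie"))
  if (is.matrix(windows)) windows <- split(windows, row(windows)[, 1])
  ft <- movie$frame_times
  dtf <- if (length(ft) > 1) diff(ft[1:2]) else NA
  counts <- data.frame(window = seq_along(windows), time = NA_real_,
                       n = NA_integer_, missing = FALSE)
  points <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    mid <- mean(windows[[i]][1:2])
    if (mid < min(ft) || mid > max(ft)) {
      counts$missing[i] <- TRUE
      next
    }
    k <- which.min(abs(ft - mid))
    k <- min(max(k, 2), length(ft) - 1)
    vm <- movie_frame(movie, k)
    dvdt <- (movie_frame(movie, k + 1) - movie_frame(movie, k - 1)) / (2 * dtf)
    ps <- detect_ps(vm, dvdt, vm_iso, dvdt_iso)
    counts$time[i] <- ft[k]
    counts$n[i] <- nrow(ps)
    if (nrow(ps)) ps$time <- ft[k]
    points[[i]] <- ps
  }
  structure(list(counts = counts, points = points), class = "ps_series")
}

#' @export
print.ps_series <- function(x, ...) {
  cat("<ps_series>", nrow(x$counts), "windows; counts:",
      paste(x$counts$n, collapse = " "), "\n")
  invisible(x)
}

#' Export phase-singularity records as a table
#'
#' @param series A `ps_series`.
#' @param dx_mm Grid spacing to convert positions to mm.
#' @return `data.frame` with `time_ms`, `x_mm`, `y_mm`, `chirality`.
#' @export
ps_records <- function(series, dx_mm = 1) {
  rec <- do.call(rbind, series$points[!vapply(series$points, is.null, TRUE)])
  if (is.null(rec) || !nrow(rec))
    return(data.frame(time_ms = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0), chirality = numeric(0)))
  data.frame(time_ms = rec$time, x_mm = rec$x * dx_mm, y_mm = rec$y * dx_mm,
             chirality = rec$chirality)
}
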