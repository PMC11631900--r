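test_that("window labels take the severity at the midpoint and flag onset", {
  prot <- severity_protocol("III", switch_time = 5000)
  ws <- list(c(0, 2000), c(3500, 5500), c(5500, 7500), c(7500, 9500))
  lab <- window_labels(ws, prot, last_stimulus_ms = 3000)
  expect_equal(lab$severity, c("mild", "mild", "moderate", "moderate"))
  # first window starting at or after the last stimulus is the onset window
  expect_equal(lab$onset, c(FALSE, TRUE, FALSE, FALSE))
  lab2 <- window_labels(ws, severity_protocol("I"), last_stimulus_ms = 20000)
  expect_true(all(lab2$severity == "healthy"))
  expect_false(any(lab2$onset))
})

test_that("the marker table has one row per lead and window", {
  set.seed(4)
  leads <- list(a = surrogate_vf_ecg(severity_styled_spec("healthy", 1L)),
                b = surrogate_vf_ecg(severity_styled_spec("mild", 2L)))
  ws <- list(c(0, 2100), c(2100, 4200), c(4200, 6300))
  lab <- window_labels(ws, severity_protocol("II", 3000), 100)
  tab <- window_markers(leads, ps = NULL, windows = ws, labels = lab)
  expect_equal(nrow(tab), 6)
  expect_setequal(tab$lead, c("a", "b"))
  expect_true(all(is.na(tab$ps)))
  expect_true(all(tab$amsa > 0))
  expect_true(all(tab$median_slope > 0))
  expect_error(window_markers(leads, windows = ws, labels = lab[1:2, ]),
               "mismatch")
})

test_that("stratified ranges equal brute-force order statistics on random tables", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    tab <- data.frame(
      lead = "x", window = seq_len(n),
      amsa = runif(n, 0, 30), median_slope = runif(n, 0, 8),
      dominant_frequency = runif(n, 2, 10),
      ps = sample(0:20, n, replace = TRUE),
      severity = sample(c("healthy", "mild", "moderate"), n, replace = TRUE),
      onset = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.2, 0.8)))
    s <- stratify_by_severity(tab)
    inc <- tab[!tab$onset, ]
    for (r in seq_len(nrow(s))) {
      v <- inc[[s$marker[r]]][inc$severity == s$severity[r]]
      expect_equal(s$lo[r], min(v))
      expect_equal(s$hi[r], max(v))
      expect_equal(s$n[r], length(v))
    }
    expect_equal(nrow(attr(s, "excluded")), sum(tab$onset))
  }
})

test_that("onset exclusion never widens a severity range", {
  set.seed(33)
  for (rep in 1:10) {
    n <- 24
    tab <- data.frame(
      lead = "x", window = seq_len(n), amsa = runif(n, 0, 30),
      median_slope = runif(n, 0, 8), dominant_frequency = runif(n, 2, 10),
      ps = sample(0:20, n, replace = TRUE),
      severity = sample(c("mild", "moderate"), n, replace = TRUE),
      onset = sample(c(TRUE, FALSE), n, replace = TRUE))
    s_ex <- stratify_by_severity(tab, exclude_onset = TRUE)
    s_all <- stratify_by_severity(tab, exclude_onset = FALSE)
    for (r in seq_len(nrow(s_ex))) {
      ref <- s_all[s_all$severity == s_ex$severity[r] &
                     s_all$marker == s_ex$marker[r], ]
      expect_gte(s_ex$lo[r], ref$lo)
      expect_lte(s_ex$hi[r], ref$hi)
    }
  }
})

test_that("the printed severity range table is reproduced from its values", {
  # published apex-anterior AMSA ranges by remote severity (used as input)
  printed <- list(healthy = c(23.62, 24.45), mild = c(10.58, 21.47),
                  moderate = c(4.82, 11.12))
  rows <- list()
  set.seed(8)
  for (sev in names(printed)) {
    r <- printed[[sev]]
    vals <- c(r[1], r[2], runif(3, r[1], r[2]))
    rows[[sev]] <- data.frame(lead = "apex-anterior",
                              window = seq_along(vals), amsa = vals,
                              median_slope = 1, dominant_frequency = 5,
                              ps = 1L, severity = sev, onset = FALSE)
  }
  tab <- do.call(rbind, rows)
  s <- stratify_by_severity(tab)
  a <- s[s$marker == "amsa", ]
  for (sev in names(printed)) {
    expect_equal(a$lo[a$severity == sev], printed[[sev]][1])
    expect_equal(a$hi[a$severity == sev], printed[[sev]][2])
  }
  expect_error(stratify_by_severity(data.frame(amsa = 1)), "labelled")
})

test_that("outcome classification distinguishes none, transient and persistent", {
  mk_movie <- function(active_until_ms) {
    times <- seq(0, 3000, by = 10)
    frames <- vapply(times, function(t) {
      if (t <= active_until_ms) rep(c(-85, 10), 50) else rep(-85, 100)
    }, numeric(100))
    structure(list(frames = frames, frame_times = times, nx = 10, ny = 10,
                   dx_mm = 1), class = "sim_movie")
  }
  o1 <- classify_vf_outcome(mk_movie(400), last_stimulus_ms = 500)
  expect_equal(o1$outcome, "none")
  o2 <- classify_vf_outcome(mk_movie(2000), last_stimulus_ms = 500)
  expect_equal(o2$outcome, "transient")
  expect_equal(o2$termination_ms, 2000)
  o3 <- classify_vf_outcome(mk_movie(3000), last_stimulus_ms = 500)
  expect_equal(o3$outcome, "persistent")
  expect_true(is.na(o3$termination_ms))
  expect_error(classify_vf_outcome(mk_movie(100), last_stimulus_ms = 4000),
               "ends during pacing")

  # ECG mode: activity = amplitude above a fraction of the post-pacing peak
  fs <- 250
  t <- (0:(fs * 4 - 1)) / fs * 1000
  x <- ifelse(t < 2500, sin(2 * pi * 6 * t / 1000), 0.001 * sin(2 * pi * t / 1000))
  oe <- classify_vf_outcome(ecg_trace(x, fs), last_stimulus_ms = 500)
  expect_equal(oe$outcome, "transient")
})

test_that("clinical threshold flags use at-or-above comparisons", {
  tab <- data.frame(amsa = c(15.5, 15.49, 20), median_slope = c(2.6, 2.59, 1))
  fl <- threshold_flags(tab)
  expect_equal(fl$amsa_favourable, c(TRUE, FALSE, TRUE))
  expect_equal(fl$ms_favourable, c(TRUE, FALSE, FALSE))
  expect_error(threshold_flags(tab, amsa_threshold = 0), "> 0")
})

test_that("marker tables round-trip through delimited text", {
  tab <- data.frame(lead = "apex-anterior", window = 1:3,
                    amsa = c(1.5, 2.5, 3.5), median_slope = c(0.1, 0.2, 0.3),
                    dominant_frequency = c(4, 5, 6), ps = c(1L, 2L, 0L),
                    severity = c("mild", "mild", "moderate"),
                    onset = c(TRUE, FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_table(tab, path)
  back <- read_marker_table(path)
  expect_equal(back, tab)
})
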