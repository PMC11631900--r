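test_that("identity delta and healthy configuration return the baseline table", {
  m <- make_cell_model("endocardial", ischaemia_config("healthy"),
                       identity_delta())
  expect_identical(m$parameters, vfib:::vfib_base_params)
})

test_that("variant delta multiplies exactly the sodium-current entries", {
  d <- vf_variant_delta()
  m <- make_cell_model(delta = d)
  b <- vfib:::vfib_base_params
  expect_identical(m$parameters[["tau_h_scale"]], b[["tau_h_scale"]] * 0.50)
  expect_identical(m$parameters[["tau_j_scale"]], b[["tau_j_scale"]] * 0.50)
  expect_identical(m$parameters[["tau_hL_scale"]], b[["tau_hL_scale"]] * 0.66)
  expect_identical(m$parameters[["g_Na"]], b[["g_Na"]] * 1.39)
  expect_identical(m$parameters[["g_NaL"]], b[["g_NaL"]] * 1.39)
  untouched <- setdiff(names(b), c("tau_h_scale", "tau_j_scale",
                                   "tau_hL_scale", "g_Na", "g_NaL"))
  expect_identical(m$parameters[untouched], b[untouched])
})

test_that("cell-type factors scale only the repolarising currents", {
  b <- vfib:::vfib_base_params
  for (ct in cell_types()) {
    m <- make_cell_model(ct)
    fac <- vfib:::vfib_celltype_factors[[ct]]
    expect_identical(m$parameters[["g_K"]], b[["g_K"]] * fac[["g_K"]])
    expect_identical(m$parameters[["g_si"]], b[["g_si"]] * fac[["g_si"]])
  }
  expect_error(make_cell_model("septal"), "unknown cell type")
})

test_that("apply_ischaemia with a healthy configuration is a bit-identical no-op", {
  m <- make_cell_model("mid-myocardial", delta = vf_variant_delta())
  m2 <- apply_ischaemia(m, ischaemia_config("healthy"))
  expect_identical(m2$parameters, m$parameters)
})

test_that("apply_ischaemia sets potassium, KATP and acidosis scales", {
  cfg <- ischaemia_config("moderate")
  m <- apply_ischaemia(make_cell_model(), cfg)
  b <- vfib:::vfib_base_params
  expect_identical(m$parameters[["Ko"]], cfg$extracellular_potassium)
  expect_identical(m$parameters[["katp_frac"]], cfg$katp_activation)
  expect_identical(m$parameters[["g_Na"]], b[["g_Na"]] * cfg$sodium_current_scale)
  expect_identical(m$parameters[["g_si"]], b[["g_si"]] * cfg$calcium_current_scale)
  expect_error(apply_ischaemia(m, list(severity = "mild")),
               "must be an ischaemia_config")
  expect_error(ischaemia_config("mild", katp_activation = 2), "0, 1")
  expect_error(ischaemia_config("mild", extracellular_potassium = -1), "> 0")
})

test_that("pacing schedules expand cycle lengths into stimulus times", {
  s <- pacing_schedule(c(300, 200), c(2, 3), origin = 50)
  expect_identical(s$times, 50 + c(0, 300, 600, 800, 1000))
  # span = sum of all intervals incl. the trailing cycle: 2*300 + 3*200
  expect_identical(s$span, 1200)
  expect_error(pacing_schedule(c(300, 200), 2), "equal length")
  expect_error(pacing_schedule(-10, 1), "positive")
  expect_error(pacing_schedule(300, 0), ">= 1")
})

test_that("the VF-induction ramp has 21 beats over about 6 seconds", {
  s <- ramp_pacing_schedule()
  expect_length(s$times, 21)
  expect_identical(max(s$times), 5800)
  expect_identical(s$span, 6050)
  expect_true(all(diff(s$times) > 0))
  s2 <- ramp_pacing_schedule(origin = 100)
  expect_identical(s2$times, s$times + 100)
})

test_that("apd recovers the closed-form duration of a trapezoidal pulse", {
  # piecewise-linear beat: rest -85 mV, instant-rise approximation over 1 ms
  # to +15 mV at t = 100, plateau to t = 300, linear fall to -85 at t = 500.
  # APD90 threshold = 15 - 0.9 * 100 = -75 mV, crossed at t = 450; activation
  # at the maximal upstroke (t in [99, 100]) => APD90 = 350.5 +- record_dt.
  t <- seq(0, 600, by = 0.5)
  v <- rep(-85, length(t))
  v[t >= 99 & t < 100] <- -85 + (t[t >= 99 & t < 100] - 99) * 100
  v[t >= 100 & t <= 300] <- 15
  fall <- t > 300 & t <= 500
  v[fall] <- 15 - (t[fall] - 300) * 0.5
  tr <- structure(list(time = t, Vm = v, Cai = rep(0.1, length(t)),
                       stim_times = 99, final_state = NULL, record_dt = 0.5),
                  class = "ap_trace")
  a <- apd(tr)
  expect_equal(nrow(a), 1)
  expect_true(a$repolarised)
  expect_equal(a$peak, 15)
  expect_equal(a$baseline, -85)
  # threshold -75 crossed at t = 480 (15 - 0.9*100 = -75; fall rate 0.5 mV/ms)
  expect_equal(a$apd, (300 + (15 - (-75)) / 0.5) - a$t_act, tolerance = 1e-6)
  a50 <- apd(tr, repolarisation_percent = 50)
  expect_equal(a50$apd, (300 + (15 - (-35)) / 0.5) - a50$t_act, tolerance = 1e-6)
})

test_that("simulate_cell is deterministic and respects the schedule", {
  m <- make_cell_model()
  sch <- pacing_schedule(400, 2)
  t1 <- simulate_cell(m, sch, dt = 0.02)
  t2 <- simulate_cell(m, sch, dt = 0.02)
  expect_identical(t1$Vm, t2$Vm)
  expect_identical(t1$final_state, t2$final_state)
  a <- apd(t1)
  expect_equal(nrow(a), 2)
  expect_true(all(a$peak > 0))
  expect_true(all(a$baseline < -75))
  expect_error(simulate_cell(m, sch, duration = 100),
               "does not cover the pacing schedule")
  expect_error(simulate_cell(m, NULL), "duration required")
})

test_that("the resting state is quiescent", {
  m <- make_cell_model()
  rs <- resting_state(m)
  tr <- simulate_cell(m, NULL, duration = 1000, init = rs, dt = 0.02)
  expect_lt(diff(range(tr$Vm)), 0.5)
  expect_lt(abs(tr$Vm[1] - rs[1]), 0.1)
})

test_that("APD90 ordering is moderate < mild < healthy for all cell types", {
  byct <- fix_apd_by_severity()
  for (ct in cell_types()) {
    a <- byct[[ct]]
    expect_lt(a[["moderate"]], a[["mild"]])
    expect_lt(a[["mild"]], a[["healthy"]])
  }
})

test_that("the apicobasal factor shortens apex APD90 by about 11 ms", {
  base <- apd90_2hz(make_cell_model())
  apex <- apd90_2hz(make_cell_model(iks_scale = apicobasal_iks_scale()))
  expect_lt(apex, base)
  expect_gt(base - apex, 5)
  expect_lt(base - apex, 20)
})

test_that("model parameters round-trip through the key-value file", {
  m <- make_cell_model("epicardial", ischaemia_config("mild"),
                       vf_variant_delta())
  path <- withr::local_tempfile(fileext = ".txt")
  write_model_params(m, path)
  p <- read_model_params(path)
  expect_equal(p, m$parameters, tolerance = 1e-15)
})

test_that("action-potential traces round-trip through columnar text", {
  m <- make_cell_model()
  tr <- simulate_cell(m, pacing_schedule(400, 1), dt = 0.02, record_dt = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ap_trace(tr, path)
  tr2 <- read_ap_trace(path)
  expect_equal(tr2$Vm, tr$Vm, tolerance = 1e-6)
  expect_equal(tr2$record_dt, 1)
})
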