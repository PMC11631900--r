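test_that("S1S2 restitution produces a clean curve for the VF variant", {
  cur <- fix_variant_curve()
  pts <- cur$points
  expect_s3_class(cur, "restitution_curve")
  expect_gt(nrow(pts), 20)
  expect_true(all(diff(pts$di) > 0))
  expect_true(all(pts$di > 0))
  expect_true(all(pts$apd90 > 0))
  # restitution: shorter diastolic interval gives shorter APD at the extremes
  expect_lt(pts$apd90[1], pts$apd90[nrow(pts)])
  # refinement resolves the steep foot: smallest DI gap below 5 ms
  expect_lt(min(diff(pts$di)), 5)
})

test_that("refinement adds points without changing the coarse sweep", {
  m <- make_cell_model(delta = vf_variant_delta())
  coarse_list <- seq(240, 600, by = 60)
  c0 <- s1s2_restitution(m, s2_list = coarse_list, refine_step = NA)
  c1 <- s1s2_restitution(m, s2_list = coarse_list, refine_step = 20)
  p0 <- c0$points
  p1 <- c1$points
  expect_true(all(p0$s2 %in% p1$s2))
  shared <- p1[match(p0$s2, p1$s2), ]
  expect_equal(shared$apd90, p0$apd90, tolerance = 1e-12)
  expect_gt(nrow(p1), nrow(p0))
  expect_error(s1s2_restitution(m, s1_cl = 400, s2_list = c(200, 450)),
               "must not exceed")
})

test_that("max_restitution_slope matches hand-computed finite differences", {
  df <- data.frame(s2 = 1:5, di = c(100, 200, 260, 300, 400),
                   apd90 = c(100, 180, 220, 240, 250))
  cur <- vfib:::new_restitution_curve(df, "S1S2")
  sl <- max_restitution_slope(cur, di_split = 280)
  # pair midpoints: 150, 230, 280, 350; the 280 midpoint sits on the split
  # and belongs to neither side
  expect_equal(sl[["below"]], max(80 / 100, 40 / 60))
  expect_equal(sl[["above"]], 10 / 100)
  # split with no pair midpoints on one side yields NA there
  sl2 <- max_restitution_slope(cur, di_split = 50)
  expect_true(is.na(sl2[["below"]]))
  dup <- vfib:::new_restitution_curve(
    data.frame(s2 = 1:2, di = c(100, 100), apd90 = c(1, 2)), "S1S2")
  expect_error(max_restitution_slope(dup), "duplicate")
})

test_that("the variant restitution is steeper than the baseline's", {
  sv <- max_restitution_slope(fix_variant_curve())
  sb <- max_restitution_slope(fix_baseline_curve())
  expect_gt(max(sv, na.rm = TRUE), max(sb, na.rm = TRUE))
})

test_that("dynamic restitution reports alternans and lost capture", {
  m <- make_cell_model(delta = vf_variant_delta())
  cur <- dynamic_restitution(m, cl_sweep = seq(500, 260, by = -60),
                             beats_per_cl = 10)
  expect_s3_class(cur, "restitution_curve")
  expect_gte(cur$alternans, 0)
  expect_true(all(cur$points$di < cur$points$cl))
  expect_error(dynamic_restitution(m, beats_per_cl = 1), ">= 2")
})

test_that("the VF variant has greater alternans amplitude than the baseline", {
  sweep <- seq(500, 260, by = -40)
  ab <- dynamic_restitution(make_cell_model(), cl_sweep = sweep,
                            beats_per_cl = 12)$alternans
  av <- dynamic_restitution(make_cell_model(delta = vf_variant_delta()),
                            cl_sweep = sweep, beats_per_cl = 12)$alternans
  expect_gt(av, ab)
})

test_that("Latin hypercube sampling is stratified at any population size", {
  for (size in c(1L, 7L, 40L)) {
    spec <- population_spec(size = size, seed = 42L)
    pop <- lhs_population(spec)
    expect_equal(nrow(pop$members), size)
    for (nm in names(spec$ranges)) {
      r <- spec$ranges[[nm]]
      u <- (pop$members[[nm]] - r[1]) / (r[2] - r[1])
      expect_true(all(u >= 0 & u <= 1))
      # exactly one sample in each of the `size` equal strata
      strata <- floor(u * size)
      expect_setequal(strata, 0:(size - 1))
    }
  }
})

test_that("population sampling is reproducible and leaves the RNG alone", {
  spec <- population_spec(size = 10, seed = 7L)
  p1 <- lhs_population(spec)
  set.seed(123)
  before <- .Random.seed
  p2 <- lhs_population(spec)
  expect_identical(.Random.seed, before)
  expect_identical(p1$members, p2$members)
  p3 <- lhs_population(population_spec(size = 10, seed = 8L))
  expect_false(identical(p1$members, p3$members))
  expect_error(population_spec(ranges = list(g_Na = c(2, 1))), "lo < hi")
  expect_error(population_spec(ranges = list(nosuch = c(1, 2))), "unknown parameter")
})

test_that("population members are multiplicative scalings of the base model", {
  pop <- lhs_population(population_spec(size = 5, seed = 1L))
  m3 <- population_model(pop, 3)
  for (nm in names(pop$members)) {
    expect_equal(m3$parameters[[nm]],
                 pop$base$parameters[[nm]] * pop$members[[nm]][3])
  }
})

test_that("two-stage calibration flags members against both range sets", {
  pop <- lhs_population(population_spec(
    size = 6, ranges = list(g_Na = c(0.5, 2), g_K = c(0.5, 2)), seed = 3L))
  # cheap synthetic evaluators reading the parameter table directly
  ev <- list(na_level = function(m) m$parameters[["g_Na"]],
             ko_level = function(m) m$parameters[["Ko"]])
  res <- calibrate_population(pop,
    healthy_ranges = list(na_level = c(10, 25)),
    ischaemia_ranges = list(ko_level = c(7.9, 8.1)),
    evaluators = ev)
  expect_equal(res$stage1, res$healthy_na_level >= 10 & res$healthy_na_level <= 25)
  # stage 2 only evaluated for stage-1 survivors; moderate config sets Ko = 8
  expect_true(all(is.na(res$ischaemic_ko_level[!res$stage1])))
  expect_equal(res$stage2, res$stage1 & !is.na(res$ischaemic_ko_level) &
                 abs(res$ischaemic_ko_level - 8) <= 0.1)
  expect_error(
    calibrate_population(pop, list(missing_marker = c(0, 1)), list(),
                         evaluators = ev),
    "missing biomarker evaluator")
})

test_that("VF-candidate selection ranks by slope and picks by alternans", {
  slopes <- c(0.2, 1.5, 0.9, 2.0, 0.1)
  alt <- c(0, 3, 10, 1, 0)
  sel <- select_vf_candidates(slopes, k = 3, alternans = alt)
  expect_identical(sel$ranked, c(4L, 2L, 3L))
  expect_identical(sel$pick, 3L)
  # abnormal members are excluded from the final pick
  sel2 <- select_vf_candidates(slopes, k = 3, alternans = alt,
                               abnormal = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(sel2$pick, 2L)
  sel3 <- select_vf_candidates(slopes, k = 2, alternans = alt,
                               abnormal = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_true(is.na(sel3$pick))
  expect_warning(select_vf_candidates(slopes, k = 10), "exceeds")
})

test_that("repolarisation-abnormality detection flags secondary upstrokes", {
  m <- make_cell_model()
  rs <- resting_state(m, duration = 2000)
  tr <- simulate_cell(m, pacing_schedule(600, 2), init = rs, dt = 0.02)
  expect_false(detect_repolarisation_abnormality(tr)$abnormal)
  # inject a synthetic early-afterdepolarisation bump during repolarisation
  a <- apd(tr)
  t_bump <- a$t_act[1] + 0.6 * a$apd[1]
  v2 <- tr$Vm
  sel <- tr$time > t_bump & tr$time < t_bump + 30
  v2[sel] <- v2[sel] + 25 * sin(pi * (tr$time[sel] - t_bump) / 30)
  tr2 <- tr
  tr2$Vm <- v2
  res <- detect_repolarisation_abnormality(tr2)
  expect_true(res$abnormal)
  expect_true(any(res$locations > t_bump & res$locations < t_bump + 30))
})
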