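test_that("noiseless traces are exact state-curve mixtures", {
  photo <- quiet_photo()
  sched <- trace_schedule()
  t <- tricscreen:::schedule_times(sched)
  # bound fraction 0: pure free-state curve
  tr0 <- simulate_trace(0, photo, sched)
  free_curve <- tricscreen:::state_curve(t, photo$f_init_free, photo$amp_free,
                                         photo$tau_free)
  expect_identical(tr0$fluorescence, free_curve)
  # cold phase is flat at the baseline mixture
  tr <- simulate_trace(0.3, photo, sched)
  cold <- tr$fluorescence[t < 0]
  expect_true(all(cold == cold[1]))
})

test_that("the long-time plateau is the bound-fraction-weighted state plateau", {
  # closed form: each state tends to f_init * (1 + amp); compare with the
  # simulated trace tail at t >> tau
  photo <- quiet_photo()
  sched <- trace_schedule(t_start = -0.2, t_end = 5, sampling_rate = 100)
  bf <- 0.5
  tr <- simulate_trace(bf, photo, sched)
  plateau_expected <- bf * photo$f_init_bound * (1 + photo$amp_bound) +
    (1 - bf) * photo$f_init_free * (1 + photo$amp_free)
  expect_equal(utils::tail(tr$fluorescence, 1), plateau_expected, tolerance = 1e-9)
})

test_that("a degenerate zero-window photophysics is rejected", {
  expect_error(tric_photophysics(amp_bound = -0.1, amp_free = -0.1),
               class = "tricscreen_invalid")
  # equal amplitudes with distinct baselines still carry signal and are fine
  expect_s3_class(tric_photophysics(f_init_bound = 800, amp_bound = -0.1,
                                    amp_free = -0.1), "tric_photophysics")
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_trace(0.4, tric_photophysics(), trace_schedule(), seed = 123)
  b <- simulate_trace(0.4, tric_photophysics(), trace_schedule(), seed = 123)
  expect_identical(a, b)
  lib <- screen_library(20, 2)
  s1 <- simulate_screen_plate(lib, bench_assay(), 100e-6, n_controls = 8, seed = 5)
  s2 <- simulate_screen_plate(lib, bench_assay(), 100e-6, n_controls = 8, seed = 5)
  expect_identical(s1, s2)
})

test_that("Fnorm encodes the bound fraction monotonically and invertibly", {
  photo <- quiet_photo()
  sched <- trace_schedule()
  bfs <- seq(0, 1, by = 0.1)
  set <- tricscreen:::simulate_trace_set(bfs, photo, sched)
  fn <- compute_fnorm(set)$fnorm
  expect_true(all(diff(fn) < 0))  # amp_bound < amp_free: more bound = dimmer
  # round trip: invert the mixture to recover the bound fraction
  fn_bound <- compute_fnorm(simulate_trace(1, photo, sched))$fnorm
  fn_free <- compute_fnorm(simulate_trace(0, photo, sched))$fnorm
  bf_rec <- (fn - fn_free) / (fn_bound - fn_free)
  expect_equal(bf_rec, bfs, tolerance = 1e-6)
})

test_that("screen plates lay out the paper-scale library with controls on every plate", {
  lib <- screen_library(220, 10)
  sc <- simulate_screen_plate(lib, bench_assay(), 100e-6, n_replicates = 2,
                              n_controls = 16, seed = 1)
  expect_equal(ncol(sc$traces$F), 220 * 2 + 16)   # 456 wells
  expect_equal(length(unique(sc$layout$plate_id)), 2)  # spill onto 2 plates
  for (p in unique(sc$layout$plate_id)) {
    lp <- sc$layout[sc$layout$plate_id == p, ]
    expect_lte(nrow(lp), 384)
    expect_gte(sum(lp$role == "control"), 2)
    expect_false(anyDuplicated(lp$well_id) > 0)
  }
  # every peptide is in duplicate at the screen concentration
  counts <- table(sc$layout$peptide_id[sc$layout$role == "test"])
  expect_true(all(counts == 2))
  expect_true(all(sc$layout$competitor_conc[sc$layout$role == "test"] == 100e-6))
})

test_that("non-binders are indistinguishable from controls without noise", {
  lib <- data.frame(peptide_id = c("a", "b"), ki = c(Inf, NA))
  sc <- simulate_screen_plate(lib, bench_assay(), 100e-6, photo = quiet_photo(),
                              n_controls = 8, seed = 1)
  ctrl <- sc$layout$well[sc$layout$role == "control"][1]
  for (w in sc$layout$well[sc$layout$role == "test"]) {
    expect_identical(sc$traces$F[, w], sc$traces$F[, ctrl])
  }
})

test_that("a binder at the screen concentration is depleted below the control", {
  lib <- data.frame(peptide_id = "hit", ki = 100e-6)
  sc <- simulate_screen_plate(lib, bench_assay(), 100e-6, n_controls = 8, seed = 1)
  bf_ctrl <- sc$truth$bound_fraction[sc$truth$role == "control"][1]
  bf_hit <- sc$truth$bound_fraction[sc$truth$role == "test"][1]
  expect_lt(bf_hit, bf_ctrl)
  # oracle: direct forward computation
  expect_equal(bf_hit,
               solve_competitive(competitive_system(5e-9, 2e-9, 1.54e-9,
                                                    100e-6, 100e-6))$tracer_bound_fraction)
})

test_that("dose-response simulations follow the dilution series and the forward model", {
  sim <- simulate_dose_response(BENCH_KI, bench_assay(), 100e-6, seed = 1)
  expect_equal(nrow(sim$layout), 12)
  expect_equal(min(sim$layout$competitor_conc), 100e-6 / 2^11, tolerance = 1e-12)
  expect_equal(max(sim$layout$competitor_conc), 100e-6)
  # a hopeless binder (Ki orders of magnitude above the top concentration)
  # leaves every well at the binary bound fraction
  sim2 <- simulate_dose_response(1e3, bench_assay(), 100e-6, seed = 1)
  bf0 <- solve_binary(bench_assay())$tracer_bound_fraction
  expect_true(all(abs(sim2$truth$bound_fraction - bf0) < 1e-6))
})

test_that("the noiseless titration crosses half-displacement at the model EC50", {
  # bisection on the forward model is the oracle for the half-displacement point
  ec50 <- tricscreen:::ic50_exact(bench_assay(), BENCH_KI)
  sys <- competitive_system(5e-9, 2e-9, 1.54e-9, 0, BENCH_KI)
  bf0 <- solve_binary(bench_assay())$tracer_bound_fraction
  bf_at <- tricscreen:::bound_fraction_curve(sys, ec50)
  expect_equal(bf_at, bf0 / 2, tolerance = 1e-9)
  # and the EC50 sits inside the simulated 12-point window from 400 uM
  conc <- build_dilution_series(BENCH_TOP)
  expect_true(ec50 < max(conc) && ec50 > min(conc))
})

test_that("artifact injection reshapes traces as specified", {
  tr <- simulate_trace(0.5, quiet_photo(), trace_schedule(), well_id = "W1")
  # vanishing magnitude leaves the trace essentially unchanged
  tiny <- inject_artifact(tr, artifact_spec("autofluorescent", 1e-12), seed = 1)
  expect_equal(tiny$fluorescence, tr$fluorescence, tolerance = 1e-9)
  up <- inject_artifact(tr, artifact_spec("autofluorescent", 0.5), seed = 1)
  expect_equal(mean(up$fluorescence) / mean(tr$fluorescence), 1.5, tolerance = 1e-12)
  dn <- inject_artifact(tr, artifact_spec("quenched", 0.3), seed = 1)
  expect_equal(dn$fluorescence, tr$fluorescence * 0.7)
  ag <- inject_artifact(tr, artifact_spec("aggregated", 0.1), seed = 1)
  expect_true(all(ag$fluorescence >= tr$fluorescence))  # additive bumps
  expect_gt(max(ag$fluorescence - tr$fluorescence), 0.05 * mean(tr$fluorescence))
  bb <- inject_artifact(tr, artifact_spec("bubble", 0.2), seed = 1)
  jumps <- abs(diff(bb$fluorescence / tr$fluorescence))
  expect_equal(sum(jumps > 0.1), 1)  # exactly one step discontinuity
  expect_error(artifact_spec("quenched", 1.2), class = "tricscreen_invalid")
})

test_that("invalid bound fractions are rejected", {
  expect_error(simulate_trace(-0.1, tric_photophysics(), trace_schedule()),
               class = "tricscreen_invalid")
  expect_error(simulate_trace(1.1, tric_photophysics(), trace_schedule()),
               class = "tricscreen_invalid")
})
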