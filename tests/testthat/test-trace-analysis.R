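make_flat_trace <- function(level = 500, hot_level = level, well = "W1") {
  t <- seq(-1, 1.5, by = 0.01)
  f <- ifelse(t <= 0, level, hot_level)
  tric_trace(well, t, f)
}

test_that("Fnorm is the hot/cold window ratio in per-mille", {
  expect_equal(compute_fnorm(make_flat_trace())$fnorm, 1000)
  # hot plateau at 90% of baseline
  expect_equal(compute_fnorm(make_flat_trace(1000, 900))$fnorm, 900)
})

test_that("Fnorm is invariant to positive rescaling of the trace", {
  tr <- simulate_trace(0.6, tric_photophysics(), trace_schedule(), seed = 3)
  fn1 <- compute_fnorm(tr)$fnorm
  for (k in c(0.01, 3, 1e4)) {
    tr2 <- tric_trace("W1", tr$time, tr$fluorescence * k)
    expect_equal(compute_fnorm(tr2)$fnorm, fn1, tolerance = 1e-12)
  }
})

test_that("pure-state Fnorm difference matches the closed-form window means", {
  photo <- quiet_photo()
  # analytic mean of 1 + amp*(1 - exp(-t/tau)) over the F1 window [1.0, 1.4]
  win_mean <- function(amp, tau, a = 1.0, b = 1.4) {
    1 + amp - amp * tau * (exp(-a / tau) - exp(-b / tau)) / (b - a)
  }
  fn_bound <- compute_fnorm(simulate_trace(1, photo, trace_schedule()))$fnorm
  fn_free <- compute_fnorm(simulate_trace(0, photo, trace_schedule()))$fnorm
  expected <- 1000 * (win_mean(photo$amp_bound, photo$tau_bound) -
                        win_mean(photo$amp_free, photo$tau_free))
  expect_equal(fn_bound - fn_free, expected, tolerance = 1e-3)
})

test_that("window misplacement and empty windows are rejected", {
  tr <- make_flat_trace()
  expect_error(compute_fnorm(tr, f0_window = c(-0.5, 0.2)), class = "tricscreen_invalid")
  expect_error(compute_fnorm(tr, f1_window = c(-0.2, 0.5)), class = "tricscreen_invalid")
  expect_error(compute_fnorm(tr, f1_window = c(2.0, 2.4)), class = "tricscreen_invalid")
})

test_that("a clean plate raises no QC flags and verdicts are deterministic", {
  lib <- screen_library(8, 0)
  sc <- simulate_screen_plate(lib, bench_assay(), 100e-6, n_controls = 8, seed = 21)
  qc1 <- qc_plate(sc$traces)
  expect_true(all(qc1$qc_pass))
  expect_identical(qc1, qc_plate(sc$traces))
})

test_that("injected artifacts are recovered by the per-well QC detectors", {
  lib <- screen_library(12, 0)
  arts <- data.frame(kind = c("autofluorescent", "quenched", "aggregated", "bubble"),
                     magnitude = c(0.5, 0.3, 0.1, 0.2))
  sc <- simulate_screen_plate(lib, bench_assay(), 100e-6, n_controls = 8,
                              artifacts = arts, seed = 31)
  qc <- qc_plate(sc$traces)
  truth <- sc$truth
  flag_of <- c(autofluorescent = "autofluorescent", quenched = "quenched",
               aggregated = "aggregated", bubble = "bubble_or_precipitate")
  for (kind in names(flag_of)) {
    w <- truth$well[which(truth$artifact == kind)]
    expect_true(qc[[flag_of[[kind]]]][match(w, qc$well_id)],
                label = paste(kind, "flagged"))
  }
})

test_that("qc_well agrees with qc_plate given the same plate context", {
  lib <- screen_library(10, 0)
  sc <- simulate_screen_plate(lib, bench_assay(), 100e-6, n_controls = 8, seed = 41)
  qc <- qc_plate(sc$traces)
  i0 <- which(sc$traces$time >= -0.8 & sc$traces$time <= 0)
  baselines <- colMeans(sc$traces$F[i0, ])
  w <- sc$layout$well[5]
  one <- qc_well(get_trace(sc$traces, w), baselines)
  expect_equal(one$qc_pass, qc$qc_pass[qc$well_id == w])
  expect_equal(one$smooth_score, qc$smooth_score[qc$well_id == w])
})

test_that("the area statistic is zero on self-comparison and non-negative always", {
  lib <- screen_library(4, 0)
  sc <- simulate_screen_plate(lib, bench_assay(), 100e-6, n_controls = 4, seed = 51)
  a <- area_statistic(sc$traces, sc$traces)
  expect_equal(a$area, 0)
  set.seed(1)
  for (i in 1:5) {
    w <- sample(sc$layout$well, 2)
    test_set <- tricscreen:::new_trace_set(sc$traces$time,
                                           sc$traces$F[, w, drop = FALSE],
                                           w, sc$traces$schedule)
    expect_gte(area_statistic(test_set, sc$traces)$area, 0)
  }
})

test_that("the noise-free full-displacement area matches the analytic integral", {
  # closed form: integral over the heating window of |mixture(bf0) - free|
  # normalized traces differ by bf0 * (g_bound - g_free) with
  # g_state = 1 + amp (1 - exp(-t/tau)); integrate term by term
  photo <- quiet_photo()
  sched <- trace_schedule()
  cfg <- tric_config()
  bf0 <- solve_binary(bench_assay())$tracer_bound_fraction
  T_end <- sched$t_end
  int_state <- function(amp, tau) amp * T_end - amp * tau * (1 - exp(-T_end / tau))
  analytic <- bf0 * abs(int_state(photo$amp_bound, photo$tau_bound) -
                          int_state(photo$amp_free, photo$tau_free)) / cfg$area_scale

  ctrl <- tricscreen:::simulate_trace_set(rep(bf0, 2), photo, sched)
  test <- tricscreen:::simulate_trace_set(0, photo, sched)
  a <- area_statistic(test, ctrl, cfg)
  expect_equal(a$area, analytic, tolerance = 1e-3)
})

test_that("the area statistic grows with the true displacement gap", {
  photo <- quiet_photo()
  sched <- trace_schedule()
  bf0 <- solve_binary(bench_assay())$tracer_bound_fraction
  ctrl <- tricscreen:::simulate_trace_set(rep(bf0, 2), photo, sched)
  areas <- vapply(seq(bf0, 0, length.out = 8), function(bf) {
    area_statistic(tricscreen:::simulate_trace_set(bf, photo, sched), ctrl)$area
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("binder classification is strict at the threshold and honors QC exclusions", {
  rec <- data.frame(peptide_id = c("a", "b", "c"), plate_id = "P01",
                    area = c(0.49, 0.51, NA), area_sd = NA, n_wells = c(2L, 2L, 0L),
                    flags = c("", "", "aggregated"),
                    evaluable = c(TRUE, TRUE, FALSE), is_binder = NA)
  out <- classify_screen(rec)
  expect_false(out$is_binder[out$peptide_id == "a"])
  expect_true(out$is_binder[out$peptide_id == "b"])
  expect_false(out$is_binder[out$peptide_id == "c"])
  expect_false(out$evaluable[out$peptide_id == "c"])
  expect_equal(out$peptide_id[1], "b")  # sorted by area
})

test_that("a binder-level peptide whose wells all fail QC is unevaluable, not a hit", {
  lib <- data.frame(peptide_id = c("hit", paste0("np", 1:11)),
                    ki = c(1e-6, rep(Inf, 11)))
  arts <- data.frame(kind = "autofluorescent", magnitude = 0.5, n = 2)
  # corrupt exactly the two wells of "hit"
  sc <- simulate_screen_plate(lib, bench_assay(), 100e-6, n_controls = 8, seed = 61)
  for (w in sc$layout$well[sc$layout$peptide_id == "hit"]) {
    tr <- inject_artifact(get_trace(sc$traces, w), artifact_spec("autofluorescent", 0.5))
    sc$traces$F[, w] <- tr$fluorescence
  }
  res <- analyze_screen(sc$traces, sc$layout)
  rec <- res$records[res$records$peptide_id == "hit", ]
  expect_false(rec$evaluable)
  expect_false(rec$is_binder)
  expect_match(rec$flags, "autofluorescent")
})

test_that("external instrument QC flags are honored in screen analysis", {
  lib <- screen_library(10, 0)
  sc <- simulate_screen_plate(lib, bench_assay(), 100e-6, n_controls = 8, seed = 71)
  sc$layout$qc_flag <- sc$layout$peptide_id == "pep001"
  res <- analyze_screen(sc$traces, sc$layout)
  expect_false(res$records$evaluable[res$records$peptide_id == "pep001"])
})
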