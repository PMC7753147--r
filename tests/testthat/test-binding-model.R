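test_that("binary equilibrium matches the single-site isotherm when depletion is negligible", {
  # 1 pM receptor, 1 nM tracer at K_D = 1 nM: free tracer ~ total, occupancy 1/2
  eq <- solve_binary(binary_system(1e-12, 1e-9, 1e-9))
  expect_equal(eq$bound_tracer / 1e-12, 0.5, tolerance = 1e-3)
  expect_equal(eq$bound_tracer, 5e-13, tolerance = 1e-3)
  # vanishing tracer probing receptor at K_D: occupancy 1/2
  eq2 <- solve_binary(binary_system(1e-9, 1e-18, 1e-9))
  expect_equal(eq2$tracer_bound_fraction, 0.5, tolerance = 1e-6)
})

test_that("binary equilibrium solves the symmetric depletion case exactly", {
  # R = T = K = 1: mass balance gives bound = (3 - sqrt(5))/2, also confirmed
  # by the independent fixed-point solver on the degenerate competitive system
  eq <- solve_binary(binary_system(1, 1, 1))
  expect_equal(eq$bound_tracer, (3 - sqrt(5)) / 2, tolerance = 1e-12)
  oracle <- solve_competitive(competitive_system(1, 1, 1, 0, 1), method = "fixed_point")
  expect_equal(eq$bound_tracer, oracle$bound_tracer, tolerance = 1e-10)
})

test_that("competitive solution degenerates correctly at the endpoints", {
  sys0 <- competitive_system(5e-9, 2e-9, 1.54e-9, 0, BENCH_KI)
  expect_equal(solve_competitive(sys0)$bound_tracer,
               solve_binary(bench_assay())$bound_tracer, tolerance = 1e-12)
  # overwhelming competitor displaces the tracer completely
  sys_inf <- competitive_system(5e-9, 2e-9, 1.54e-9, 1e6 * BENCH_KI, BENCH_KI)
  expect_lt(solve_competitive(sys_inf)$tracer_bound_fraction, 1e-4)
})

test_that("closed-form cubic agrees with the fixed-point oracle on the benchmark system", {
  sys <- competitive_system(5e-9, 2e-9, 1.54e-9, BENCH_KI, BENCH_KI)
  a <- solve_competitive(sys)
  b <- solve_competitive(sys, method = "fixed_point")
  expect_equal(a$bound_tracer, b$bound_tracer, tolerance = 1e-8)
  expect_equal(a$tracer_bound_fraction, b$tracer_bound_fraction, tolerance = 1e-8)
})

test_that("every equilibrium closes its mass balances", {
  set.seed(42)
  for (i in 1:100) {
    sys <- random_system()
    for (m in c("cubic", "fixed_point")) {
      st <- solve_competitive(sys, method = m)
      expect_lt(tricscreen:::mass_balance_error(st, sys), 1e-9)
      expect_equal(st$tracer_bound_fraction, st$bound_tracer / sys$tracer_total)
      expect_true(st$tracer_bound_fraction >= 0 && st$tracer_bound_fraction <= 1)
    }
  }
})

test_that("bound tracer is monotone in totals and dissociation constants", {
  base <- list(r = 5e-9, t = 2e-9, kd = 1.54e-9, c = 10e-6, ki = 12e-6)
  bf <- function(r = base$r, t = base$t, kd = base$kd, c = base$c, ki = base$ki) {
    solve_competitive(competitive_system(r, t, kd, c, ki))$bound_tracer
  }
  grid <- 10^seq(-1, 1, length.out = 9)
  expect_true(all(diff(vapply(grid, function(g) bf(r = base$r * g), 1)) > 0))
  expect_true(all(diff(vapply(grid, function(g) bf(t = base$t * g), 1)) > 0))
  expect_true(all(diff(vapply(grid, function(g) bf(c = base$c * g), 1)) < 0))
  expect_true(all(diff(vapply(grid, function(g) bf(kd = base$kd * g), 1)) < 0))
})

test_that("Cheng-Prusoff conversion is exact in its textbook regime", {
  # free tracer at K_D makes the correction factor exactly 2
  expect_equal(ec50_to_ki(2, binary_system(1e-12, 1, 1), mode = "cheng_prusoff"),
               1, tolerance = 1e-6)
  # zero-depletion limit: exact and Cheng-Prusoff agree within 1%, and the
  # correction factor itself tends to 1 + L/K_D with L ~ 0
  sys <- binary_system(1.54e-12, 1.54e-12, 1.54e-9)  # totals = 1e-3 x K_D
  for (ec50 in c(1e-6, 1e-5, 1e-4)) {
    cp <- ec50_to_ki(ec50, sys, mode = "cheng_prusoff")
    ex <- ec50_to_ki(ec50, sys, mode = "exact")
    expect_equal(ex / cp, 1, tolerance = 0.01)
    expect_equal(cp / ec50, 1, tolerance = 0.01)
  }
})

test_that("exact EC50-to-Ki inversion round-trips the forward model", {
  sys <- bench_assay()
  for (ki in c(1e-6, BENCH_KI, 1e-4)) {
    ec50 <- tricscreen:::ic50_exact(sys, ki)
    expect_equal(ec50_to_ki(ec50, sys, mode = "exact"), ki, tolerance = 1e-6)
  }
  # frozen value: bisection on the forward model for EC50 = 20 uM gives the
  # K_i whose predicted half-displacement is 20 uM
  ki20 <- ec50_to_ki(20e-6, sys, mode = "exact")
  expect_equal(tricscreen:::ic50_exact(sys, ki20), 20e-6, tolerance = 1e-6)
  expect_lt(ki20, 20e-6)  # the correction always shrinks the EC50
})

test_that("tight-binding EC50s below the stoichiometric floor are rejected", {
  err <- expect_error(ec50_to_ki(1e-12, bench_assay(), mode = "exact"),
                      class = "tricscreen_numeric")
  expect_match(conditionMessage(err), "tracer")
})

test_that("displacement curves are monotone with correctly ordered affinities", {
  conc <- build_dilution_series(100e-6)
  expect_equal(conc[12], 100e-6 / 2^11, tolerance = 1e-12)
  sys1 <- competitive_system(5e-9, 2e-9, 1.54e-9, 0, 2e-6)
  sys2 <- competitive_system(5e-9, 2e-9, 1.54e-9, 0, 50e-6)
  c1 <- displacement_curve(sys1, conc)
  c2 <- displacement_curve(sys2, conc)
  ord1 <- c1$bound_fraction[order(c1$competitor_total)]
  expect_true(all(diff(ord1) < 0))
  # the tighter binder displaces more at every concentration
  expect_true(all(c1$bound_fraction < c2$bound_fraction))
})

test_that("the bound fraction at the exact EC50 is the mean of the plateaus", {
  sys <- competitive_system(5e-9, 2e-9, 1.54e-9, 0, BENCH_KI)
  ec50 <- tricscreen:::ic50_exact(bench_assay(), BENCH_KI)
  bf_at_ec50 <- displacement_curve(sys, ec50)$bound_fraction
  plateau_lo <- 0  # complete displacement
  plateau_hi <- solve_binary(bench_assay())$tracer_bound_fraction
  expect_equal(bf_at_ec50, (plateau_lo + plateau_hi) / 2, tolerance = 1e-6)
})

test_that("invalid system parameters are rejected", {
  expect_error(binary_system(-1e-9, 2e-9, 1.54e-9), class = "tricscreen_invalid")
  expect_error(binary_system(1e-9, Inf, 1.54e-9), class = "tricscreen_invalid")
  expect_error(binary_system(1e-9, 2e-9, 0), class = "tricscreen_invalid")
  expect_error(competitive_system(1e-9, 2e-9, 1e-9, -1e-6, 1e-6),
               class = "tricscreen_invalid")
  expect_error(competitive_system(1e-9, 2e-9, 1e-9, 1e-6, 0),
               class = "tricscreen_invalid")
  expect_error(displacement_curve(competitive_system(1e-9, 2e-9, 1e-9, 0, 1e-6),
                                  c(1e-6, -1e-6)),
               class = "tricscreen_invalid")
})
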