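#' Binary receptor-tracer system
#'
#' Describes a single-site binding system of a receptor and a fluorescent
#' tracer. All concentrations are total (analytical) concentrations in molar;
#' use [as_molar()] for unit conversion. The benchmark assay of this package
#' uses a high-affinity dimeric tracer with an effective dissociation constant
#' of 1.54 nM, modeled as a single species with one effective K_D (avidity
#' mechanics are out of scope).
#'
#' @param receptor_total total receptor concentration (M).
#' @param tracer_total total tracer concentration (M).
#' @param kd_tracer tracer dissociation constant (M).
#' @return An object of class `binary_system`.
#' @examples
#' binary_system(5e-9, 2e-9, 1.54e-9)
#' @export
binary_system <- function(receptor_total, tracer_total, kd_tracer) {
  check_scalar(receptor_total, "receptor_total")
  check_scalar(tracer_total, "tracer_total")
  check_scalar(kd_tracer, "kd_tracer")
  structure(
    list(receptor_total = receptor_total,
         tracer_total = tracer_total,
         kd_tracer = kd_tracer),
    class = "binary_system"
  )
}

#' Competitive three-component system
#'
#' Extends [binary_system()] with an unlabeled competitor that competes with
#' the tracer for the same receptor site (displacement geometry). The
#' competitor affinity is its inhibition constant K_i.
#'
#' @inheritParams binary_system
#' @param competitor_total total competitor concentration (M), may be 0.
#' @param ki_competitor competitor dissociation constant K_i (M).
#' @return An object of class `competitive_system` (inherits `binary_system`).
#' @examples
#' competitive_system(5e-9, 2e-9, 1.54e-9, 12.1e-6, 12.1e-6)
#' @export
competitive_system <- function(receptor_total, tracer_total, kd_tracer,
                               competitor_total, ki_competitor) {
  base <- binary_system(receptor_total, tracer_total, kd_tracer)
  check_scalar(competitor_total, "competitor_total", positive = FALSE, nonneg = TRUE)
  check_scalar(ki_competitor, "ki_competitor")
  structure(
    c(unclass(base),
      list(competitor_total = competitor_total, ki_competitor = ki_competitor)),
    class = c("competitive_system", "binary_system")
  )
}

equilibrium_state <- function(free_receptor, free_tracer, free_competitor,
                              bound_tracer, bound_competitor, tracer_total) {
  structure(
    list(free_receptor = free_receptor,
         free_tracer = free_tracer,
         free_competitor = free_competitor,
         bound_tracer = bound_tracer,
         bound_competitor = bound_competitor,
         tracer_bound_fraction = bound_tracer / tracer_total),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Equilibrium state (molar):\n")
  cat(sprintf("  free receptor:   %.6g\n", x$free_receptor))
  cat(sprintf("  free tracer:     %.6g\n", x$free_tracer))
  cat(sprintf("  free competitor: %.6g\n", x$free_competitor))
  cat(sprintf("  bound tracer:    %.6g\n", x$bound_tracer))
  cat(sprintf("  bound competitor:%.6g\n", x$bound_competitor))
  cat(sprintf("  tracer bound fraction: %.6f\n", x$tracer_bound_fraction))
  invisible(x)
}

#' Exact binary binding equilibrium
#'
#' Solves the single-site mass-balance quadratic for a receptor-tracer pair,
#' with full ligand-depletion accounting (no excess-ligand approximation).
#' The bound-complex concentration is the physically admissible root
#'
#' \deqn{RT = \frac{(R_0 + T_0 + K_D) - \sqrt{(R_0 + T_0 + K_D)^2 - 4 R_0 T_0}}{2}}
#'
#' @param system a [binary_system()].
#' @return An `equilibrium_state` with `free_competitor` and
#'   `bound_competitor` set to 0.
#' @examples
#' solve_binary(binary_system(1e-12, 1e-9, 1e-9))
#' @export
solve_binary <- function(system) {
  if (!inherits(system, "binary_system")) stop_invalid("`system` must be a binary_system")
  r0 <- system$receptor_total
  t0 <- system$tracer_total
  kd <- system$kd_tracer
  s <- r0 + t0 + kd
  disc <- s^2 - 4 * r0 * t0
  # disc >= kd^2 > 0 algebraically; guard against rounding
  bound <- (s - sqrt(max(disc, 0))) / 2
  bound <- min(max(bound, 0), min(r0, t0))
  equilibrium_state(
    free_receptor = r0 - bound,
    free_tracer = t0 - bound,
    free_competitor = 0,
    bound_tracer = bound,
    bound_competitor = 0,
    tracer_total = t0
  )
}

# Free receptor concentration for two ligands (tracer A, competitor B)
# competing for one receptor site, via the exact cubic
#   P^3 + a P^2 + b P + c = 0
# (trigonometric root), vectorized over b0 (competitor total).
#
# Over the pM-mM parameter range the admissible root can sit 10+ orders of
# magnitude below the cubic coefficients, where the bare trigonometric
# formula cancels catastrophically; the root is therefore polished with
# safeguarded Newton steps, seeded from whichever of the trig root and the
# well-conditioned small-root limit (-c/b, exact as P -> 0) has the smaller
# cubic residual. Returns free receptor in [0, p0].
free_receptor_cubic <- function(p0, a0, ka, b0, kb) {
  n <- length(b0)
  a <- ka + kb + a0 + b0 - p0
  b <- kb * (a0 - p0) + ka * (b0 - p0) + ka * kb
  cc <- rep_len(-ka * kb * p0, n)
  a <- rep_len(a, n); b <- rep_len(b, n)
  q <- pmax(a^2 - 3 * b, 0)
  arg <- (-2 * a^3 + 9 * a * b - 27 * cc) / (2 * sqrt(q^3))
  arg <- pmin(pmax(arg, -1), 1)
  p_trig <- -a / 3 + (2 / 3) * sqrt(q) * cos(acos(arg) / 3)
  p_trig <- pmin(pmax(p_trig, 0), p0)
  cubic <- function(p) ((p + a) * p + b) * p + cc
  # cancellation-free positive root of the quadratic truncation
  # a*p^2 + b*p + cc (exact in the small-root regime where the trig
  # formula cancels); a > 0 there since a ~ max(K, totals) dominates
  disc <- sqrt(pmax(b^2 - 4 * a * cc, 0))
  p_quad <- ifelse(b >= 0, -2 * cc / (b + disc), (disc - b) / (2 * a))
  p_quad <- pmin(pmax(p_quad, 0), p0)
  p <- ifelse(abs(cubic(p_quad)) < abs(cubic(p_trig)), p_quad, p_trig)
  # safeguarded Newton: the cubic shares the sign of the monotone
  # mass-balance function on [0, p0], so f(0) <= 0 <= f(p0) brackets the
  # admissible root; fall back to bisection when Newton leaves the bracket
  lo <- rep_len(0, n)
  hi <- rep_len(p0, n)
  for (i in 1:200) {
    fr <- cubic(p)
    pos <- fr > 0
    hi[pos] <- p[pos]
    lo[!pos] <- p[!pos]
    dfr <- (3 * p + 2 * a) * p + b
    p_new <- ifelse(dfr != 0, p - fr / dfr, p)
    bad <- !is.finite(p_new) | p_new <= lo | p_new >= hi
    p_new[bad] <- (lo[bad] + hi[bad]) / 2
    done <- abs(p_new - p) <= 1e-15 * p_new | (hi - lo) <= 1e-15 * p_new
    p <- p_new
    if (all(done)) break
  }
  p
}

# Damped fixed-point iteration on the three free-species mass balances.
# Independent of the cubic route; serves as the numerical cross-check.
solve_competitive_fixed_point <- function(system, damping = 0.5,
                                          max_iter = 10000L, tol = 1e-12) {
  r0 <- system$receptor_total; t0 <- system$tracer_total
  kd <- system$kd_tracer
  c0 <- system$competitor_total; ki <- system$ki_competitor
  rf <- r0; tf <- t0; cf <- c0
  for (i in seq_len(max_iter)) {
    rf_new <- r0 / (1 + tf / kd + cf / ki)
    tf_new <- t0 / (1 + rf / kd)
    cf_new <- c0 / (1 + rf / ki)
    rf1 <- damping * rf + (1 - damping) * rf_new
    tf1 <- damping * tf + (1 - damping) * tf_new
    cf1 <- damping * cf + (1 - damping) * cf_new
    delta <- max(abs(rf1 - rf) / max(rf, 1e-300),
                 abs(tf1 - tf) / max(tf, 1e-300),
                 abs(cf1 - cf) / max(cf, 1e-300))
    rf <- rf1; tf <- tf1; cf <- cf1
    if (delta < tol) {
      # bound species from the converged free receptor via the isotherms
      # (cancellation-free form of total - free)
      return(equilibrium_state(
        free_receptor = rf, free_tracer = tf, free_competitor = cf,
        bound_tracer = t0 * (rf / kd) / (1 + rf / kd),
        bound_competitor = c0 * (rf / ki) / (1 + rf / ki),
        tracer_total = t0
      ))
    }
  }
  # stiff titration regimes (totals orders of magnitude above K) contract
  # too slowly for the damped iteration; finish on the monotone scalar mass
  # balance g(rf) = rf, bracketed on [0, receptor_total], by bisection
  g <- function(x) r0 / (1 + t0 / (kd + x) + c0 / (ki + x))
  lo <- 0; hi <- r0
  for (i in seq_len(300)) {
    mid <- (lo + hi) / 2
    if (g(mid) > mid) lo <- mid else hi <- mid
    if (hi - lo <= 1e-15 * hi) break
  }
  rf <- (lo + hi) / 2
  equilibrium_state(
    free_receptor = rf,
    free_tracer = t0 / (1 + rf / kd),
    free_competitor = c0 / (1 + rf / ki),
    bound_tracer = t0 * (rf / kd) / (1 + rf / kd),
    bound_competitor = c0 * (rf / ki) / (1 + rf / ki),
    tracer_total = t0
  )
}

#' Exact competitive (displacement) equilibrium
#'
#' Solves the simultaneous equilibrium of a tracer and an unlabeled
#' competitor binding the same receptor site. The free-receptor concentration
#' is the physically admissible root of the exact cubic for three-component
#' competition; complexes follow from the individual binding isotherms. A
#' damped fixed-point iteration on the mass balances is available as an
#' independent numerical route (`method = "fixed_point"`), used throughout the
#' test suite to cross-validate the closed form.
#'
#' @param system a [competitive_system()].
#' @param method `"cubic"` (closed form, default) or `"fixed_point"`.
#' @return An `equilibrium_state`.
#' @examples
#' sys <- competitive_system(5e-9, 2e-9, 1.54e-9, 12.1e-6, 12.1e-6)
#' solve_competitive(sys)
#' @export
solve_competitive <- function(system, method = c("cubic", "fixed_point")) {
  if (!inherits(system, "competitive_system")) {
    stop_invalid("`system` must be a competitive_system")
  }
  method <- match.arg(method)
  if (method == "fixed_point") return(solve_competitive_fixed_point(system))
  if (system$competitor_total == 0) {
    return(solve_binary(binary_system(system$receptor_total, system$tracer_total,
                                      system$kd_tracer)))
  }
  r0 <- system$receptor_total; t0 <- system$tracer_total
  rf <- free_receptor_cubic(r0, t0, system$kd_tracer,
                            system$competitor_total, system$ki_competitor)
  kd <- system$kd_tracer; ki <- system$ki_competitor
  tf <- t0 * kd / (kd + rf)
  cf <- system$competitor_total * ki / (ki + rf)
  equilibrium_state(
    free_receptor = rf, free_tracer = tf, free_competitor = cf,
    bound_tracer = t0 * rf / (kd + rf),
    bound_competitor = system$competitor_total * rf / (ki + rf),
    tracer_total = t0
  )
}

# Tracer bound fraction along a competitor concentration vector (vectorized
# cubic; competitor_total = 0 entries fall back to the binary solution).
bound_fraction_curve <- function(system, competitor_totals) {
  r0 <- system$receptor_total; t0 <- system$tracer_total
  kd <- system$kd_tracer; ki <- system$ki_competitor
  rf <- free_receptor_cubic(r0, t0, kd, competitor_totals, ki)
  bf <- rf / (kd + rf)
  if (any(competitor_totals == 0)) {
    bf0 <- solve_binary(binary_system(r0, t0, kd))$tracer_bound_fraction
    bf[competitor_totals == 0] <- bf0
  }
  bf
}

#' Displacement curve
#'
#' Tracer bound fraction as a function of competitor concentration for a
#' fixed receptor/tracer/K_i system. The curve is non-increasing in
#' competitor concentration; its endpoints approach the binary (no
#' competitor) solution and complete displacement.
#'
#' @param system a [competitive_system()]; its `competitor_total` is ignored.
#' @param competitor_totals non-negative numeric vector of competitor
#'   concentrations (M).
#' @return A data frame with columns `competitor_total` and `bound_fraction`,
#'   in the input order.
#' @examples
#' sys <- competitive_system(5e-9, 2e-9, 1.54e-9, 0, 12.1e-6)
#' displacement_curve(sys, build_dilution_series(100e-6))
#' @export
displacement_curve <- function(system, competitor_totals) {
  if (!inherits(system, "competitive_system")) {
    stop_invalid("`system` must be a competitive_system")
  }
  if (any(!is.finite(competitor_totals)) || any(competitor_totals < 0)) {
    stop_invalid("`competitor_totals` must be finite and non-negative")
  }
  data.frame(
    competitor_total = competitor_totals,
    bound_fraction = bound_fraction_curve(system, competitor_totals)
  )
}

# Competitor concentration at which bound tracer falls to half its
# no-competitor value (the model-predicted IC50), by root bracketing on
# log10 concentration.
ic50_exact <- function(system_binary, ki) {
  bf0 <- solve_binary(system_binary)$tracer_bound_fraction
  target <- bf0 / 2
  sys <- competitive_system(system_binary$receptor_total,
                            system_binary$tracer_total,
                            system_binary$kd_tracer, 1, ki)
  f <- function(lc) bound_fraction_curve(sys, 10^lc) - target
  lo <- -16; hi <- max(3, log10(ki) + 6)
  if (f(lo) < 0 || f(hi) > 0) {
    stop_numeric("IC50 bracketing failed for ki=", ki)
  }
  10^stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Convert an EC50 to an inhibition constant K_i
#'
#' In a displacement titration the measured half-displacement concentration
#' (EC50/IC50) overstates the competitor's true affinity because the
#' competitor must also out-compete the tracer. Two corrections are provided:
#'
#' * `"cheng_prusoff"`: \eqn{K_i = EC_{50} / (1 + [T]_{free}/K_D)} with the
#'   free tracer concentration evaluated at the half-displacement point.
#'   Exact only when receptor depletion of the tracer is negligible.
#' * `"exact"`: numerically inverts the exact competitive equilibrium — finds
#'   the K_i whose model-predicted half-displacement concentration equals the
#'   supplied EC50. Valid at any depletion level; the default downstream.
#'
#' @param ec50 measured half-displacement competitor concentration (M).
#' @param system the assay's [binary_system()] (receptor, tracer, K_D).
#' @param mode `"exact"` or `"cheng_prusoff"`.
#' @return K_i in molar.
#' @examples
#' sys <- binary_system(5e-9, 2e-9, 1.54e-9)
#' ec50_to_ki(20e-6, sys, mode = "exact")
#' ec50_to_ki(20e-6, sys, mode = "cheng_prusoff")
#' @export
ec50_to_ki <- function(ec50, system, mode = c("exact", "cheng_prusoff")) {
  check_scalar(ec50, "ec50")
  if (!inherits(system, "binary_system")) stop_invalid("`system` must be a binary_system")
  mode <- match.arg(mode)
  eq0 <- solve_binary(system)
  if (mode == "cheng_prusoff") {
    # free tracer when half the initially bound tracer has been displaced
    free_tracer_half <- system$tracer_total - eq0$bound_tracer / 2
    return(ec50 / (1 + free_tracer_half / system$kd_tracer))
  }
  # exact inversion: IC50(ki) is strictly increasing in ki
  ic50_floor <- ic50_exact(system, 1e-15)
  if (ec50 <= ic50_floor) {
    stop_numeric(
      "ec50 = ", ec50, " M is below the resolvable range of this tracer ",
      "(tight-binding floor ", signif(ic50_floor, 4),
      " M); no K_i reproduces it - the tracer is unsuitable for this affinity"
    )
  }
  g <- function(lki) log(ic50_exact(system, 10^lki)) - log(ec50)
  if (g(3) < 0) stop_numeric("ec50 = ", ec50, " M exceeds the invertible range")
  10^stats::uniroot(g, c(-15, 3), tol = 1e-10)$root
}

# Relative mass-balance closure error of an equilibrium state; used by the
# invariant tests.
mass_balance_error <- function(state, system) {
  r0 <- system$receptor_total; t0 <- system$tracer_total
  c0 <- if (!is.null(system$competitor_total)) system$competitor_total else 0
  r_err <- abs(state$free_receptor + state$bound_tracer + state$bound_competitor - r0) / r0
  t_err <- abs(state$free_tracer + state$bound_tracer - t0) / t0
  c_err <- if (c0 > 0) {
    abs(state$free_competitor + state$bound_competitor - c0) / c0
  } else 0
  max(r_err, t_err, c_err)
}
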