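#' TRIC photophysics parameters
#'
#' Parameters of the two-state (bound / free tracer) mono-exponential trace
#' model. Before the IR laser fires, a well fluoresces at the cold-state
#' level; upon heating each tracer state relaxes toward a hot plateau,
#' `f_init * (1 + amp * (1 - exp(-t / tau)))`, and the recorded trace is the
#' bound-fraction-weighted mixture of the two state curves. Defaults place
#' the hot quasi-plateau inside the standard F1 window and give a fully
#' displacing competitor an area statistic of roughly 1.5-3 under the default
#' calibration, comfortably separable at the 0.5 binder threshold.
#'
#' @param f_init_bound,f_init_free cold-state fluorescence of the bound and
#'   free tracer (arbitrary units).
#' @param amp_bound,amp_free fractional fluorescence change on heating, in
#'   (-1, 1); negative means the dye dims when hot.
#' @param tau_bound,tau_free relaxation time constants (s).
#' @param noise_cv coefficient of variation of multiplicative Gaussian noise
#'   applied per sample (0.005 = 0.5%).
#' @return An object of class `tric_photophysics`.
#' @export
tric_photophysics <- function(f_init_bound = 1000, f_init_free = 1000,
                              amp_bound = -0.12, amp_free = -0.06,
                              tau_bound = 0.15, tau_free = 0.12,
                              noise_cv = 0.005) {
  check_scalar(f_init_bound, "f_init_bound")
  check_scalar(f_init_free, "f_init_free")
  check_scalar(tau_bound, "tau_bound")
  check_scalar(tau_free, "tau_free")
  check_scalar(noise_cv, "noise_cv", positive = FALSE, nonneg = TRUE)
  for (a in c(amp_bound, amp_free)) {
    if (!is.finite(a) || a <= -1 || a >= 1) {
      stop_invalid("amplitudes must lie in (-1, 1)")
    }
  }
  if (amp_bound == amp_free && f_init_bound == f_init_free) {
    stop_invalid("amp_bound == amp_free with equal baselines gives a zero assay window")
  }
  structure(
    list(f_init_bound = f_init_bound, f_init_free = f_init_free,
         amp_bound = amp_bound, amp_free = amp_free,
         tau_bound = tau_bound, tau_free = tau_free, noise_cv = noise_cv),
    class = "tric_photophysics"
  )
}

#' Trace acquisition schedule
#'
#' Timing of one TRIC acquisition: recording starts at `t_start` (< 0, cold
#' baseline), the IR laser fires at t = 0, recording ends at `t_end`.
#'
#' @param t_start start of recording (s, negative).
#' @param t_end end of recording (s, positive).
#' @param sampling_rate samples per second (Hz).
#' @return An object of class `trace_schedule`.
#' @export
trace_schedule <- function(t_start = -1, t_end = 1.5, sampling_rate = 100) {
  if (!is.finite(t_start) || !is.finite(t_end) || t_start >= 0 || t_end <= 0) {
    stop_invalid("need t_start < 0 < t_end")
  }
  check_scalar(sampling_rate, "sampling_rate")
  structure(list(t_start = t_start, t_end = t_end, sampling_rate = sampling_rate),
            class = "trace_schedule")
}

schedule_times <- function(schedule) {
  seq(schedule$t_start, schedule$t_end, by = 1 / schedule$sampling_rate)
}

# Noiseless state curve: cold baseline for t < 0, mono-exponential
# relaxation for t >= 0.
state_curve <- function(t, f_init, amp, tau) {
  f_init * ifelse(t < 0, 1, 1 + amp * (1 - exp(-pmax(t, 0) / tau)))
}

# Noiseless mixture trace for a vector of bound fractions: returns a
# length(t) x length(bf) matrix.
mixture_curves <- function(bound_fractions, photo, t) {
  fb <- state_curve(t, photo$f_init_bound, photo$amp_bound, photo$tau_bound)
  ff <- state_curve(t, photo$f_init_free, photo$amp_free, photo$tau_free)
  outer(fb, bound_fractions) + outer(ff, 1 - bound_fractions)
}

new_trace_set <- function(time, F, well_id, schedule) {
  colnames(F) <- well_id
  structure(list(time = time, F = F, well_id = well_id, schedule = schedule),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set: %d wells x %d samples, t in [%g, %g] s>\n",
              ncol(x$F), length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Extract one trace from a trace set
#'
#' @param set a `trace_set`.
#' @param well well id.
#' @return A `tric_trace` (well_id, time, fluorescence, schedule).
#' @export
get_trace <- function(set, well) {
  if (!well %in% set$well_id) stop_invalid("well '", well, "' not in trace set")
  tric_trace(well, set$time, set$F[, well], set$schedule)
}

#' Construct a single TRIC trace
#'
#' @param well_id well identifier.
#' @param time strictly increasing time vector (s).
#' @param fluorescence positive fluorescence vector (a.u.).
#' @param schedule optional [trace_schedule()].
#' @return An object of class `tric_trace`.
#' @export
tric_trace <- function(well_id, time, fluorescence, schedule = NULL) {
  if (length(time) != length(fluorescence)) {
    stop_invalid("time and fluorescence must have equal length")
  }
  if (any(diff(time) <= 0)) stop_invalid("time must be strictly increasing")
  if (any(!is.finite(fluorescence)) || any(fluorescence <= 0)) {
    stop_invalid("fluorescence must be finite and positive (well ", well_id, ")")
  }
  structure(list(well_id = well_id, time = time, fluorescence = fluorescence,
                 schedule = schedule),
            class = "tric_trace")
}

#' Simulate a single TRIC trace
#'
#' Generates the bound-fraction-weighted mixture of the bound and free state
#' curves on the schedule's time grid, with multiplicative Gaussian noise.
#' Deterministic for a fixed seed.
#'
#' @param bound_fraction tracer bound fraction in \[0, 1\].
#' @param photo a [tric_photophysics()].
#' @param schedule a [trace_schedule()].
#' @param seed integer seed, or NULL to draw from the ambient RNG stream.
#' @param well_id well identifier for the returned trace.
#' @return A `tric_trace`.
#' @examples
#' tr <- simulate_trace(0.5, tric_photophysics(), trace_schedule(), seed = 1)
#' @export
simulate_trace <- function(bound_fraction, photo = tric_photophysics(),
                           schedule = trace_schedule(), seed = NULL,
                           well_id = "A1") {
  if (!is.numeric(bound_fraction) || length(bound_fraction) != 1L ||
      !is.finite(bound_fraction) || bound_fraction < 0 || bound_fraction > 1) {
    stop_invalid("`bound_fraction` must be a single value in [0, 1]")
  }
  t <- schedule_times(schedule)
  f <- drop(mixture_curves(bound_fraction, photo, t))
  if (photo$noise_cv > 0) {
    f <- with_seed(seed, f * (1 + stats::rnorm(length(f), sd = photo$noise_cv)))
  }
  tric_trace(well_id, t, f, schedule)
}

# Vectorized simulation of many wells sharing one schedule; one RNG draw
# block so results are reproducible as a set.
simulate_trace_set <- function(bound_fractions, photo, schedule, seed = NULL,
                               well_id = NULL) {
  t <- schedule_times(schedule)
  F <- mixture_curves(bound_fractions, photo, t)
  if (photo$noise_cv > 0) {
    F <- with_seed(seed,
      F * (1 + matrix(stats::rnorm(length(F), sd = photo$noise_cv), nrow(F))))
  }
  if (is.null(well_id)) well_id <- paste0("W", seq_along(bound_fractions))
  new_trace_set(t, F, well_id, schedule)
}

#' Artifact specification
#'
#' Describes one measurement artifact class injected into simulated wells:
#' `autofluorescent` (whole trace scaled up), `quenched` (scaled down),
#' `aggregated` (smooth spurious bumps in the heating window, the signature
#' of protein/peptide aggregates drifting through the detection volume), or
#' `bubble` (a step discontinuity, as caused by air bubbles or
#' precipitates).
#'
#' @param kind one of `"autofluorescent"`, `"quenched"`, `"aggregated"`,
#'   `"bubble"`.
#' @param magnitude positive relative magnitude of the distortion.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(kind = c("autofluorescent", "quenched", "aggregated", "bubble"),
                          magnitude) {
  kind <- match.arg(kind)
  check_scalar(magnitude, "magnitude")
  if (kind == "quenched" && magnitude >= 1) {
    stop_invalid("quenching magnitude >= 1 would make fluorescence non-positive")
  }
  structure(list(kind = kind, magnitude = magnitude), class = "artifact_spec")
}

#' Inject a measurement artifact into a trace
#'
#' @param trace a `tric_trace`.
#' @param spec an [artifact_spec()].
#' @param seed integer seed for the randomized artifact shapes (aggregation
#'   bump placement, bubble step time).
#' @return The distorted `tric_trace`.
#' @export
inject_artifact <- function(trace, spec, seed = NULL) {
  if (!inherits(trace, "tric_trace")) stop_invalid("`trace` must be a tric_trace")
  if (!inherits(spec, "artifact_spec")) stop_invalid("`spec` must be an artifact_spec")
  f <- trace$fluorescence
  t <- trace$time
  m <- spec$magnitude
  f2 <- switch(spec$kind,
    autofluorescent = f * (1 + m),
    quenched = f * (1 - m),
    aggregated = with_seed(seed, {
      n_bump <- sample(1:3, 1)
      hot <- range(t[t >= 0])
      height <- m * mean(f)
      bump <- rep(0, length(t))
      for (i in seq_len(n_bump)) {
        center <- stats::runif(1, hot[1] + 0.05, hot[2] - 0.05)
        width <- stats::runif(1, 0.05, 0.3)
        bump <- bump + height * exp(-0.5 * ((t - center) / width)^2)
      }
      f + bump
    }),
    bubble = with_seed(seed, {
      hot <- t[t >= 0]
      t_step <- hot[sample(seq(10, length(hot) - 10), 1)]
      f * ifelse(t >= t_step, 1 + m, 1)
    })
  )
  if (any(f2 <= 0)) {
    stop_invalid("artifact magnitude ", m, " drives fluorescence non-positive")
  }
  tric_trace(trace$well_id, t, f2, trace$schedule)
}

well_ids_384 <- function(idx) {
  # A1..A24, B1..B24, ... P24 (row-major)
  rows <- LETTERS[1:16]
  paste0(rows[(idx - 1) %/% 24 + 1], (idx - 1) %% 24 + 1)
}

#' Simulate a single-dose screening experiment
#'
#' Lays a peptide library out on one or more 384-well plates, each peptide
#' in `n_replicates` wells at a single screening concentration plus
#' no-competitor control wells (tracer-receptor complex only), computes the
#' ground-truth tracer bound fraction of every well from the exact
#' competitive equilibrium, and simulates all traces. Optional artifact
#' wells are corrupted after simulation and recorded in the ground truth.
#' Libraries exceeding one plate spill onto additional plates; controls are
#' distributed so every plate carries its own.
#'
#' @param library data frame with columns `peptide_id` and `ki` (molar;
#'   `NA` or `Inf` marks a non-binder).
#' @param assay the assay [binary_system()].
#' @param screen_conc single screening concentration of every peptide (M).
#' @param photo,schedule simulator parameter objects.
#' @param n_replicates wells per peptide (default 2, the standard duplicate).
#' @param n_controls total number of control wells (split across plates).
#' @param artifacts optional data frame with columns `kind`, `magnitude` and
#'   optionally `n` (default 1): each row corrupts `n` randomly chosen test
#'   wells.
#' @param seed integer seed.
#' @return A list with elements `traces` (a `trace_set`), `layout` (plate
#'   layout data frame) and `truth` (per-well ground truth: bound fraction,
#'   artifact kind).
#' @export
simulate_screen_plate <- function(library, assay, screen_conc,
                                  photo = tric_photophysics(),
                                  schedule = trace_schedule(),
                                  n_replicates = 2, n_controls = 16,
                                  artifacts = NULL, seed = NULL) {
  if (!is.data.frame(library) || nrow(library) == 0 ||
      !all(c("peptide_id", "ki") %in% names(library))) {
    stop_invalid("`library` must be a non-empty data frame with peptide_id and ki")
  }
  if (n_controls < 2) stop_invalid("at least 2 control wells are required")
  check_scalar(screen_conc, "screen_conc")

  bf0 <- solve_binary(assay)$tracer_bound_fraction
  ki <- library$ki
  is_binder_truth <- is.finite(ki)
  bf_pep <- rep(bf0, nrow(library))
  if (any(is_binder_truth)) {
    bf_pep[is_binder_truth] <- vapply(ki[is_binder_truth], function(k) {
      solve_competitive(competitive_system(
        assay$receptor_total, assay$tracer_total, assay$kd_tracer,
        screen_conc, k))$tracer_bound_fraction
    }, numeric(1))
  }

  n_test <- nrow(library) * n_replicates
  n_total <- n_test + n_controls
  n_plates <- ceiling(n_total / 384L)

  # distribute controls round-robin across plates, then fill test wells
  ctrl_plate <- rep(seq_len(n_plates), length.out = n_controls)
  cap <- rep(384L, n_plates)
  ctrl_per_plate <- tabulate(ctrl_plate, n_plates)
  test_cap <- cap - ctrl_per_plate

  test_rows <- data.frame(
    peptide_id = rep(library$peptide_id, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = nrow(library)),
    bound_fraction = rep(bf_pep, each = n_replicates),
    stringsAsFactors = FALSE
  )
  test_plate <- rep(seq_len(n_plates), times = test_cap)[seq_len(n_test)]

  layout <- rbind(
    data.frame(plate_id = sprintf("P%02d", test_plate),
               peptide_id = test_rows$peptide_id, role = "test",
               competitor_conc = screen_conc, replicate = test_rows$replicate,
               stringsAsFactors = FALSE),
    data.frame(plate_id = sprintf("P%02d", ctrl_plate),
               peptide_id = "CONTROL", role = "control",
               competitor_conc = 0, replicate = seq_len(n_controls),
               stringsAsFactors = FALSE)
  )
  layout <- layout[order(layout$plate_id), ]
  idx_in_plate <- stats::ave(rep(1L, nrow(layout)), layout$plate_id, FUN = seq_along)
  layout$well_id <- well_ids_384(idx_in_plate)
  layout$well <- paste(layout$plate_id, layout$well_id, sep = ":")
  rownames(layout) <- NULL

  bf_well <- ifelse(layout$role == "control", bf0, NA_real_)
  bf_map <- stats::setNames(bf_pep, library$peptide_id)
  test_idx <- layout$role == "test"
  bf_well[test_idx] <- bf_map[layout$peptide_id[test_idx]]

  traces <- simulate_trace_set(bf_well, photo, schedule,
                               seed = child_seed(seed, 1), well_id = layout$well)

  truth <- data.frame(well = layout$well, peptide_id = layout$peptide_id,
                      role = layout$role, bound_fraction = bf_well,
                      artifact = NA_character_, stringsAsFactors = FALSE)

  if (!is.null(artifacts) && nrow(artifacts) > 0) {
    if (is.null(artifacts$n)) artifacts$n <- 1L
    pool <- which(test_idx)
    k <- 0L
    pick <- with_seed(child_seed(seed, 2),
                      sample(pool, sum(artifacts$n)))
    for (i in seq_len(nrow(artifacts))) {
      for (j in seq_len(artifacts$n[i])) {
        k <- k + 1L
        w <- pick[k]
        tr <- inject_artifact(
          get_trace(traces, layout$well[w]),
          artifact_spec(artifacts$kind[i], artifacts$magnitude[i]),
          seed = child_seed(seed, 100 + k)
        )
        traces$F[, layout$well[w]] <- tr$fluorescence
        truth$artifact[w] <- artifacts$kind[i]
      }
    }
  }

  list(traces = traces, layout = layout, truth = truth)
}

#' Simulate a twelve-point dose-response experiment
#'
#' Generates the standard displacement titration: a dilution series of the
#' unlabeled peptide (default 12 points, factor 2) incubated with a constant
#' receptor-tracer complex, with per-well ground truth from the exact
#' competitive equilibrium.
#'
#' @param ki true competitor K_i (M); `NA`/`Inf` simulates a non-binder.
#' @param assay the assay [binary_system()].
#' @param top top competitor concentration (M).
#' @param n_points,factor dilution series geometry.
#' @param photo,schedule simulator parameter objects.
#' @param n_replicates number of independent series.
#' @param seed integer seed.
#' @param peptide_id identifier used in the layout.
#' @return A list with `traces`, `layout` (including `competitor_conc`) and
#'   `truth`.
#' @export
simulate_dose_response <- function(ki, assay, top, n_points = 12, factor = 2,
                                   photo = tric_photophysics(),
                                   schedule = trace_schedule(),
                                   n_replicates = 1, seed = NULL,
                                   peptide_id = "PEP1") {
  conc <- build_dilution_series(top, n_points, factor)
  if (is.finite(ki)) {
    sys <- competitive_system(assay$receptor_total, assay$tracer_total,
                              assay$kd_tracer, 1, ki)
    bf <- bound_fraction_curve(sys, conc)
  } else {
    bf <- rep(solve_binary(assay)$tracer_bound_fraction, n_points)
  }
  layout <- data.frame(
    plate_id = "P01",
    peptide_id = peptide_id, role = "dose",
    competitor_conc = rep(conc, times = n_replicates),
    replicate = rep(seq_len(n_replicates), each = n_points),
    stringsAsFactors = FALSE
  )
  layout$well_id <- well_ids_384(seq_len(nrow(layout)))
  layout$well <- paste(layout$plate_id, layout$well_id, sep = ":")
  traces <- simulate_trace_set(rep(bf, times = n_replicates), photo, schedule,
                               seed = child_seed(seed, 1), well_id = layout$well)
  truth <- data.frame(well = layout$well, peptide_id = peptide_id,
                      role = "dose",
                      competitor_conc = layout$competitor_conc,
                      bound_fraction = rep(bf, times = n_replicates),
                      artifact = NA_character_, stringsAsFactors = FALSE)
  list(traces = traces, layout = layout, truth = truth)
}
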