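#' Analysis configuration
#'
#' Window placements, QC thresholds and the area calibration used by the
#' trace-analysis stage. All thresholds are explicit so a binder call is a
#' pure function of trace + plate context + configuration.
#'
#' @param f0_window,f1_window cold (pre-laser) and hot (quasi-plateau) time
#'   windows, seconds, as `c(lo, hi)`.
#' @param area_window integration window of the area statistic (s).
#' @param area_scale calibration divisor of the area statistic. The default
#'   (0.04) is the analytic area between the pure free-state and pure
#'   bound-state curves under the default photophysics divided by 2, so that
#'   a fully displacing competitor in a fully bound control assay scores
#'   about 2 on the dimensionless area scale.
#' @param area_threshold binder classification threshold on the area
#'   statistic (strictly greater than; default 0.5).
#' @param t_auto,t_quench relative deviation of a well's cold baseline from
#'   the plate median that flags autofluorescence / quenching.
#' @param t_agg aggregation flag threshold: maximum deviation of the smoothed
#'   heating-phase trace from its mono-exponential relaxation reference, in
#'   robust noise units.
#' @param t_step bubble/precipitate flag threshold: largest single-sample
#'   jump in robust noise units of the differenced trace.
#' @return An object of class `tric_config` (a list).
#' @export
tric_config <- function(f0_window = c(-0.8, 0), f1_window = c(1.0, 1.4),
                        area_window = NULL, area_scale = 0.04,
                        area_threshold = 0.5,
                        t_auto = 0.2, t_quench = 0.15,
                        t_agg = 6, t_step = 8) {
  structure(list(f0_window = f0_window, f1_window = f1_window,
                 area_window = area_window, area_scale = area_scale,
                 area_threshold = area_threshold,
                 t_auto = t_auto, t_quench = t_quench,
                 t_agg = t_agg, t_step = t_step),
            class = "tric_config")
}

window_idx <- function(time, window, what, well = NULL) {
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) == 0) {
    stop_invalid("empty ", what, " window [", window[1], ", ", window[2], "]",
                 if (!is.null(well)) paste0(" for well ", well))
  }
  idx
}

#' Normalized fluorescence (F_norm) of TRIC traces
#'
#' F_norm compares the relative fluorescence in the hot window (F1) to the
#' cold baseline (F0): `fnorm = 1000 * mean(F1) / mean(F0)`, conventionally
#' reported in per-mille. Because it is a ratio, F_norm is invariant to any
#' positive rescaling of the raw trace.
#'
#' @param x a `tric_trace` or a `trace_set`.
#' @param f0_window,f1_window time windows (s); F0 must end at or before
#'   laser-on (t = 0), F1 must start after it.
#' @return A data frame with columns `well_id`, `f0`, `f1`, `fnorm`.
#' @examples
#' tr <- simulate_trace(1, tric_photophysics(noise_cv = 0), trace_schedule())
#' compute_fnorm(tr)
#' @export
compute_fnorm <- function(x, f0_window = c(-0.8, 0), f1_window = c(1.0, 1.4)) {
  if (f0_window[2] > 0) stop_invalid("f0_window must end at or before laser-on (t = 0)")
  if (f1_window[1] <= 0) stop_invalid("f1_window must start after laser-on (t = 0)")
  if (inherits(x, "tric_trace")) {
    x <- new_trace_set(x$time, matrix(x$fluorescence, ncol = 1), x$well_id,
                       x$schedule)
  }
  if (!inherits(x, "trace_set")) stop_invalid("`x` must be a tric_trace or trace_set")
  i0 <- window_idx(x$time, f0_window, "F0")
  i1 <- window_idx(x$time, f1_window, "F1")
  f0 <- colMeans(x$F[i0, , drop = FALSE])
  f1 <- colMeans(x$F[i1, , drop = FALSE])
  data.frame(well_id = x$well_id, f0 = unname(f0), f1 = unname(f1),
             fnorm = unname(1000 * f1 / f0), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Robust noise scale of a vector: 1.4826 * MAD of the high-pass residual
# (trace minus its running median), i.e. an outlier-resistant sigma.
robust_noise_scale <- function(f, k = 5) {
  hp <- f - stats::runmed(f, k, endrule = "median")
  stats::mad(hp)
}

# Smooth reference of the heating phase: running median, then the best
# least-squares mono-exponential relaxation c0 + c1*exp(-t/tau) over a grid
# of time constants. Any well is a two-state relaxation mixture, which a
# single exponential tracks to well below the noise floor, while aggregation
# bumps cannot be absorbed - including bumps that ride the transient without
# breaking monotonicity, which an isotonic reference would miss.
relaxation_reference <- function(f_hot, t_hot,
                                 taus = seq(0.06, 0.4, by = 0.02)) {
  mm <- stats::runmed(f_hot, 5, endrule = "median")
  best <- Inf
  resid <- mm * 0
  for (tau in taus) {
    X <- cbind(1, exp(-t_hot / tau))
    cf <- stats::.lm.fit(X, mm)
    sse <- sum(cf$residuals^2)
    if (sse < best) {
      best <- sse
      resid <- cf$residuals
    }
  }
  resid
}

qc_metrics_one <- function(f, time, baseline, plate_median_baseline) {
  hot <- which(time >= 0)
  fh <- f[hot]
  resid <- relaxation_reference(fh, time[hot])
  scale <- robust_noise_scale(fh)
  smooth_score <- if (scale > 0) max(abs(resid)) / scale else 0
  d <- diff(f)
  dscale <- stats::mad(d)
  # a bubble step must stand out of the sample-to-sample noise AND be a
  # discontinuity of meaningful size relative to the signal level (guards
  # the noise-normalized score against near-zero noise floors)
  step_score <- if (dscale > 0 && max(abs(d)) > 0.05 * stats::median(f)) {
    max(abs(d)) / dscale
  } else 0
  c(baseline = unname(baseline),
    baseline_ratio = unname(baseline / plate_median_baseline),
    smooth_score = smooth_score,
    step_score = step_score)
}

#' Per-well quality control
#'
#' Flags wells whose traces carry measurement artifacts, using the plate as
#' its own reference population:
#'
#' * `autofluorescent`: cold baseline above the plate median by more than
#'   `t_auto` (relative).
#' * `quenched`: cold baseline below the plate median by more than `t_quench`.
#' * `aggregated`: the smoothed heating-phase trace deviates from its best
#'   mono-exponential relaxation reference (running median followed by a
#'   least-squares relaxation fit over a grid of time constants) by more
#'   than `t_agg` robust noise units - the signature of aggregates drifting
#'   through the detection volume.
#' * `bubble_or_precipitate`: a single-sample step exceeding `t_step` robust
#'   noise units of the differenced trace. Instrument-side axial-scan flags,
#'   when present in the layout (`qc_flag` column), are honored in
#'   [analyze_screen()]; this detector is the software proxy.
#'
#' Verdicts are pure functions of the traces and the configuration; metrics
#' are always reported alongside the flags.
#'
#' @param traces a `trace_set` covering one plate (at least 8 wells for a
#'   robust baseline reference).
#' @param config a [tric_config()].
#' @return A data frame, one row per well: `well_id`, metric columns
#'   (`baseline`, `baseline_ratio`, `smooth_score`, `step_score`), one
#'   logical column per flag, and `qc_pass`.
#' @export
qc_plate <- function(traces, config = tric_config()) {
  if (!inherits(traces, "trace_set")) stop_invalid("`traces` must be a trace_set")
  n <- ncol(traces$F)
  if (n < 8) stop_invalid("need >= 8 wells on a plate for robust QC baselines")
  i0 <- window_idx(traces$time, config$f0_window, "F0")
  baselines <- colMeans(traces$F[i0, , drop = FALSE])
  med <- stats::median(baselines)
  metrics <- t(vapply(seq_len(n), function(j) {
    qc_metrics_one(traces$F[, j], traces$time, baselines[j], med)
  }, numeric(4)))
  out <- data.frame(well_id = traces$well_id, metrics, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$autofluorescent <- out$baseline_ratio > 1 + config$t_auto
  out$quenched <- out$baseline_ratio < 1 - config$t_quench
  out$aggregated <- out$smooth_score > config$t_agg
  out$bubble_or_precipitate <- out$step_score > config$t_step
  out$qc_pass <- !(out$autofluorescent | out$quenched | out$aggregated |
                     out$bubble_or_precipitate)
  out
}

#' QC verdict for a single well
#'
#' Convenience wrapper around [qc_plate()] when the plate context (cold
#' baselines of all wells) is supplied separately.
#'
#' @param trace a `tric_trace`.
#' @param plate_baselines numeric vector of cold-baseline means of all wells
#'   on the plate (length >= 8).
#' @param config a [tric_config()].
#' @return A one-row data frame as in [qc_plate()].
#' @export
qc_well <- function(trace, plate_baselines, config = tric_config()) {
  if (length(plate_baselines) < 8) {
    stop_invalid("need >= 8 plate baselines for robust QC")
  }
  i0 <- window_idx(trace$time, config$f0_window, "F0", trace$well_id)
  baseline <- mean(trace$fluorescence[i0])
  med <- stats::median(plate_baselines)
  m <- qc_metrics_one(trace$fluorescence, trace$time, baseline, med)
  out <- data.frame(well_id = trace$well_id, t(m), row.names = NULL,
                    stringsAsFactors = FALSE)
  out$autofluorescent <- out$baseline_ratio > 1 + config$t_auto
  out$quenched <- out$baseline_ratio < 1 - config$t_quench
  out$aggregated <- out$smooth_score > config$t_agg
  out$bubble_or_precipitate <- out$step_score > config$t_step
  out$qc_pass <- !(out$autofluorescent | out$quenched | out$aggregated |
                     out$bubble_or_precipitate)
  out
}

# Baseline-normalize trace columns to their own F0 mean (baseline = 1).
normalize_to_f0 <- function(F, time, f0_window) {
  i0 <- window_idx(time, f0_window, "F0")
  sweep(F, 2, colMeans(F[i0, , drop = FALSE]), "/")
}

#' Area-between-traces screening statistic
#'
#' The single-dose binder readout: every trace is normalized to its own cold
#' baseline, and the statistic is the trapezoidal integral over the heating
#' window of the absolute difference between the mean normalized test trace
#' and the mean normalized control trace, divided by the calibration scale
#' `area_scale`. The absolute difference makes the call one-sided in
#' magnitude regardless of whether the dye brightens or dims on binding.
#' The replicate spread is the standard deviation of single-test-trace areas
#' against the pooled control.
#'
#' @param test_traces,control_traces `trace_set`s of QC-passing test and
#'   control wells (>= 1 test, >= 2 controls) on a shared time grid.
#' @param config a [tric_config()]; `area_window` defaults to the full
#'   heating phase.
#' @return A list with `area`, `area_sd`, `n_test`, `n_control`.
#' @export
area_statistic <- function(test_traces, control_traces, config = tric_config()) {
  if (!inherits(test_traces, "trace_set") || !inherits(control_traces, "trace_set")) {
    stop_invalid("trace inputs must be trace_sets")
  }
  if (ncol(test_traces$F) < 1) stop_invalid("need >= 1 usable test trace")
  if (ncol(control_traces$F) < 2) stop_invalid("need >= 2 usable control traces")
  if (!isTRUE(all.equal(test_traces$time, control_traces$time))) {
    stop_invalid("test and control traces must share a time grid")
  }
  time <- test_traces$time
  win <- config$area_window
  if (is.null(win)) win <- c(0, max(time))
  iw <- window_idx(time, win, "area")
  Ft <- normalize_to_f0(test_traces$F, time, config$f0_window)
  Fc <- normalize_to_f0(control_traces$F, time, config$f0_window)
  ctrl_mean <- rowMeans(Fc)
  tw <- time[iw]
  area_of <- function(curve) {
    trapz(tw, abs(curve - ctrl_mean)[iw]) / config$area_scale
  }
  area <- area_of(rowMeans(Ft))
  per_test <- apply(Ft, 2, area_of)
  list(area = area,
       area_sd = if (length(per_test) > 1) stats::sd(per_test) else NA_real_,
       n_test = ncol(Ft), n_control = ncol(Fc))
}

#' Run the single-dose screen analysis on a plate set
#'
#' For each peptide: QC all wells, drop flagged test wells, compute the
#' area statistic of the surviving wells against the QC-passing control
#' wells of the same plate, and classify. External instrument QC flags can
#' be supplied as a logical `qc_flag` column in the layout (`TRUE` =
#' flagged); they are combined with the software detectors.
#'
#' @param traces a `trace_set` (may span several plates).
#' @param layout plate layout data frame as produced by
#'   [simulate_screen_plate()] or [read_layout()].
#' @param config a [tric_config()].
#' @return A list with `records` (per-peptide screen records) and `qc`
#'   (per-well QC table).
#' @export
analyze_screen <- function(traces, layout, config = tric_config()) {
  stopifnot(inherits(traces, "trace_set"), is.data.frame(layout))
  if (!all(layout$well %in% traces$well_id)) {
    stop_invalid("layout wells missing from trace set: ",
                 paste(utils::head(setdiff(layout$well, traces$well_id), 3),
                       collapse = ", "))
  }
  plates <- unique(layout$plate_id)
  qc_all <- list()
  records <- list()
  for (p in plates) {
    lp <- layout[layout$plate_id == p, ]
    sub <- new_trace_set(traces$time, traces$F[, lp$well, drop = FALSE],
                         lp$well, traces$schedule)
    qc <- qc_plate(sub, config)
    if (!is.null(lp$qc_flag)) {
      ext <- lp$qc_flag[match(qc$well_id, lp$well)]
      ext[is.na(ext)] <- FALSE
      qc$external_flag <- as.logical(ext)
      qc$qc_pass <- qc$qc_pass & !qc$external_flag
    }
    qc$plate_id <- p
    qc_all[[p]] <- qc
    ctrl_wells <- lp$well[lp$role == "control"]
    ctrl_ok <- ctrl_wells[qc$qc_pass[match(ctrl_wells, qc$well_id)]]
    if (length(ctrl_ok) < 2) {
      stop_invalid("fewer than 2 QC-passing control wells on plate ", p)
    }
    ctrl_set <- new_trace_set(traces$time, traces$F[, ctrl_ok, drop = FALSE],
                              ctrl_ok, traces$schedule)
    for (pep in unique(lp$peptide_id[lp$role == "test"])) {
      wells <- lp$well[lp$role == "test" & lp$peptide_id == pep]
      pass <- qc$qc_pass[match(wells, qc$well_id)]
      flags <- character(0)
      for (fl in c("autofluorescent", "quenched", "aggregated",
                   "bubble_or_precipitate")) {
        if (any(qc[[fl]][match(wells, qc$well_id)])) flags <- c(flags, fl)
      }
      usable <- wells[pass]
      if (length(usable) == 0) {
        records[[paste(p, pep)]] <- data.frame(
          peptide_id = pep, plate_id = p, area = NA_real_, area_sd = NA_real_,
          n_wells = 0L, flags = paste(flags, collapse = ";"),
          evaluable = FALSE, is_binder = FALSE, stringsAsFactors = FALSE)
        next
      }
      test_set <- new_trace_set(traces$time, traces$F[, usable, drop = FALSE],
                                usable, traces$schedule)
      a <- area_statistic(test_set, ctrl_set, config)
      records[[paste(p, pep)]] <- data.frame(
        peptide_id = pep, plate_id = p, area = a$area, area_sd = a$area_sd,
        n_wells = length(usable), flags = paste(flags, collapse = ";"),
        evaluable = TRUE, is_binder = NA, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, unname(records))
  rownames(records) <- NULL
  records <- classify_screen(records, config$area_threshold)
  qc_all <- do.call(rbind, unname(qc_all))
  rownames(qc_all) <- NULL
  list(records = records, qc = qc_all)
}

#' Classify screen records into binders and non-binders
#'
#' A peptide is a binder when its area statistic strictly exceeds the
#' threshold (default 0.5) and it is evaluable, i.e. at least one of its
#' wells survived QC; peptides whose every well was flagged are marked
#' unevaluable rather than silently scored 0. The returned table is sorted
#' by decreasing area.
#'
#' @param records data frame with at least `peptide_id`, `area`, `evaluable`.
#' @param threshold area threshold (default 0.5, strict inequality).
#' @return The records, with `is_binder` filled in, sorted by area.
#' @export
classify_screen <- function(records, threshold = 0.5) {
  stopifnot(is.data.frame(records))
  records$is_binder <- records$evaluable & !is.na(records$area) &
    records$area > threshold
  records[order(-ifelse(is.na(records$area), -Inf, records$area)), , drop = FALSE]
}
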