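#' Build a geometric dilution series
#'
#' The standard displacement titration layout: `n` concentrations starting
#' at `top` and decreasing by `factor` (default 12 points, two-fold), i.e.
#' `top / factor^k` for k = 0..n-1.
#'
#' @param top top concentration (M).
#' @param n number of points (>= 2).
#' @param factor dilution factor (> 1).
#' @return Numeric vector of length `n`, decreasing.
#' @examples
#' build_dilution_series(100e-6)  # 100 uM down to ~48.8 nM
#' @export
build_dilution_series <- function(top, n = 12, factor = 2) {
  check_scalar(top, "top")
  if (!is.numeric(n) || n < 2 || n != round(n)) stop_invalid("`n` must be an integer >= 2")
  if (!is.numeric(factor) || factor <= 1) stop_invalid("`factor` must be > 1")
  top / factor^(seq_len(n) - 1)
}

#' Assemble a dose series from traces and layout
#'
#' Computes F_norm for every dose-response well and attaches concentrations
#' and QC verdicts, yielding the table [fit_dose_response()] consumes.
#'
#' @param traces a `trace_set`.
#' @param layout layout data frame with `well`, `competitor_conc`,
#'   `replicate` (role `"dose"` rows are used; all rows if no role column).
#' @param config a [tric_config()].
#' @param qc apply the per-well QC detectors (default TRUE; baselines are
#'   referenced to the dose wells themselves).
#' @return A data frame: `well`, `concentration`, `fnorm`, `replicate`,
#'   `qc_pass`.
#' @export
build_dose_series <- function(traces, layout, config = tric_config(), qc = TRUE) {
  if (!is.null(layout$role)) layout <- layout[layout$role == "dose", ]
  sub <- new_trace_set(traces$time, traces$F[, layout$well, drop = FALSE],
                       layout$well, traces$schedule)
  fn <- compute_fnorm(sub, config$f0_window, config$f1_window)
  pass <- rep(TRUE, nrow(layout))
  if (qc && nrow(layout) >= 8) {
    qt <- qc_plate(sub, config)
    pass <- qt$qc_pass[match(layout$well, qt$well_id)]
  }
  data.frame(well = layout$well, concentration = layout$competitor_conc,
             fnorm = fn$fnorm[match(layout$well, fn$well_id)],
             replicate = layout$replicate, qc_pass = pass,
             stringsAsFactors = FALSE)
}

logistic4_predict <- function(pars, lconc) {
  pars[["r0"]] + (pars[["rinf"]] - pars[["r0"]]) /
    (1 + 10^((pars[["lec50"]] - lconc) * pars[["hill"]]))
}

fit_logistic4 <- function(conc, y) {
  lconc <- log10(conc)
  ord <- order(lconc)
  lo_mean <- mean(y[ord][seq_len(min(2, length(y)))])
  hi_mean <- mean(rev(y[ord])[seq_len(min(2, length(y)))])
  mid <- (lo_mean + hi_mean) / 2
  lec50_init <- lconc[which.min(abs(y - mid))]
  start <- list(r0 = lo_mean, rinf = hi_mean, lec50 = lec50_init, hill = 1)
  fit <- minpack.lm::nlsLM(
    y ~ r0 + (rinf - r0) / (1 + 10^((lec50 - lconc) * hill)),
    start = start,
    data = data.frame(y = y, lconc = lconc),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- stats::coef(fit)
  list(pars = p, nls = fit,
       predict = function(conc) logistic4_predict(as.list(p), log10(conc)),
       residuals = stats::resid(fit),
       ec50 = 10^p[["lec50"]], hill = p[["hill"]],
       bottom = unname(p[["r0"]]), top = unname(p[["rinf"]]),
       converged = fit$convInfo$isConv %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hat-matrix diagonal of a fitted nls model, from its gradient matrix.
leverage_of <- function(fit, n) {
  J <- tryCatch(fit$nls$m$gradient(), error = function(e) NULL)
  if (is.null(J) || nrow(J) != n) return(rep(0, n))
  h <- tryCatch({
    q <- qr.Q(qr(J))
    rowSums(q^2)
  }, error = function(e) rep(0, n))
  pmin(h, 0.99)
}

fit_competitive_exact <- function(conc, y, assay, ki_init) {
  # fnorm is affine in the tracer bound fraction: y = a + b * bf(conc; ki)
  bf_fun <- function(conc, lki) {
    sys <- competitive_system(assay$receptor_total, assay$tracer_total,
                              assay$kd_tracer, 1, 10^lki)
    bound_fraction_curve(sys, conc)
  }
  lki_init <- log10(ki_init)
  bf0 <- bf_fun(conc, lki_init)
  ab <- stats::coef(stats::lm(y ~ bf0))
  fit <- minpack.lm::nlsLM(
    y ~ a + b * bf_fun(conc, lki),
    start = list(a = unname(ab[1]), b = unname(ab[2]), lki = lki_init),
    data = data.frame(y = y, conc = conc),
    lower = c(-Inf, -Inf, -15), upper = c(Inf, Inf, 3),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- stats::coef(fit)
  bf_max <- solve_binary(assay)$tracer_bound_fraction
  list(pars = p, nls = fit,
       predict = function(conc) p[["a"]] + p[["b"]] * bf_fun(conc, p[["lki"]]),
       residuals = stats::resid(fit),
       ki = 10^p[["lki"]],
       # plateaus: zero competitor (bf = binary) vs full displacement (bf = 0)
       bottom = unname(p[["a"]] + p[["b"]] * bf_max), top = unname(p[["a"]]),
       converged = fit$convInfo$isConv %||% TRUE)
}

#' Fit a displacement dose-response series
#'
#' Fits a 12-point displacement titration and reports EC50, K_i and the
#' signal-to-noise ratio. Two models are available:
#'
#' * `"competitive_exact"` (default): least-squares fit of
#'   `fnorm = a + b * bound_fraction(conc; K_i)` with the exact competitive
#'   equilibrium as the forward model; K_i is a fit parameter, so no
#'   low-depletion approximation enters.
#' * `"logistic4"`: four-parameter logistic on log10 concentration (top,
#'   bottom, EC50, Hill slope); K_i attached via [ec50_to_ki()].
#'
#' Outliers are excluded iteratively (see [detect_outliers()]), at most
#' `max_exclude` points. Series whose fitted amplitude does not exceed
#' `no_displacement_k` times the residual noise are reported as
#' "no displacement detected" with a one-sided censored affinity
#' (K_i > top concentration) rather than a meaningless point estimate. Both
#' EC50 and K_i are always reported together with the conversion mode used.
#'
#' @param series data frame with `concentration` (M), `fnorm`, optionally
#'   `qc_pass` (flagged points are dropped first) and `replicate`.
#' @param assay the assay [binary_system()].
#' @param model `"competitive_exact"` or `"logistic4"`.
#' @param config a [tric_config()] (not used by the fit itself; reserved).
#' @param ki_mode EC50-to-K_i conversion for the logistic model:
#'   `"exact"` (default) or `"cheng_prusoff"`.
#' @param exclude_outliers iteratively drop studentized-residual outliers.
#' @param max_exclude cap on excluded points (default 2).
#' @param no_displacement_k amplitude must exceed this multiple of the
#'   residual SD to count as displacement (default 4).
#' @return An object of class `dose_response_fit`: a list with `peptide_id`,
#'   `model`, `ec50`, `hill`, `top`, `bottom`, `ki`, `ki_censored`,
#'   `ki_mode`, `s_n`, `excluded` (data frame), `verdict`
#'   (`"ok"`, `"no_displacement"` or `"unfittable"`), `n_points`, `residual_sd`.
#' @export
fit_dose_response <- function(series, assay,
                              model = c("competitive_exact", "logistic4"),
                              config = tric_config(),
                              ki_mode = c("exact", "cheng_prusoff"),
                              exclude_outliers = TRUE, max_exclude = 2,
                              no_displacement_k = 4) {
  model <- match.arg(model)
  ki_mode <- match.arg(ki_mode)
  stopifnot(is.data.frame(series), all(c("concentration", "fnorm") %in% names(series)))
  if (any(series$concentration <= 0)) stop_invalid("concentrations must be positive")
  keep <- if (!is.null(series$qc_pass)) series$qc_pass else rep(TRUE, nrow(series))
  dat <- series[keep & is.finite(series$fnorm), , drop = FALSE]
  span <- if (nrow(dat) > 0) diff(range(log10(dat$concentration))) else 0
  res <- list(peptide_id = attr(series, "peptide_id") %||% series$peptide_id[1] %||% NA,
              model = model, ki_mode = ki_mode,
              top_conc = max(series$concentration))
  if (nrow(dat) < 8 || span < 2) {
    res$verdict <- "unfittable"
    res$reason <- sprintf("%d usable points spanning %.2f log units (need >= 8 over >= 2)",
                          nrow(dat), span)
    res$ec50 <- res$ki <- res$s_n <- NA_real_
    res$ki_censored <- FALSE
    res$excluded <- data.frame(index = integer(0), residual = numeric(0))
    class(res) <- "dose_response_fit"
    return(res)
  }

  fit_fun <- function(d) {
    if (model == "logistic4") {
      fit_logistic4(d$concentration, d$fnorm)
    } else {
      # initial ki: crude Cheng-Prusoff from the mid-response concentration
      mid <- (max(d$fnorm) + min(d$fnorm)) / 2
      ec50_guess <- d$concentration[which.min(abs(d$fnorm - mid))]
      ki_init <- ec50_guess / (1 + assay$tracer_total / assay$kd_tracer)
      fit_competitive_exact(d$concentration, d$fnorm, assay, ki_init)
    }
  }

  excluded <- data.frame(index = integer(0), residual = numeric(0),
                         studentized = numeric(0))
  if (exclude_outliers) {
    det <- detect_outliers(dat, fit_fun, max_exclude = max_exclude)
    excluded <- det$excluded
    fit <- det$fit
    if (nrow(excluded) > 0) dat <- dat[-excluded$index, , drop = FALSE]
  } else {
    fit <- fit_fun(dat)
  }

  rsd <- stats::sd(fit$residuals)
  # displacement actually observed across the measured series; the plateau
  # difference |top - bottom| can extrapolate absurdly when a flat series
  # sends the affinity parameter to a bound
  amplitude <- diff(range(fit$predict(dat$concentration)))
  res$top <- fit$top; res$bottom <- fit$bottom
  res$residual_sd <- rsd
  res$n_points <- nrow(dat)
  res$excluded <- excluded
  res$converged <- fit$converged

  if (!is.finite(amplitude) || amplitude < no_displacement_k * rsd) {
    res$verdict <- "no_displacement"
    res$ki <- max(series$concentration)   # one-sided bound: ki > top
    res$ki_censored <- TRUE
    res$ec50 <- NA_real_
    res$s_n <- amplitude / rsd
    res$hill <- NA_real_
    class(res) <- "dose_response_fit"
    return(res)
  }

  res$verdict <- "ok"
  res$s_n <- amplitude / rsd
  res$ki_censored <- FALSE
  if (model == "logistic4") {
    res$ec50 <- fit$ec50
    res$hill <- fit$hill
    res$ki <- tryCatch(ec50_to_ki(fit$ec50, assay, mode = ki_mode),
                       error = function(e) NA_real_)
  } else {
    res$ki <- fit$ki
    res$hill <- NA_real_
    res$ec50 <- tryCatch(ic50_exact(assay, fit$ki), error = function(e) NA_real_)
  }
  class(res) <- "dose_response_fit"
  res
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit %s: %s", x$model, x$verdict))
  if (x$verdict == "ok") {
    cat(sprintf(", Ki = %.4g M, EC50 = %.4g M, S/N = %.1f", x$ki, x$ec50, x$s_n))
  } else if (identical(x$verdict, "no_displacement")) {
    cat(sprintf(", Ki > %.3g M", x$ki))
  }
  cat(">\n")
  invisible(x)
}

#' Iterative studentized-residual outlier exclusion
#'
#' Fits the series and removes, one at a time and up to `max_exclude`
#' points, the single worst point that is an outlier by a dual criterion:
#'
#' * statistically outlying - its externally studentized residual exceeds
#'   `threshold` (default 3.0): `|r_i| / sqrt(s_(-i)^2 (1 - h_i))`, with
#'   leverage `h_i` from the fit's Jacobian and the variance `s_(-i)^2`
#'   estimated with point i's (leverage-corrected) contribution removed
#'   from the SSE, so a candidate does not inflate its own yardstick; and
#' * practically significant - its residual exceeds `min_effect` (default
#'   8%) of the fitted response amplitude, so points whose deviation is
#'   irrelevant at the scale of the signal are never discarded merely for
#'   being statistically conspicuous. With a dozen points a bare 3-sigma
#'   rule would flag some point in a sizeable fraction of perfectly clean
#'   series; the amplitude floor removes that failure mode while leaving
#'   genuine gross outliers (10 sigma at realistic noise) untouched.
#'
#' Exclusions are logged with their residuals; the series is refit after
#' each exclusion.
#'
#' @param dat data frame with `concentration` and `fnorm`.
#' @param fit_fun function taking such a data frame and returning a fit list
#'   with `residuals`, `predict` and plateau (`top`, `bottom`) elements.
#' @param threshold studentized-residual threshold (default 3.0).
#' @param max_exclude maximum number of exclusions (default 2).
#' @param min_effect minimum residual magnitude as a fraction of the fitted
#'   amplitude (default 0.08).
#' @return A list: `fit` (final fit), `excluded` (data frame of original
#'   row indices, residuals and studentized residuals).
#' @export
detect_outliers <- function(dat, fit_fun, threshold = 3, max_exclude = 2,
                            min_effect = 0.08) {
  orig_idx <- seq_len(nrow(dat))
  excluded <- data.frame(index = integer(0), residual = numeric(0),
                         studentized = numeric(0))
  repeat {
    fit <- fit_fun(dat)
    if (nrow(excluded) >= max_exclude) {
      return(list(fit = fit, excluded = excluded))
    }
    n <- nrow(dat)
    r <- as.numeric(fit$residuals)
    # standard externally studentized residuals for a nonlinear fit:
    # leverage from the Jacobian (gradient) at convergence, per-point scale
    # from the deletion SSE so a candidate never inflates its own yardstick
    h <- leverage_of(fit, n)
    p_n <- length(fit$pars)
    sse <- sum(r^2)
    df_del <- n - p_n - 1L
    stud <- vapply(seq_len(n), function(i) {
      ri2 <- r[i]^2 / (1 - h[i])
      s2 <- (sse - ri2) / df_del
      if (!is.finite(s2) || s2 <= 0) return(0)
      abs(r[i]) / sqrt(s2 * (1 - h[i]))
    }, numeric(1))
    amp <- abs((fit$top %||% 0) - (fit$bottom %||% 0))
    resid_i <- r
    # floor compares the deletion residual r/(1-h) - the estimated true
    # displacement of the point - against the response amplitude
    candidate <- stud > threshold & abs(r) / (1 - h) > min_effect * amp
    if (!any(candidate)) {
      return(list(fit = fit, excluded = excluded))
    }
    worst <- which.max(ifelse(candidate, stud, -Inf))
    excluded <- rbind(excluded, data.frame(
      index = orig_idx[worst], residual = resid_i[worst],
      studentized = stud[worst]))
    dat <- dat[-worst, , drop = FALSE]
    orig_idx <- orig_idx[-worst]
  }
}

#' Summarize replicate affinity determinations
#'
#' Replicate K_i values are summarized on the linear scale (mean, SD,
#' median, quartiles with linear interpolation, whiskers within 1.5 IQR of
#' the quartiles, and points beyond as outliers), with the geometric mean as
#' a companion since affinities are log-normally distributed in general.
#'
#' @param x numeric vector of K_i values (M), or a list of
#'   `dose_response_fit` objects (censored / unfittable fits are dropped).
#' @return A list of class `replicate_summary`: `n`, `mean`, `sd`, `median`,
#'   `q25`, `q75`, `whisker_lo`, `whisker_hi`, `outliers`, `geometric_mean`.
#' @examples
#' summarize_replicates(c(10, 11, 12, 13, 14) * 1e-6)
#' @export
summarize_replicates <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- vapply(x, function(f) {
      if (inherits(f, "dose_response_fit") &&
          identical(f$verdict, "ok") && !isTRUE(f$ki_censored)) f$ki else NA_real_
    }, numeric(1))
  }
  x <- x[is.finite(x)]
  if (length(x) == 0) stop_invalid("no finite values to summarize")
  if (length(x) == 1) {
    out <- list(n = 1L, mean = x, sd = NA_real_, median = x, q25 = x, q75 = x,
                whisker_lo = x, whisker_hi = x, outliers = numeric(0),
                geometric_mean = x)
    class(out) <- "replicate_summary"
    return(out)
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  out <- list(n = length(x), mean = mean(x), sd = stats::sd(x),
              median = q[2], q25 = q[1], q75 = q[3],
              whisker_lo = min(inside), whisker_hi = max(inside),
              outliers = x[x < lo_fence | x > hi_fence],
              geometric_mean = exp(mean(log(x))))
  class(out) <- "replicate_summary"
  out
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.4g +/- %.3g, median = %.4g [%.4g, %.4g], geo mean = %.4g\n",
              x$n, x$mean, x$sd, x$median, x$q25, x$q75, x$geometric_mean))
  if (length(x$outliers)) {
    cat("outliers beyond 1.5 IQR:", paste(signif(x$outliers, 4), collapse = ", "), "\n")
  }
  invisible(x)
}
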