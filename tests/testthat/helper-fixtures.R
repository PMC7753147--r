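# Shared fixtures: the benchmark gephyrin-E displacement assay (tracer
# K_D 1.54 nM, 2 nM tracer, 5 nM receptor) and quiet/noisy photophysics.

bench_assay <- function() binary_system(5e-9, 2e-9, 1.54e-9)

quiet_photo <- function(...) tric_photophysics(noise_cv = 0, ...)

BENCH_KI <- 12.1e-6
BENCH_TOP <- 400e-6

random_system <- function() {
  p <- 10^stats::runif(5, -12, -3)
  competitive_system(p[1], p[2], p[3], p[4], p[5])
}

# small screen library: n_binders binders at ki_binder, rest non-binders
screen_library <- function(n = 220, n_binders = 10, ki_binder = 5e-6) {
  data.frame(
    peptide_id = sprintf("pep%03d", seq_len(n)),
    ki = c(rep(Inf, n - n_binders), rep(ki_binder, n_binders))
  )
}
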