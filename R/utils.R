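#' Convert a concentration to molar units
#'
#' Assay files and configs quote concentrations in whatever unit is handy
#' (the benchmark system mixes nM tracer and uM peptide stocks); everything
#' inside the package is molar. `as_molar()` converts a number with an
#' explicit unit tag, and `parse_conc()` parses strings such as `"1.54 nM"`.
#'
#' @param x numeric value(s).
#' @param unit one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"` (also accepts
#'   `"µM"`).
#' @return numeric concentration(s) in molar.
#' @examples
#' as_molar(1.54, "nM")
#' parse_conc("12.1 uM")
#' @export
as_molar <- function(x, unit) {
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  unit <- sub("µ", "u", unit)
  if (!all(unit %in% names(scale))) {
    stop("unknown concentration unit: ", paste(setdiff(unit, names(scale)), collapse = ", "),
         call. = FALSE)
  }
  x * unname(scale[unit])
}

#' @rdname as_molar
#' @param s character vector like `"1.54 nM"` or `"100uM"`.
#' @export
parse_conc <- function(s) {
  m <- regmatches(s, regexec("^\\s*([-0-9.eE+]+)\\s*([a-zA-Zµ]+)\\s*$", s))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("cannot parse concentration string(s): ", paste(s[bad], collapse = ", "),
         call. = FALSE)
  }
  vapply(m, function(p) as_molar(as.numeric(p[2]), p[3]), numeric(1))
}

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
# seed = NULL runs with the ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed, staying inside 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) %% 2011L
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("tricscreen_invalid", "tricscreen_error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("tricscreen_numeric", "tricscreen_error")))
}

check_scalar <- function(x, name, positive = TRUE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  if (positive && x <= 0) stop_invalid("`", name, "` must be strictly positive")
  if (nonneg && x < 0) stop_invalid("`", name, "` must be non-negative")
  invisible(x)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n])) / 2
}

#' Benchmark peptide sequences
#'
#' Peptide sequences of the gephyrin / glycine-receptor benchmark system used
#' throughout the examples and the simulator defaults: the GlyR beta-derived
#' 15-mer (loop residues 414-428), the mutation-sensitive GlyR beta core motif
#' FSIVG (420-424), the GABA-A receptor alpha-3 motif FNIVG (395-399), and the
#' two neutralization peptides.
#'
#' @format A named list of character strings with residue coordinates in
#'   attributes `first_residue`.
#' @export
tric_sequences <- local({
  wt <- "DLRSNDFSIVGSLPR"
  attr(wt, "first_residue") <- 414L
  glyrb <- "FSIVG"
  attr(glyrb, "first_residue") <- 420L
  gabaa3 <- "FNIVG"
  attr(gabaa3, "first_residue") <- 395L
  list(
    glyrb_414_428       = wt,
    motif_glyrb         = glyrb,
    motif_gabaa3        = gabaa3,
    neutralizer_glyrb   = "FSIVGSLPRDFELC",
    neutralizer_gabaa3  = "FNIVGTTY"
  )
})

#' The 20 proteinogenic amino acids (one-letter codes)
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
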