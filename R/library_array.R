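#' Build an overlapping (tiling) peptide library
#'
#' Tiles a parent sequence with fixed-length windows stepped by `offset`
#' (default 15-mers, offset 1), the standard design for locating linear
#' binding sites. Residue coordinates are 1-based inclusive in the parent's
#' own numbering (set `first_residue` to match a construct's numbering, e.g.
#' 414 for the GlyR beta loop peptide).
#'
#' @param parent parent amino-acid sequence (single-letter codes).
#' @param parent_id identifier recorded for every entry.
#' @param length window length (default 15).
#' @param offset step between window starts (default 1).
#' @param first_residue residue number of the first parent position.
#' @return A `peptide_library` data frame: `peptide_id`, `sequence`,
#'   `parent_id`, `start`, `end`, `sub_pos`, `sub_res`, `is_wt`.
#' @examples
#' make_overlapping_library("DLRSNDFSIVGSLPRDFELC", length = 15)
#' @export
make_overlapping_library <- function(parent, parent_id = "parent",
                                     length = 15, offset = 1,
                                     first_residue = 1) {
  parent <- validate_sequence(parent, "parent")
  L <- nchar(parent)
  if (L < length) stop_invalid("parent (", L, " aa) shorter than window (", length, ")")
  starts <- seq(1, L - length + 1, by = offset)
  seqs <- substring(parent, starts, starts + length - 1)
  out <- data.frame(
    peptide_id = sprintf("%s_%d_%d", parent_id,
                         first_residue + starts - 1,
                         first_residue + starts + length - 2),
    sequence = seqs, parent_id = parent_id,
    start = first_residue + starts - 1L,
    end = first_residue + starts + length - 2L,
    sub_pos = NA_integer_, sub_res = NA_character_, is_wt = FALSE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("peptide_library", "data.frame")
  out
}

validate_sequence <- function(s, what) {
  if (!is.character(s) || length(s) != 1L || nchar(s) == 0) {
    stop_invalid("`", what, "` must be a single non-empty string")
  }
  s <- toupper(s)
  bad <- setdiff(strsplit(s, "")[[1]], AA_ALPHABET)
  if (length(bad)) {
    stop_invalid("invalid residue code(s) in ", what, ": ",
                 paste(unique(bad), collapse = ", "))
  }
  s
}

#' Build a positional-scan (substitution) library
#'
#' Systematically interchanges each selected position of a parent peptide
#' with every residue of the alphabet, yielding one variant per (position,
#' residue) pair; entries identical to the parent are kept and marked
#' `is_wt`, since WT-replicate spots are the normalization anchor of a scan.
#' A full scan of a 15-mer gives 15 x 20 = 300 entries.
#'
#' @param parent parent peptide sequence.
#' @param positions residue coordinates to scan (in the parent's numbering;
#'   default all positions).
#' @param alphabet substitution alphabet (default the 20 proteinogenic
#'   residues).
#' @param parent_id identifier.
#' @param first_residue residue number of the parent's first position.
#' @return A `peptide_library` data frame (see
#'   [make_overlapping_library()]); `sub_pos`/`sub_res` record the
#'   substitution.
#' @examples
#' # scan of the GlyR beta core motif positions 420-424
#' lib <- make_positional_scan(tric_sequences$glyrb_414_428,
#'                             positions = 420:424, first_residue = 414)
#' nrow(lib)  # 100
#' @export
make_positional_scan <- function(parent, positions = NULL,
                                 alphabet = AA_ALPHABET,
                                 parent_id = "parent", first_residue = 1) {
  parent <- validate_sequence(parent, "parent")
  alphabet <- toupper(alphabet)
  bad <- setdiff(alphabet, AA_ALPHABET)
  if (length(bad)) stop_invalid("invalid residue code(s) in alphabet: ",
                                paste(bad, collapse = ", "))
  L <- nchar(parent)
  if (is.null(positions)) positions <- seq(first_residue, first_residue + L - 1)
  idx <- positions - first_residue + 1L
  if (any(idx < 1 | idx > L)) {
    stop_invalid("positions outside parent range [", first_residue, ", ",
                 first_residue + L - 1, "]")
  }
  grid <- expand.grid(res = alphabet, pos = positions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$pos), c("pos", "res")]
  i <- grid$pos - first_residue + 1L
  seqs <- vapply(seq_len(nrow(grid)), function(k) {
    s <- strsplit(parent, "")[[1]]
    s[i[k]] <- grid$res[k]
    paste(s, collapse = "")
  }, character(1))
  wt_res <- substring(parent, i, i)
  out <- data.frame(
    peptide_id = sprintf("%s_p%d%s", parent_id, grid$pos, grid$res),
    sequence = seqs, parent_id = parent_id,
    start = first_residue, end = first_residue + L - 1L,
    sub_pos = as.integer(grid$pos), sub_res = grid$res,
    is_wt = grid$res == wt_res,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("peptide_library", "data.frame")
  out
}

#' Attach ground-truth affinities to a positional-scan library
#'
#' Synthetic truth model for end-to-end validation: each (position, residue)
#' substitution multiplies the parent K_i by a log-uniform penalty factor.
#' Positions inside the binding motif carry large penalties (strong affinity
#' loss on substitution, the signature of a conserved core such as FSIVG);
#' positions outside carry small ones. Optionally a fraction of motif
#' substitutions abolish binding altogether (`ki = Inf`). WT-identical
#' entries keep the parent affinity exactly.
#'
#' @param library a positional-scan `peptide_library`.
#' @param wt_ki parent K_i (M); default the benchmark 12.1 uM.
#' @param motif_positions residue coordinates of the binding motif.
#' @param motif_penalty_log10,other_penalty_log10 ranges (log10 units) of
#'   the multiplicative K_i penalties.
#' @param nonbinder_fraction fraction of motif substitutions made complete
#'   non-binders (default 0).
#' @param seed integer seed.
#' @return The library with a `ki` column (M).
#' @export
simulate_scan_truth <- function(library, wt_ki = 12.1e-6,
                                motif_positions = 420:424,
                                motif_penalty_log10 = c(0.5, 1.2),
                                other_penalty_log10 = c(-0.2, 0.3),
                                nonbinder_fraction = 0, seed = NULL) {
  stopifnot(is.data.frame(library), !is.null(library$sub_pos))
  n <- nrow(library)
  with_seed(seed, {
    in_motif <- library$sub_pos %in% motif_positions
    pen <- ifelse(in_motif,
                  stats::runif(n, motif_penalty_log10[1], motif_penalty_log10[2]),
                  stats::runif(n, other_penalty_log10[1], other_penalty_log10[2]))
    pen[library$is_wt] <- 0
    ki <- wt_ki * 10^pen
    if (nonbinder_fraction > 0) {
      cand <- which(in_motif & !library$is_wt)
      kill <- cand[stats::runif(length(cand)) < nonbinder_fraction]
      ki[kill] <- Inf
    }
    library$ki <- ki
    library
  })
}

#' Simulate microarray spot intensities from binding ground truth
#'
#' Generates replicate arrays whose spot intensities follow receptor
#' occupancy of the immobilized peptides at the probing concentration,
#' `occ = probe / (probe + ki)`, scaled to an arbitrary intensity unit, with
#' multiplicative log-normal spot noise and negative-control spots. This is
#' a synthetic stand-in for scanned array data; it models relative
#' intensities only.
#'
#' @param library a `peptide_library` with a `ki` column (Inf = non-binder).
#' @param probe_conc probing protein concentration (M); default 50 nM.
#' @param n_arrays number of replicate arrays (default 3).
#' @param scale intensity of a fully occupied spot (a.u.).
#' @param background additive background intensity (a.u.).
#' @param noise_cv log-normal spot noise CV (0 = noiseless).
#' @param n_neg negative-control spots per array (peptide_id `"NEG"`).
#' @param seed integer seed.
#' @return Long data frame: `array_id`, `peptide_id`, `intensity`.
#' @export
simulate_array_intensities <- function(library, probe_conc = 50e-9,
                                       n_arrays = 3, scale = 2e5,
                                       background = 100, noise_cv = 0.1,
                                       n_neg = 8, seed = NULL) {
  stopifnot(is.data.frame(library), !is.null(library$ki))
  occ <- ifelse(is.finite(library$ki),
                probe_conc / (probe_conc + library$ki), 0)
  with_seed(seed, {
    rows <- list()
    for (a in seq_len(n_arrays)) {
      mu <- c(scale * occ + background, rep(background, n_neg))
      ids <- c(library$peptide_id, rep("NEG", n_neg))
      noise <- if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
      } else rep(1, length(mu))
      rows[[a]] <- data.frame(array_id = sprintf("array%02d", a),
                              peptide_id = ids, intensity = mu * noise,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' WT-normalized positional-scan matrix
#'
#' Converts replicate spot-intensity tables into the standard positional-
#' scan heatmap: per array, the negative-control mean is subtracted
#' (floored at zero), intensities are divided by that array's mean WT spot
#' intensity, and cells are averaged across arrays. WT-residue cells equal 1
#' up to replicate noise by construction.
#'
#' @param spots long data frame: `array_id`, `peptide_id`, `intensity`.
#' @param library positional-scan `peptide_library` mapping peptide ids to
#'   (position, residue); entries with `is_wt` define the normalizer.
#' @param background `"negctrl"` (default) or `"none"`.
#' @param neg_id peptide_id of negative-control spots.
#' @return An object of class `positional_scan_matrix`: list with `parent_id`,
#'   `positions`, `residues`, matrices `mean`, `sd`, `n` (residues x
#'   positions), and `n_arrays`.
#' @export
normalize_to_wt <- function(spots, library, background = c("negctrl", "none"),
                            neg_id = "NEG") {
  background <- match.arg(background)
  stopifnot(is.data.frame(spots),
            all(c("array_id", "peptide_id", "intensity") %in% names(spots)))
  wt_ids <- library$peptide_id[library$is_wt]
  if (length(wt_ids) == 0) stop_invalid("library has no WT-marked entries")
  arrays <- unique(spots$array_id)
  norm <- list()
  for (a in arrays) {
    sa <- spots[spots$array_id == a & spots$peptide_id != neg_id, ]
    v <- sa$intensity
    if (background == "negctrl") {
      neg <- spots$intensity[spots$array_id == a & spots$peptide_id == neg_id]
      if (length(neg)) v <- pmax(v - mean(neg), 0)
    }
    wt_mean <- mean(v[sa$peptide_id %in% wt_ids])
    if (!is.finite(wt_mean) || wt_mean <= 0) {
      warning("array ", a, " has no usable WT spots; excluded")
      next
    }
    norm[[a]] <- data.frame(array_id = a, peptide_id = sa$peptide_id,
                            rel = v / wt_mean, stringsAsFactors = FALSE)
  }
  if (length(norm) == 0) stop_invalid("no array with usable WT spots")
  norm <- do.call(rbind, norm)
  norm <- merge(norm, library[, c("peptide_id", "sub_pos", "sub_res")],
                by = "peptide_id")
  positions <- sort(unique(library$sub_pos))
  residues <- unique(library$sub_res)
  residues <- AA_ALPHABET[AA_ALPHABET %in% residues]
  mk <- function(f) {
    m <- matrix(NA_real_, length(residues), length(positions),
                dimnames = list(residues, positions))
    agg <- stats::aggregate(rel ~ sub_res + sub_pos, norm, f)
    m[cbind(match(agg$sub_res, residues), match(as.character(agg$sub_pos),
                                                colnames(m)))] <- agg$rel
    m
  }
  out <- list(parent_id = library$parent_id[1], positions = positions,
              residues = residues,
              mean = mk(mean),
              sd = mk(function(v) if (length(v) > 1) stats::sd(v) else 0),
              n = mk(length),
              n_arrays = length(unique(norm$array_id)))
  class(out) <- "positional_scan_matrix"
  out
}

#' @export
print.positional_scan_matrix <- function(x, ...) {
  cat(sprintf("<positional_scan_matrix: %d residues x %d positions, %d arrays>\n",
              length(x$residues), length(x$positions), x$n_arrays))
  invisible(x)
}

#' @export
as.data.frame.positional_scan_matrix <- function(x, ...) {
  grid <- expand.grid(sub_res = x$residues, sub_pos = x$positions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rel_intensity <- as.vector(x$mean)
  grid$sd <- as.vector(x$sd)
  grid$n <- as.vector(x$n)
  grid
}

#' Correlate array intensities with TRIC affinities
#'
#' Spearman rank correlation between relative microarray intensity and TRIC
#' affinity (as -log10 K_i) over paired peptides. Censored affinities
#' (non-binders reported as K_i above the top titration concentration)
#' cannot be ranked among finite values; per policy they are either tied
#' jointly below every finite-affinity peptide (`"rank_lowest"`, default) or
#' dropped (`"exclude"`).
#'
#' @param pairs data frame with `peptide_id`, `intensity` (relative array
#'   intensity) and `ki` (M), plus logical `censored` (optional; default all
#'   finite).
#' @param policy `"rank_lowest"` or `"exclude"`.
#' @return A list of class `array_tric_comparison`: `rho`, `n`, `policy`,
#'   `pairs`.
#' @export
correlate_array_tric <- function(pairs, policy = c("rank_lowest", "exclude")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(pairs),
            all(c("peptide_id", "intensity", "ki") %in% names(pairs)))
  if (is.null(pairs$censored)) pairs$censored <- !is.finite(pairs$ki)
  pairs$censored <- pairs$censored | !is.finite(pairs$ki)
  if (policy == "exclude") pairs <- pairs[!pairs$censored, , drop = FALSE]
  if (nrow(pairs) < 3) stop_invalid("need >= 3 paired records, got ", nrow(pairs))
  affinity <- ifelse(pairs$censored, -Inf, -log10(pairs$ki))
  rho <- stats::cor(rank(pairs$intensity), rank(affinity))
  out <- list(rho = rho, n = nrow(pairs), policy = policy, pairs = pairs)
  class(out) <- "array_tric_comparison"
  out
}

#' @export
print.array_tric_comparison <- function(x, ...) {
  cat(sprintf("Array vs TRIC rank correlation: rho = %.3f over %d pairs (censored policy: %s)\n",
              x$rho, x$n, x$policy))
  invisible(x)
}

#' Pair a scan matrix with dose-response fits
#'
#' Builds the paired table for [correlate_array_tric()] from a
#' WT-normalized scan matrix and a list of per-variant dose-response fits.
#'
#' @param matrix a `positional_scan_matrix`.
#' @param fits named list of `dose_response_fit` objects (names = peptide
#'   ids) or a data frame with `peptide_id`, `ki`, `ki_censored`.
#' @param library the scan `peptide_library` (maps ids to cells).
#' @return Data frame consumable by [correlate_array_tric()].
#' @export
pair_scan_with_fits <- function(matrix, fits, library) {
  md <- as.data.frame(matrix)
  lib <- merge(library, md, by = c("sub_pos", "sub_res"))
  if (is.data.frame(fits)) {
    fd <- fits
  } else {
    fd <- data.frame(
      peptide_id = names(fits),
      ki = vapply(fits, function(f) f$ki %||% NA_real_, numeric(1)),
      ki_censored = vapply(fits, function(f) isTRUE(f$ki_censored), logical(1)),
      stringsAsFactors = FALSE)
  }
  m <- merge(lib[, c("peptide_id", "rel_intensity")], fd, by = "peptide_id")
  data.frame(peptide_id = m$peptide_id, intensity = m$rel_intensity,
             ki = m$ki, censored = m$ki_censored, stringsAsFactors = FALSE)
}
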