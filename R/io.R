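#' Read TRIC traces from a long-format CSV
#'
#' Expects columns `well_id`, `time_s`, `fluorescence` (and optionally
#' `plate_id`, prepended to the well id as `plate:well`). Rows are validated
#' strictly: non-finite fluorescence and non-monotone time within a well are
#' rejected with the offending line numbers.
#'
#' @param path CSV file path.
#' @return A `trace_set`. All wells must share one time grid.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop_invalid("trace file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("well_id", "time_s", "fluorescence")
  if (!all(need %in% names(d))) {
    stop_invalid("trace CSV must have columns ", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(d$fluorescence) | d$fluorescence <= 0 |
                 !is.finite(d$time_s))
  if (length(bad)) {
    stop_invalid("malformed trace rows (non-finite or non-positive values) at line(s): ",
                 paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  well <- if (!is.null(d$plate_id)) paste(d$plate_id, d$well_id, sep = ":") else d$well_id
  wells <- unique(well)
  first <- well == wells[1]
  t0 <- d$time_s[first]
  F <- matrix(NA_real_, length(t0), length(wells))
  for (j in seq_along(wells)) {
    rows <- which(well == wells[j])
    tj <- d$time_s[rows]
    if (any(diff(tj) <= 0)) {
      stop_invalid("non-monotone time in well ", wells[j], " near line ",
                   rows[which(diff(tj) <= 0)[1] + 1L] + 1L)
    }
    if (length(tj) != length(t0) || !isTRUE(all.equal(tj, t0))) {
      stop_invalid("well ", wells[j], " is not on the shared time grid")
    }
    F[, j] <- d$fluorescence[rows]
  }
  new_trace_set(t0, F, wells, NULL)
}

#' Write a trace set to long-format CSV
#'
#' @param traces a `trace_set`.
#' @param path output path (written atomically via a temp file).
#' @param provenance optional named list written as `# key: value` header
#'   comments.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, provenance = NULL) {
  stopifnot(inherits(traces, "trace_set"))
  d <- data.frame(
    well_id = rep(traces$well_id, each = length(traces$time)),
    time_s = rep(traces$time, times = ncol(traces$F)),
    fluorescence = as.vector(traces$F)
  )
  write_with_header(d, path, provenance, sep = ",")
}

write_with_header <- function(d, path, provenance, sep = "\t") {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  on.exit(close(con), add = TRUE)
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  }
  utils::write.table(d, con, sep = sep, row.names = FALSE, quote = FALSE)
  close(con)
  on.exit()
  file.rename(tmp, path)
  invisible(path)
}

#' Read / write a plate layout CSV
#'
#' Layout rows map wells to peptides, roles and competitor concentrations.
#' Concentration columns carry an explicit unit: either a molar
#' `competitor_conc` column or a `competitor_conc_uM` / `_nM` variant, which
#' is converted on read. Well ids are validated against 384-well geometry
#' (A1..P24) and (plate, well) pairs must be unique.
#'
#' @param path CSV file path.
#' @return Layout data frame with molar `competitor_conc` and a `well`
#'   (`plate:well_id`) key column.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop_invalid("layout file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("plate_id", "well_id", "peptide_id", "role")
  if (!all(need %in% names(d))) {
    stop_invalid("layout CSV must have columns ", paste(need, collapse = ", "))
  }
  conc_col <- grep("^competitor_conc", names(d), value = TRUE)
  if (length(conc_col) != 1) {
    stop_invalid("layout needs exactly one competitor_conc[_unit] column")
  }
  unit <- sub("^competitor_conc_?", "", conc_col)
  d$competitor_conc <- if (nzchar(unit)) as_molar(d[[conc_col]], unit) else d[[conc_col]]
  valid <- well_ids_384(1:384)
  bad <- setdiff(unique(d$well_id), valid)
  if (length(bad)) {
    stop_invalid("invalid 384-well ids: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  d$well <- paste(d$plate_id, d$well_id, sep = ":")
  if (anyDuplicated(d$well)) {
    stop_invalid("duplicate (plate, well) pairs: ",
                 paste(utils::head(d$well[duplicated(d$well)], 5), collapse = ", "))
  }
  tst <- d[d$role == "test", ]
  for (p in unique(tst$plate_id)) {
    if (!any(d$role == "control" & d$plate_id == p)) {
      stop_invalid("plate ", p, " has test wells but no control well")
    }
  }
  if (is.null(d$replicate)) d$replicate <- 1L
  d
}

#' @rdname read_layout
#' @param layout layout data frame.
#' @param unit concentration unit used in the file (default `"uM"`).
#' @param provenance optional named list of header comments.
#' @export
write_layout <- function(layout, path, unit = "uM", provenance = NULL) {
  d <- layout[, intersect(c("plate_id", "well_id", "peptide_id", "role",
                            "replicate", "qc_flag"), names(layout))]
  d[[paste0("competitor_conc_", unit)]] <- layout$competitor_conc / as_molar(1, unit)
  write_with_header(d, path, provenance, sep = ",")
}

#' Read a peptide library (CSV or FASTA)
#'
#' CSV files use the schema written by [write_library()]
#' (`peptide_id, sequence, parent_id, start, end, sub_pos, sub_res, is_wt`);
#' window coordinates are checked against the sequence where a parent
#' sequence is supplied. FASTA files (requires the Biostrings package)
#' provide sequences only, with ids from the headers; lowercase sequences
#' are accepted and uppercased with a warning.
#'
#' @param path file path (`.fasta`/`.fa` for FASTA, else CSV).
#' @param parent optional parent sequence to validate window slices against.
#' @return A `peptide_library` data frame.
#' @export
read_library <- function(path, parent = NULL) {
  if (!file.exists(path)) stop_invalid("library file not found: ", path)
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop_invalid("reading FASTA libraries requires the Biostrings package")
    }
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
    if (any(seqs != toupper(seqs))) {
      warning("lowercase residues in FASTA uppercased")
      seqs <- toupper(seqs)
    }
    out <- data.frame(peptide_id = names(ss), sequence = unname(seqs),
                      parent_id = NA_character_, start = NA_integer_,
                      end = NA_integer_, sub_pos = NA_integer_,
                      sub_res = NA_character_, is_wt = FALSE,
                      stringsAsFactors = FALSE)
    class(out) <- c("peptide_library", "data.frame")
    return(out)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("peptide_id", "sequence")
  if (!all(need %in% names(d))) {
    stop_invalid("library CSV must have columns ", paste(need, collapse = ", "))
  }
  d$sequence <- toupper(d$sequence)
  for (i in seq_len(nrow(d))) validate_sequence(d$sequence[i], d$peptide_id[i])
  if (!is.null(parent) && !is.null(d$start) && !is.null(d$end)) {
    first_res <- min(d$start, na.rm = TRUE)
    for (i in which(is.finite(d$start) & is.na(d$sub_pos))) {
      sl <- substring(parent, d$start[i] - first_res + 1,
                      d$end[i] - first_res + 1)
      if (nzchar(sl) && sl != d$sequence[i]) {
        stop_invalid("window ", d$start[i], "-", d$end[i],
                     " of parent does not match sequence of ", d$peptide_id[i])
      }
    }
  }
  for (col in c("parent_id", "sub_res")) if (is.null(d[[col]])) d[[col]] <- NA_character_
  for (col in c("start", "end", "sub_pos")) if (is.null(d[[col]])) d[[col]] <- NA_integer_
  if (is.null(d$is_wt)) d$is_wt <- FALSE
  class(d) <- c("peptide_library", "data.frame")
  d
}

#' @rdname read_library
#' @param library a `peptide_library`.
#' @param provenance optional named list of header comments.
#' @export
write_library <- function(library, path, provenance = NULL) {
  cols <- c("peptide_id", "sequence", "parent_id", "start", "end",
            "sub_pos", "sub_res", "is_wt")
  extra <- intersect("ki", names(library))
  write_with_header(library[, c(cols, extra)], path, provenance, sep = ",")
}

#' Write screen results to TSV
#'
#' @param records screen records from [analyze_screen()].
#' @param path output TSV path.
#' @param provenance optional named list of header comments (config hash,
#'   seed, package version).
#' @export
write_screen_results <- function(records, path, provenance = NULL) {
  write_with_header(records, path, provenance, sep = "\t")
}

#' Write a QC report as JSON
#'
#' @param qc per-well QC table from [analyze_screen()] / [qc_plate()].
#' @param path output JSON path.
#' @param provenance optional named list stored under `$provenance`.
#' @export
write_qc_report <- function(qc, path, provenance = NULL) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(list(provenance = provenance, wells = qc), tmp,
                       auto_unbox = TRUE, digits = NA, na = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Write dose-response fit results to TSV
#'
#' @param fits list of `dose_response_fit` objects.
#' @param path output TSV path.
#' @param provenance optional named list of header comments.
#' @export
write_fit_results <- function(fits, path, provenance = NULL) {
  d <- do.call(rbind, lapply(fits, function(f) {
    data.frame(peptide_id = as.character(f$peptide_id %||% NA),
               model = f$model, verdict = f$verdict,
               ec50_M = f$ec50 %||% NA_real_, ki_M = f$ki %||% NA_real_,
               ki_censored = isTRUE(f$ki_censored),
               s_n = f$s_n %||% NA_real_,
               top = f$top %||% NA_real_, bottom = f$bottom %||% NA_real_,
               hill = f$hill %||% NA_real_,
               n_points = f$n_points %||% NA_integer_,
               n_excluded = nrow(f$excluded %||% data.frame()),
               stringsAsFactors = FALSE)
  }))
  write_with_header(d, path, provenance, sep = "\t")
}

#' Load and validate a run configuration
#'
#' Run configurations are YAML or JSON with unit-tagged concentrations
#' (strings like `"1.54 nM"`, converted to molar on load). Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return A named list with molar concentrations, merged over the package
#'   defaults, plus a `hash` attribute for provenance.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- default_run_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  conc_keys <- c("kd_tracer", "tracer_total", "receptor_total",
                 "screen_conc", "top_conc")
  for (k in names(raw)) {
    v <- raw[[k]]
    if (k %in% conc_keys && is.character(v)) v <- parse_conc(v)
    defaults[[k]] <- v
  }
  attr(defaults, "hash") <- rlang::hash(defaults)
  defaults
}

#' Default run configuration
#'
#' Working concentrations of receptor and tracer are not universal
#' constants; they are assay choices, exposed here (and in every config
#' file) rather than hard-coded. Defaults describe the benchmark gephyrin-E
#' assay: 1.54 nM tracer K_D, 2 nM tracer, 5 nM receptor.
#'
#' @return Named list of configuration defaults.
#' @export
default_run_config <- function() {
  list(
    kd_tracer = 1.54e-9,
    tracer_total = 2e-9,
    receptor_total = 5e-9,
    screen_conc = 100e-6,
    top_conc = 400e-6,
    n_dilution = 12,
    dilution_factor = 2,
    n_replicates = 2,
    area_threshold = 0.5,
    area_scale = 0.04,
    f0_window = c(-0.8, 0),
    f1_window = c(1.0, 1.4),
    noise_cv = 0.005,
    seed = 1
  )
}

config_to_objects <- function(cfg) {
  list(
    assay = binary_system(cfg$receptor_total, cfg$tracer_total, cfg$kd_tracer),
    config = tric_config(f0_window = cfg$f0_window, f1_window = cfg$f1_window,
                         area_scale = cfg$area_scale,
                         area_threshold = cfg$area_threshold),
    photo = tric_photophysics(noise_cv = cfg$noise_cv)
  )
}
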