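Package: tricscreen
Title: High-Throughput TRIC Displacement Screening and Affinity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for temperature-related intensity change (TRIC)
    displacement assays of unmodified peptide libraries in 384-well format:
    exact competitive-binding equilibria and EC50-to-Ki conversion, raw-trace
    processing into normalized fluorescence (Fnorm), quality-control artifact
    flagging, the area-between-traces single-dose screening statistic with
    binder classification, twelve-point dose-response fitting with outlier
    exclusion and replicate summaries, overlapping and positional-scan peptide
    library construction, microarray intensity normalization, and array-versus-
    TRIC affinity correlation. Includes a physics-based synthetic trace
    generator with known ground truth so every stage of the pipeline can be
    validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    rlang
Suggests:
    ggplot2,
    Biostrings,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
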