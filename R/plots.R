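# Figure exports. ggplot2 is suggested, not imported; each function errors
# cleanly when it is absent.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_invalid("plotting requires the ggplot2 package")
  }
}

#' Screen bar chart
#'
#' Area statistic per peptide in library order, hits highlighted — the
#' standard single-dose screen figure.
#'
#' @param records screen records from [analyze_screen()].
#' @return A ggplot object.
#' @export
plot_screen_areas <- function(records) {
  need_ggplot()
  d <- records[order(records$peptide_id), ]
  d$peptide_id <- factor(d$peptide_id, levels = d$peptide_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$peptide_id, y = .data$area,
                                  fill = .data$is_binder)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$area - .data$area_sd,
                                        ymax = .data$area + .data$area_sd),
                           width = 0.3, linewidth = 0.2, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "darkred", `FALSE` = "grey60"),
                               name = "binder") +
    ggplot2::labs(x = "peptide", y = "area statistic") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Dose-response curve plot
#'
#' Measured F_norm points (excluded outliers highlighted) with the fitted
#' displacement curve.
#'
#' @param fit a `dose_response_fit`.
#' @param series the fitted dose series (`concentration`, `fnorm`).
#' @param assay the assay [binary_system()] (used to redraw the fitted
#'   curve for the exact model).
#' @return A ggplot object.
#' @export
plot_dose_fit <- function(fit, series, assay) {
  need_ggplot()
  d <- series
  d$excluded <- seq_len(nrow(d)) %in% fit$excluded$index
  grid <- exp(seq(log(min(d$concentration)), log(max(d$concentration)),
                  length.out = 120))
  curve <- NULL
  if (identical(fit$verdict, "ok")) {
    pred <- if (fit$model == "competitive_exact") {
      sys <- competitive_system(assay$receptor_total, assay$tracer_total,
                                assay$kd_tracer, 1, fit$ki)
      fit$top + (fit$bottom - fit$top) *
        bound_fraction_curve(sys, grid) /
        solve_binary(assay)$tracer_bound_fraction
    } else {
      logistic4_predict(list(r0 = fit$bottom, rinf = fit$top,
                             lec50 = log10(fit$ec50), hill = fit$hill),
                        log10(grid))
    }
    curve <- data.frame(concentration = grid, fnorm = pred)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration, y = .data$fnorm)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$excluded)) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "competitor (M)", y = "Fnorm (per mille)") +
    ggplot2::theme_minimal()
  if (!is.null(curve)) p <- p + ggplot2::geom_line(data = curve, color = "darkred")
  p
}

#' Positional-scan heatmap
#'
#' WT-normalized relative binding intensity per (position, residue) cell.
#'
#' @param matrix a `positional_scan_matrix`.
#' @return A ggplot object.
#' @export
plot_scan_heatmap <- function(matrix) {
  need_ggplot()
  d <- as.data.frame(matrix)
  d$sub_pos <- factor(d$sub_pos)
  d$sub_res <- factor(d$sub_res, levels = rev(matrix$residues))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sub_pos, y = .data$sub_res,
                                  fill = .data$rel_intensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 name = "rel. intensity") +
    ggplot2::labs(x = "position", y = "substituted residue") +
    ggplot2::theme_minimal()
}
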