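# ggplot2 visualizations mirroring the study's figure types: per-gene
# expression boxplots, ranked significance, binary call heatmaps, lane QC.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplot of normalized counts for one probe by outcome group
#'
#' @param counts Normalized wide count tibble.
#' @param sheet Sample sheet.
#' @param probe Probe id.
#' @param tissue Tissue to display (default tumor).
#' @return A ggplot object.
#' @export
plot_probe_counts <- function(counts, sheet, probe, tissue = "tumor") {
  m <- counts_to_matrix(counts)
  if (!probe %in% rownames(m)) abort(sprintf("unknown probe: %s", probe))
  sub <- sheet[sheet$tissue == tissue, , drop = FALSE]
  df <- tibble::tibble(outcome = sub$outcome, count = m[probe, sub$sample])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$count + 1,
                                   fill = .data$outcome)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = probe, x = NULL, y = "normalized count + 1") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Ranked significance plot for an FDR table
#'
#' -log10 p-values by rank, colored by direction, with the significance
#' cutoff applied to the rounded q-values.
#'
#' @param object A `bcr_fdr` tibble.
#' @param q_cutoff Cutoff drawn through the table (default 0.075).
#' @param top Number of top-ranked probes to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bcr_fdr <- function(object, q_cutoff = 0.075, top = 25, ...) {
  df <- utils::head(dplyr::arrange(object, .data$rank), top)
  df$significant <- round_dec(df$q_value, 3) <= q_cutoff
  ggplot2::ggplot(df, ggplot2::aes(
      x = stats::reorder(.data$probe, -.data$rank),
      y = -log10(.data$p_value),
      fill = .data$direction, alpha = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 p",
                  title = sprintf("Top %d probes (q cutoff %.3f)", top, q_cutoff)) +
    ggplot2::theme_minimal()
}

#' Binary call heatmap for a panel
#'
#' Patients as columns, member probes as rows, tiles colored by call; the
#' layout of the published panel figure.
#'
#' @param object A `bcr_panel` from [build_panel()].
#' @param calls Optional wide call tibble (defaults to the calls stored in
#'   the panel's build).
#' @param outcome Optional tibble `patient`, `outcome` to order columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bcr_panel <- function(object, calls = NULL, outcome = NULL, ...) {
  df <- object$calls
  df$probe <- "panel"
  long <- df[, c("patient", "probe", "call")]
  if (!is.null(calls)) {
    extra <- tidyr::pivot_longer(calls, -"patient", names_to = "probe",
                                 values_to = "call")
    long <- dplyr::bind_rows(extra[extra$probe %in% object$members, ], long)
  }
  if (!is.null(outcome)) {
    ord <- outcome$patient[order(outcome$outcome != "BCR", outcome$patient)]
    long$patient <- factor(long$patient, levels = ord)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient, y = .data$probe,
                                     fill = .data$call)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(
      values = c(positive = "salmon", negative = "#6fc7c7"),
      na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Lane QC overview
#'
#' Spike linearity R squared per lane with the pass threshold.
#'
#' @param object A `bcr_lane_qc` tibble from [lane_qc()].
#' @param r2_min Threshold line (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bcr_lane_qc <- function(object, r2_min = 0.95, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
      x = seq_len(nrow(object)), y = .data$r_squared, color = .data$pass)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = r2_min, linetype = 2) +
    ggplot2::labs(x = "lane", y = expression(R^2),
                  title = "Positive-control spike linearity") +
    ggplot2::theme_minimal()
}
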