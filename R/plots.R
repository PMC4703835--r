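#' Plot carrier frequencies with confidence intervals
#'
#' @param summary A [carrier_frequency()] result tibble.
#' @return A ggplot: per-cancer-type carrier fractions with 95% Wilson
#'   intervals, faceted by gene set.
#' @export
plot_carrier_frequency <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$cancer_type,
                                                  -.data$fraction),
                               y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.25) +
    ggplot2::facet_wrap(~gene_set) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Cancer type", y = "Cases carrying a rare truncation") +
    ggplot2::theme_minimal()
}

#' Plot burden-test results
#'
#' @param burden A [run_burden()] result tibble.
#' @param fdr FDR line to draw (default 0.05).
#' @return A ggplot of -log10 q per gene, faceted by cohort.
#' @export
plot_burden <- function(burden, fdr = 0.05) {
  ggplot2::ggplot(burden,
                  ggplot2::aes(x = stats::reorder(.data$gene, .data$q),
                               y = -log10(pmax(.data$q, 1e-300)),
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = "dashed") +
    ggplot2::facet_wrap(~cohort, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = NULL, y = expression(-log[10]~q)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot tumour/normal VAF ratios of tested sites
#'
#' @param sites A [run_site_loh()] result tibble.
#' @return A ggplot of per-site VAF ratios coloured by significance, with
#'   reference lines at 1 (no LOH) and 2 (complete LOH at purity 1).
#' @export
plot_vaf_ratios <- function(sites) {
  df <- sites %>% filter(.data$prefilter_pass, !is.na(.data$vaf_ratio))
  ggplot2::ggplot(df,
                  ggplot2::aes(x = stats::reorder(paste(.data$gene,
                                                        .data$sample_id),
                                                  .data$vaf_ratio),
                               y = .data$vaf_ratio,
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(1, 2), linetype = c("dashed", "dotted")) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = NULL, y = "Tumour / normal VAF ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot hotspot regions along a protein
#'
#' @param events Event tibble (`position`, `significant`) for one protein.
#' @param regions Hotspot regions for that protein ([run_hotspot_scan()]
#'   rows).
#' @param L Protein length.
#' @return A ggplot showing events and shaded hotspot intervals.
#' @export
plot_hotspots <- function(events, regions, L) {
  p <- ggplot2::ggplot(events,
                       ggplot2::aes(x = .data$position, y = 0,
                                    colour = .data$significant)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "royalblue",
                                            `FALSE` = "indianred")) +
    ggplot2::xlim(1, L) +
    ggplot2::labs(x = "Amino-acid position", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -0.4, ymax = 0.4),
      alpha = 0.2, fill = "goldenrod"
    )
  }
  p
}
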