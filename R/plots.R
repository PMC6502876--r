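# ggplot2 views of the main result types. Figures are deliberately plain;
# all aesthetics can be overridden by adding ggplot layers.

#' Plot per-group primer coverage
#'
#' @param coverage_tbl Tidy coverage tibble (`pair`, `group`, `coverage`).
#' @return A ggplot: grouped bars of coverage (%) per taxon group and pair.
#' @export
plot_coverage <- function(coverage_tbl) {
  ggplot2::ggplot(
    coverage_tbl,
    ggplot2::aes(x = .data$group, y = 100 * .data$coverage, fill = .data$pair)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::labs(x = NULL, y = "coverage [%]", fill = "primer pair") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot theoretical measured abundances
#'
#' @param measurements Tibble from [theoretical_abundance()].
#' @return A ggplot: measured copies/mL per group and primer pair, log scale.
#' @export
plot_theoretical_abundance <- function(measurements) {
  ggplot2::ggplot(
    measurements,
    ggplot2::aes(x = .data$group, y = .data$measured, fill = .data$pair)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "measured abundance [copies/mL]",
                  fill = "primer pair") +
    ggplot2::theme_minimal()
}

#' Plot pairwise percentage dissimilarity between primer pairs
#'
#' @param dissim_tbl Tibble from [pairwise_dissimilarity()].
#' @return A ggplot: dissimilarity (0-100%) per comparison, faceted by sample.
#' @export
plot_dissimilarity <- function(dissim_tbl) {
  ggplot2::ggplot(
    dissim_tbl,
    ggplot2::aes(x = .data$comparison, y = .data$dissimilarity)
  ) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::facet_wrap(~sample) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "percentage dissimilarity [%]") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot primer-usage diversity per target group
#'
#' @param distribution Tibble from [group_usage_distribution()].
#' @return A ggplot: distinct primer pairs per group, annotated with the
#'   group's share of all hits.
#' @export
plot_primer_usage <- function(distribution) {
  ggplot2::ggplot(
    distribution,
    ggplot2::aes(x = stats::reorder(.data$target_group, .data$n_pairs),
                 y = .data$n_pairs)
  ) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%%", .data$share_pct)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = NULL, y = "distinct primer pairs") +
    ggplot2::theme_minimal()
}
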