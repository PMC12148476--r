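# ggplot2 views of detection results.

#' Island length distribution on a log10 scale
#'
#' Histogram of island lengths, log10 x-axis, faceted by sequence when
#' `facet = TRUE`. The pile-up just above the window size is expected: the
#' scan cannot emit anything shorter.
#'
#' @param islands Island tibble from [detect_islands()].
#' @param bins Number of histogram bins.
#' @param facet Facet by `seq_id`?
#' @return A ggplot object.
#' @export
plot_island_lengths <- function(islands, bins = 40, facet = FALSE) {
  p <- ggplot2::ggplot(islands, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "grey20") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "island length (bp, log10)", y = "islands") +
    ggplot2::theme_minimal()
  if (facet) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$seq_id))
  p
}

#' Per-chromosome island frequency and coverage
#'
#' Bars give islands per 1000 bp; points (secondary axis) give percent of
#' the chromosome covered. The genome `total` row is dropped.
#'
#' @param summary Tibble from [summarize_islands()].
#' @return A ggplot object.
#' @export
plot_summary <- function(summary) {
  df <- filter(summary, .data$seq_id != "total")
  scale <- max(df$freq_per_kb, 1e-9) / max(df$coverage_pct, 1e-9)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$seq_id, levels = df$seq_id))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$freq_per_kb),
                      fill = "steelblue", width = 0.7) +
    ggplot2::geom_point(ggplot2::aes(y = .data$coverage_pct * scale),
                        colour = "darkorange", size = 3) +
    ggplot2::scale_y_continuous(
      name = "islands per 1000 bp",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "coverage (%)")
    ) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
}
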