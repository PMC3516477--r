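#' Plot per-position information content of a PWM
#'
#' Bar plot of the per-position bit content (the column heights of a
#' sequence logo), annotated with the majority-base consensus.
#'
#' @param object,x A `pwm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_information_content <- function(x, ...) {
  ic <- information_content(x)
  ic$base <- strsplit(consensus_sequence(x), "", fixed = TRUE)[[1]]
  ggplot2::ggplot(ic, ggplot2::aes(x = .data$position, y = .data$bits)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$base),
      vjust = -0.4, size = 3
    ) +
    ggplot2::scale_x_continuous(breaks = ic$position) +
    ggplot2::ylim(0, 2.1) +
    ggplot2::labs(
      title = x$motif_id,
      x = "Motif position", y = "Information content (bits)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_information_content
#' @method autoplot pwm
#' @export
autoplot.pwm <- function(object, ...) plot_information_content(object, ...)

#' Plot a conservation comparison
#'
#' Conserved fraction per site class (proto-silencer vs genome-wide),
#' with the chi-squared p-value in the subtitle.
#'
#' @param object,x A `conservation_comparison` from
#'   [compare_conservation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_conservation_comparison <- function(x, ...) {
  ggplot2::ggplot(
    x$fractions,
    ggplot2::aes(x = .data$class, y = .data$conserved_fraction, fill = .data$class)
  ) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("n = %d", .data$n)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::scale_fill_manual(values = c(
      proto_silencer = "#c0392b", genome_wide = "#2c5f8a"
    )) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(
      x = NULL, y = "Fraction conserved (≥ min species)",
      subtitle = sprintf(
        "chi-squared = %.3f, p = %.3g", x$test$statistic, x$test$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_conservation_comparison
#' @method autoplot conservation_comparison
#' @export
autoplot.conservation_comparison <- function(object, ...) {
  plot_conservation_comparison(object, ...)
}

#' Plot motif frequency per factor-bound region set
#'
#' Bars of matches per 10 kb of bound intergenic sequence for each
#' transcription factor, faceted by motif; optionally highlights one
#' factor (e.g. the reciprocal factor of the plotted motif).
#'
#' @param freq Frequency tibble from [motif_frequency()].
#' @param highlight Optional factor name to highlight.
#' @return A ggplot object.
#' @export
plot_motif_frequency <- function(freq, highlight = NULL) {
  freq$highlight <- !is.null(highlight) & freq$factor %in% highlight
  ggplot2::ggplot(
    freq,
    ggplot2::aes(
      x = stats::reorder(.data$factor, -.data$freq_per_10kb),
      y = .data$freq_per_10kb, fill = .data$highlight
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "#7d3c98")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$motif_id), ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "Transcription factor (bound region set)",
      y = "Binding-site matches per 10 kb"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
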