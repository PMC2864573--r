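# ggplot2 visualisations for the main result types.

#' Plot a TSS-aligned binding profile
#'
#' @param profile A `binding_profile` from [build_profile()].
#' @param highlight_mode Draw a dashed line at the modal bin (default TRUE).
#' @return A ggplot object.
#' @export
plot_binding_profile <- function(profile, highlight_mode = TRUE) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$bin_center, y = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = if (identical(attr(profile, "mode"), "max1"))
                    "relative fraction (max = 1)"
                  else "fraction of high-score probes") +
    ggplot2::theme_minimal()
  if (highlight_mode) {
    p <- p + ggplot2::geom_vline(xintercept = profile_mode(profile),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.binding_profile <- function(object, ...) {
  plot_binding_profile(object, ...)
}

#' Plot a TFIIB/NC2 ratio curve
#'
#' @param curve A `ratio_curve` tibble.
#' @return A ggplot object.
#' @export
plot_ratio_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$pct_hi, y = .data$ratio)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "expression percentile (bin upper edge)",
                  y = "mean TFIIB / mean NC2 (linear scale)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ratio_curve <- function(object, ...) plot_ratio_curve(object)

#' Plot motif class frequencies
#'
#' @param freq Frequency tibble from [motif_frequency()].
#' @return A ggplot object.
#' @export
plot_motif_frequency <- function(freq) {
  ggplot2::ggplot(freq,
                  ggplot2::aes(x = stats::reorder(.data$class, -.data$percent),
                               y = .data$percent)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "% of promoters") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a sliding-window occupancy-expression curve
#'
#' @param fit A `sliding_window_fit` from [sliding_window_expression()].
#' @return A ggplot object.
#' @export
plot_expression_curve <- function(fit) {
  ggplot2::ggplot(fit$windows,
                  ggplot2::aes(x = .data$occupancy,
                               y = .data$mean_expression)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "promoter occupancy (log2)",
                  y = "mean expression per window",
                  subtitle = sprintf("Pearson r = %.3f", fit$pearson_r)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sliding_window_fit <- function(object, ...) {
  plot_expression_curve(object)
}

#' Plot a per-position nucleotide frequency matrix
#'
#' @param freq_matrix Tibble from [nucleotide_frequency_matrix()].
#' @return A ggplot object (one line per base).
#' @export
plot_nucleotide_frequency <- function(freq_matrix) {
  long <- tidyr::pivot_longer(freq_matrix, cols = c("A", "C", "G", "T"),
                              names_to = "base", values_to = "frequency")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position,
                                     y = .data$frequency,
                                     colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to TSS", y = "base frequency") +
    ggplot2::theme_minimal()
}
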