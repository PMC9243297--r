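# ggplot2 visualisations of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-category enrichment, protein versus control
#'
#' The standard HT-SELEX summary figure: mean fold change per
#' A/T-content category, one panel per cycle, protein series next to the
#' no-protein control, error bars showing the dispersion across
#' replicate libraries.
#'
#' @param object A `selex_enrichment` from [enrich_dataset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selex_enrichment
#' @export
autoplot.selex_enrichment <- function(object, ...) {
  s <- suppressWarnings(summarize_by_category(object))
  s$series <- ifelse(s$is_control, "no-protein control", s$protein)
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$at_category),
                                  y = .data$mean_fc,
                                  colour = .data$series,
                                  group = .data$series)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_fc - .data$sd_fc,
                                          ymax = .data$mean_fc + .data$sd_fc)) +
    ggplot2::facet_wrap(~cycle, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "A/T letters in k-mer", y = "mean fold change vs cycle 0",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' Plot depth-concordance curves
#'
#' Spearman R squared between sub-sampled and full-depth k-mer
#' abundances, against depth, one line per k.
#'
#' @param object A `coverage_report` from [coverage_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_report
#' @export
autoplot.coverage_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$depth, y = .data$r2,
                               colour = factor(.data$k),
                               group = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sub-sampled depth (reads)",
                  y = expression("Spearman" ~ R^2 ~ "vs full depth"),
                  colour = "k") +
    ggplot2::theme_bw()
}

#' Plot the positional nucleotide composition of a sample
#'
#' @param object A `positional_model` from [positional_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot positional_model
#' @export
autoplot.positional_model <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), cols = c("A", "C", "G", "T"),
                              names_to = "base", values_to = "freq")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$freq,
                                     colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.25, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "read position", y = "base frequency") +
    ggplot2::theme_bw()
}
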