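# ggplot2 views of the main result types.

#' Volcano plot of a differential-expression result
#'
#' @param object A `circ_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.circ_de <- function(object, ...) {
  df <- tidy(object)
  df$neglog_fdr <- -log10(pmax(df$fdr, 1e-300))
  lfc <- df$log2_fc
  lfc[!is.finite(lfc)] <- NA
  df$log2_fc_plot <- lfc
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc_plot,
                                   y = .data$neglog_fdr,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", unchanged = "grey60")
    ) +
    ggplot2::labs(x = "log2 fold change (tumor / normal)",
                  y = "-log10 FDR", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of circRNA exonic lengths
#'
#' @param calls circRNA calls tibble (with `exonic_length`).
#' @param binwidth Histogram bin width in nt (default 100).
#' @return A ggplot with the median length marked.
#' @export
plot_circ_lengths <- function(calls, binwidth = 100) {
  med <- median(calls$exonic_length)
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$exonic_length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = med, linetype = 2, colour = "#c0392b") +
    ggplot2::labs(x = "circRNA exonic length (nt)", y = "circRNA count",
                  subtitle = sprintf("median %.0f nt", med)) +
    ggplot2::theme_minimal()
}

#' Bar chart of the genomic region tally
#'
#' @param tally Output of [region_tally()].
#' @return A ggplot.
#' @export
plot_region_tally <- function(tally) {
  tally$region <- factor(tally$region, levels = tally$region)
  ggplot2::ggplot(tally, ggplot2::aes(x = .data$region, y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "mapped reads") +
    ggplot2::theme_minimal()
}

#' Degree distribution of a co-expression network
#'
#' @param object A `coexp_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coexp_network <- function(object, ...) {
  deg <- degree_centrality(object)
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_bar(fill = "grey40") +
    ggplot2::labs(x = "degree", y = "nodes",
                  subtitle = sprintf("condition: %s", object$condition)) +
    ggplot2::theme_minimal()
}
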