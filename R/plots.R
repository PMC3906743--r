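#' Abundance-versus-DE plot of a contrast, highlighting calls
#'
#' The qPCR-style MA view of a contrast: average abundance on x,
#' differential expression on y. Because PIF is the product of the two
#' axes, iso-PIF contours are hyperbolas — abundant genes need less DE to
#' reach the same impact. Optionally colours probes by the `call` column of
#' a [classify_de()] result joined on `probe_id`.
#'
#' @param contrast A [de_scores()] tibble.
#' @param calls Optional [classify_de()] tibble to colour by call.
#' @return A ggplot object.
#' @export
plot_contrast <- function(contrast, calls = NULL) {
  df <- as_tibble(contrast)
  if (!is.null(calls)) {
    df <- dplyr::left_join(df,
                           dplyr::select(as_tibble(calls), "probe_id", "call"),
                           by = "probe_id")
  } else {
    df$call <- "null"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg_abund, y = .data$de,
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", null = "grey60")) +
    ggplot2::labs(x = "average abundance", y = "differential expression",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Edge-weight view of a PCIT-filtered network
#'
#' Histogram of pairwise correlations split by whether PCIT kept the edge;
#' useful to see where the information-theoretic tolerance cut fell.
#'
#' @param object A `coexpr_network` with adjacency filled.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coexpr_network
#' @export
autoplot.coexpr_network <- function(object, ...) {
  edges <- tidy(object)
  if (!"kept" %in% names(edges)) {
    abort("run pcit_filter() before plotting the network")
  }
  ggplot2::ggplot(edges, ggplot2::aes(x = .data$r, fill = .data$kept)) +
    ggplot2::geom_histogram(bins = 50, position = "identity", alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#27ae60",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "Pearson r", fill = "kept") +
    ggplot2::theme_minimal()
}
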