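# ggplot2 views of the result tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cumulative motif-occurrence profile
#'
#' Step plot of running forward-strand site count against genome position, one
#' line per motif, faceted by replicon — the origin-proximal density view.
#'
#' @param object A [cumulative_occurrence()] result (several may be
#'   `dplyr::bind_rows()`-combined first to overlay motifs).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.motif_cumulative <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$position, y = .data$cumulative, colour = .data$motif)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$replicon_id), scales = "free_x") +
    ggplot2::labs(x = "genome position (nt)", y = "cumulative occurrence",
                  colour = "motif") +
    ggplot2::theme_minimal()
}

#' Plot windowed motif density with enrichment calls
#'
#' Observed window counts along the replicon with the expected (uniform) count
#' as a reference line; windows significant after Benjamini-Hochberg
#' adjustment (q < `alpha`) are highlighted.
#'
#' @param object A [windowed_density()] result.
#' @param alpha Significance threshold on the q-value.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.motif_density <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(object,
                      midpoint = (.data$window_start + .data$window_end) / 2,
                      enriched = .data$q_value < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint, y = .data$observed)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$enriched), width = NULL) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$replicon_id), scales = "free_x") +
    ggplot2::labs(x = "window midpoint (nt)", y = "observed motif sites",
                  fill = sprintf("q < %.2g", alpha)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.motif_cumulative
#' @param x A [cumulative_occurrence()] result.
#' @export
plot_cumulative <- function(x, ...) autoplot.motif_cumulative(x, ...)

#' @rdname autoplot.motif_density
#' @param x A [windowed_density()] result.
#' @export
plot_window_density <- function(x, alpha = 0.05, ...) {
  autoplot.motif_density(x, alpha = alpha, ...)
}
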