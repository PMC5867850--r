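# broom-style accessors for the window-density result.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a window-density result
#'
#' @param x A [windowed_density()] tibble.
#' @param ... Unused.
#' @return The per-window tibble as a plain tibble (one row per window).
#' @exportS3Method generics::tidy
#' @export
tidy.motif_density <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a window-density result
#'
#' @param x A [windowed_density()] tibble.
#' @param alpha q-value threshold for counting enriched windows.
#' @param ... Unused.
#' @return A one-row tibble: `n_windows`, `n_enriched`, `min_q`,
#'   `total_observed`.
#' @exportS3Method generics::glance
#' @export
glance.motif_density <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_windows = nrow(x),
    n_enriched = sum(x$q_value < alpha),
    min_q = if (nrow(x) > 0) min(x$q_value) else NA_real_,
    total_observed = sum(x$observed)
  )
}
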