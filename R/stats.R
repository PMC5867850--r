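# Ratio, summary, cumulative-occurrence and window-enrichment statistics.

#' Classify a GATC:CTAG ratio
#'
#' Band scheme used to color halobacterial chromosomes by Dam-like GATC
#' dominance: ratios below 5 (`below_5`, the *Haloferax*-like regime where
#' GATC dominance is lost), between 5 and 14 inclusive (`from_5_to_14`),
#' and above 20 (`above_20`, the *E. coli*-like regime). The band (14, 20]
#' is left unnamed by that scheme and is reported as `intermediate`.
#'
#' @param ratio Positive numeric vector; `NA` propagates.
#' @return A factor with levels `below_5`, `from_5_to_14`, `intermediate`,
#'   `above_20`.
#' @examples
#' classify_ratio(c(2.8, 6.3, 17, 21.6))
#' @export
classify_ratio <- function(ratio) {
  if (any(!is.na(ratio) & ratio <= 0)) {
    stop("ratio must be positive", call. = FALSE)
  }
  cls <- dplyr::case_when(
    is.na(ratio) ~ NA_character_,
    ratio < 5 ~ "below_5",
    ratio <= 14 ~ "from_5_to_14",
    ratio <= 20 ~ "intermediate",
    TRUE ~ "above_20"
  )
  factor(cls, levels = c("below_5", "from_5_to_14", "intermediate", "above_20"))
}

#' Per-replicon GATC:CTAG ratio table
#'
#' Joins the per-replicon counts of two motifs (by default `GATC` and `CTAG`)
#' from a [count_motifs()] result into one row per replicon with counts,
#' per-kb frequencies, the GATC/CTAG site-count ratio (raw and half-up rounded
#' to 1 decimal, the printed-table convention) and its [classify_ratio()]
#' class. Replicons with a zero CTAG count get an `NA` ratio and a warning;
#' they are flagged, never dropped.
#'
#' @param counts A [count_motifs()] tibble containing both motifs.
#' @param gatc,ctag Motif names (values of the `motif` column) playing the
#'   numerator and denominator roles.
#' @return A tibble with columns `replicon_id`, `ctag_count`, `gatc_count`,
#'   `ctag_per_kb`, `gatc_per_kb`, `ratio`, `ratio_1dp`, `ratio_class`,
#'   `ratio_defined`.
#' @export
ratio_table <- function(counts, gatc = "GATC", ctag = "CTAG") {
  need <- c(gatc, ctag)
  if (!all(need %in% counts$motif)) {
    stop("`counts` must contain motifs: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  wide <- counts |>
    dplyr::filter(.data$motif %in% need) |>
    dplyr::mutate(role = ifelse(.data$motif == gatc, "gatc", "ctag")) |>
    dplyr::select("replicon_id", "role", "site_count", "per_kb_2dp") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("site_count", "per_kb_2dp"))
  out <- wide |>
    dplyr::transmute(
      replicon_id = .data$replicon_id,
      ctag_count = .data$site_count_ctag,
      gatc_count = .data$site_count_gatc,
      ctag_per_kb = .data$per_kb_2dp_ctag,
      gatc_per_kb = .data$per_kb_2dp_gatc,
      ratio_defined = .data$ctag_count > 0,
      ratio = ifelse(.data$ratio_defined, .data$gatc_count / .data$ctag_count,
                     NA_real_),
      ratio_1dp = round_half_up(.data$ratio, 1),
      ratio_class = classify_ratio(.data$ratio)
    ) |>
    dplyr::relocate("ratio_defined", .after = "ratio_class")
  if (any(!out$ratio_defined)) {
    warning("ratio undefined (zero ", ctag, " count) for: ",
            paste(out$replicon_id[!out$ratio_defined], collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Column mean and standard deviations
#'
#' Mean together with both the sample (n-1 denominator) and population (n
#' denominator) standard deviation of a per-chromosome statistic, as needed to
#' reproduce the summary rows of printed frequency tables (whose SD row
#' matches the population form).
#'
#' @param values Numeric vector, `NA` removed.
#' @param name Label for the `column` field.
#' @return A one-row tibble: `column`, `n`, `mean`, `sd_sample`,
#'   `sd_population` (SDs are `NA` when fewer than two values).
#' @examples
#' column_summary(c(1, 1, 1))
#' @export
column_summary <- function(values, name = deparse(substitute(values))) {
  force(name)  # resolve the label before `values` is modified
  values <- values[!is.na(values)]
  n <- length(values)
  m <- mean(values)
  tibble::tibble(
    column = name,
    n = n,
    mean = m,
    sd_sample = if (n >= 2) stats::sd(values) else NA_real_,
    sd_population = if (n >= 2) sqrt(mean((values - m)^2)) else NA_real_
  )
}

#' Cumulative motif occurrence along a replicon
#'
#' The step function whose x-axis is genome position and whose y-axis is the
#' running count of forward-strand motif sites up to that position — the
#' profile used to visualize origin-proximal CTAG/GATC concentration. One row
#' per hit; a replicon with no hits contributes no rows (final value 0).
#'
#' @param replicons A [replicon_table()] tibble.
#' @param motif A [parse_motif()] object.
#' @return A tibble of class `motif_cumulative` with columns `replicon_id`,
#'   `motif`, `position`, `cumulative`, plus a `lengths` attribute for
#'   plotting.
#' @examples
#' cumulative_occurrence(replicon_table("chr", "CTAGCTAG"), parse_motif("CTAG"))
#' @export
cumulative_occurrence <- function(replicons, motif) {
  hits <- scan_motif(replicons, motif, strands = "forward")
  out <- hits |>
    dplyr::group_by(.data$replicon_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(position = .data$start, cumulative = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("replicon_id", "motif", "position", "cumulative")
  attr(out, "lengths") <- stats::setNames(replicons$length, replicons$replicon_id)
  class(out) <- c("motif_cumulative", class(out))
  out
}

#' Windowed motif density with Poisson enrichment test
#'
#' Tiles (or slides over) each replicon, counts forward-strand motif sites per
#' window by their start coordinate, and tests each window's count against the
#' replicon-wide rate with a Poisson upper-tail test
#' (`P(X >= observed)` at `lambda = rate * window width`). P-values are
#' Benjamini-Hochberg adjusted across the windows of each replicon. With
#' `step = window` (the default) the tiling is exact: window counts sum to the
#' replicon's site count, the last partial window included.
#'
#' @param replicons A [replicon_table()] tibble.
#' @param motif A [parse_motif()] object.
#' @param window Window width in nt (default 10000); must be at least the
#'   motif length. A window wider than the replicon falls back to a single
#'   whole-replicon window with a warning.
#' @param step Step between window starts in nt; defaults to `window`.
#' @return A tibble of class `motif_density` with columns `replicon_id`,
#'   `motif`, `window_start`, `window_end` (1-based inclusive), `observed`,
#'   `expected`, `p_value`, `q_value`.
#' @export
windowed_density <- function(replicons, motif, window = 10000, step = window) {
  stopifnot(window >= nchar(motif$pattern), step >= 1)
  hits <- scan_motif(replicons, motif, strands = "forward")
  out <- purrr::pmap_dfr(
    replicons[, c("replicon_id", "length")],
    function(replicon_id, length) {
      w <- window
      if (w > length) {
        warning(sprintf("window (%d nt) exceeds replicon '%s' (%d nt); using one whole-replicon window",
                        as.integer(w), replicon_id, length), call. = FALSE)
        starts <- 1L
      } else if (step >= w) {
        # tiling: keep the partial tail window so counts are conserved
        starts <- seq(1L, length, by = step)
      } else {
        # sliding scan: only windows that fit entirely
        starts <- seq(1L, length - w + 1L, by = step)
      }
      ends <- pmin(starts + w - 1L, length)
      pos <- hits$start[hits$replicon_id == replicon_id]
      site_count <- length(pos)
      observed <- vapply(seq_along(starts), function(i) {
        sum(pos >= starts[i] & pos <= ends[i])
      }, integer(1))
      rate <- site_count / length
      expected <- rate * (ends - starts + 1)
      p <- stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
      tibble::tibble(
        replicon_id = replicon_id, motif = motif$name,
        window_start = starts, window_end = as.integer(ends),
        observed = observed, expected = expected,
        p_value = p,
        q_value = stats::p.adjust(p, method = "BH")
      )
    }
  )
  class(out) <- c("motif_density", class(out))
  out
}
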