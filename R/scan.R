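# Degenerate-motif scanning over replicon tables.
#
# Sequences are held as plain character columns; scanning converts a sequence
# once into a vector of 4-bit IUPAC masks and tests each pattern position with
# a vectorized subset check, so the scan is O(N * L) with L vectorized passes
# over the sequence (L = motif length). At the replicon sizes this package
# targets (up to a few Mb) this stays well under a second per motif.

#' Build a replicon table
#'
#' Validates and normalizes a set of replicons into the tibble format consumed
#' by the scanning functions. Usually produced by [read_fasta()]; use this
#' constructor for sequences built in code.
#'
#' @param replicon_id Character vector of unique replicon names.
#' @param sequence Character vector of nucleotide sequences (IUPAC alphabet;
#'   case-insensitive, `U` normalized to `T`).
#' @param topology `"linear"` (default) or `"circular"`, recycled.
#' @return A tibble with columns `replicon_id`, `sequence`, `topology`,
#'   `length`.
#' @examples
#' replicon_table("chr", "CTAGGATCCTAG")
#' @export
replicon_table <- function(replicon_id, sequence, topology = "linear") {
  stopifnot(length(replicon_id) == length(sequence))
  if (anyDuplicated(replicon_id)) {
    stop("duplicate replicon_id: ",
         paste(unique(replicon_id[duplicated(replicon_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(sequence))) stop("empty replicon sequence", call. = FALSE)
  topology <- rep_len(match.arg(topology, c("linear", "circular")),
                      length(sequence))
  sequence <- vapply(seq_along(sequence), function(i) {
    normalize_nt(sequence[i], what = paste0("replicon '", replicon_id[i], "'"))
  }, character(1))
  tibble::tibble(
    replicon_id = as.character(replicon_id),
    sequence = sequence,
    topology = topology,
    length = nchar(sequence)
  )
}

# Integer mask vector for a normalized sequence string.
seq_masks <- function(sequence) {
  unname(IUPAC_MASK[strsplit(sequence, "", fixed = TRUE)[[1]]])
}

# Forward-strand match starts of `pattern` (normalized string) against a mask
# vector, subset semantics. Returns an integer vector of 1-based starts.
match_starts <- function(masks, pattern) {
  n <- length(masks)
  pm <- unname(IUPAC_MASK[strsplit(pattern, "", fixed = TRUE)[[1]]])
  L <- length(pm)
  if (L > n) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    if (pm[j] == 15L) next  # pattern N admits every genome code
    ok <- ok & (bitwAnd(masks[j:(n - L + j)], bitwXor(pm[j], 15L)) == 0L)
  }
  which(ok)
}

text_at <- function(sequence, starts, L) {
  if (length(starts) == 0) return(character(0))
  substring(sequence, starts, starts + L - 1L)
}

scan_one <- function(sequence, topology, motif, strands) {
  L <- nchar(motif$pattern)
  n <- nchar(sequence)
  if (L > n) {
    warning(sprintf("motif %s (length %d) longer than replicon (length %d); no hits",
                    motif$name, L, n), call. = FALSE)
    return(tibble::tibble(start = integer(0), strand = character(0),
                          matched_text = character(0)))
  }
  scan_seq <- sequence
  if (identical(topology, "circular") && L > 1) {
    # junction scan: append the first L-1 bases; starts beyond n belong to the
    # linear duplicate and are dropped, so nothing is double-reported
    scan_seq <- paste0(sequence, substr(sequence, 1L, L - 1L))
  }
  masks <- seq_masks(scan_seq)
  pieces <- list()
  fwd <- match_starts(masks, motif$pattern)
  fwd <- fwd[fwd <= n]
  pieces$fwd <- tibble::tibble(
    start = fwd, strand = "+",
    matched_text = text_at(scan_seq, fwd, L)
  )
  if (strands == "both") {
    rev <- match_starts(masks, revcomp_chr(motif$pattern))
    rev <- rev[rev <= n]
    pieces$rev <- tibble::tibble(
      start = rev, strand = "-",
      matched_text = text_at(scan_seq, rev, L)
    )
  }
  dplyr::arrange(dplyr::bind_rows(pieces), .data$start, .data$strand)
}

#' Scan replicons for a degenerate motif
#'
#' Reports every position where the motif matches under subset semantics
#' ([base_matches()]); overlapping matches are all reported. Reverse-strand
#' occurrences are found by scanning the reverse-complement pattern on the
#' forward strand, so `start` is always the forward-strand coordinate of the
#' leftmost matched base and `matched_text` is the forward-strand window. For
#' circular replicons the origin-spanning junction is scanned as well.
#'
#' @param replicons A [replicon_table()] / [read_fasta()] tibble.
#' @param motif A [parse_motif()] object.
#' @param strands `"both"` (default) or `"forward"`.
#' @return A tibble with columns `replicon_id`, `motif`, `start`, `strand`,
#'   `matched_text`.
#' @examples
#' reps <- replicon_table("chr", "CTAGGCTAGT")
#' scan_motif(reps, parse_motif("CTAG"), strands = "forward")
#' @export
scan_motif <- function(replicons, motif, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(inherits(motif, "degenerate_motif"))
  purrr::pmap_dfr(
    replicons[, c("replicon_id", "sequence", "topology")],
    function(replicon_id, sequence, topology) {
      hits <- scan_one(sequence, topology, motif, strands)
      tibble::tibble(
        replicon_id = rep(replicon_id, nrow(hits)),
        motif = rep(motif$name, nrow(hits)),
        hits
      )
    }
  )
}

#' Count motif sites and occurrences per replicon
#'
#' `site_count` is the forward-strand match count (the convention of the
#' halobacterial chromosome frequency table); `occurrence_count` counts
#' strand-specific occurrences on both strands, which for palindromic motifs
#' on unambiguous sequence is exactly `2 * site_count` (the methylome-table
#' denominator, e.g. 1342 CTAG occurrences = 2 x 671 chromosome sites).
#' `per_kb` is `1000 * site_count / length`; `per_kb_2dp` is its half-up
#' 2-decimal rounding used when reproducing printed frequency tables.
#'
#' @param replicons A [replicon_table()] tibble.
#' @param motifs A single [parse_motif()] object or a list of them.
#' @return A tibble with one row per replicon x motif: `replicon_id`, `motif`,
#'   `length`, `site_count`, `occurrence_count`, `per_kb`, `per_kb_2dp`.
#' @examples
#' reps <- replicon_table("chr", strrep("CTAGATCGG", 50))
#' count_motifs(reps, hvo_motifs()[c("ctag", "gatc")])
#' @export
count_motifs <- function(replicons, motifs) {
  if (inherits(motifs, "degenerate_motif")) motifs <- list(motifs)
  purrr::map_dfr(motifs, function(m) {
    hits <- scan_motif(replicons, m, strands = "both")
    counts <- hits |>
      dplyr::group_by(.data$replicon_id) |>
      dplyr::summarise(
        site_count = sum(.data$strand == "+"),
        occurrence_count = dplyr::n(),
        .groups = "drop"
      )
    replicons |>
      dplyr::select("replicon_id", "length") |>
      dplyr::left_join(counts, by = "replicon_id") |>
      dplyr::mutate(
        motif = m$name,
        site_count = dplyr::coalesce(.data$site_count, 0L),
        occurrence_count = dplyr::coalesce(.data$occurrence_count, 0L),
        per_kb = 1000 * .data$site_count / .data$length,
        per_kb_2dp = round_half_up(.data$per_kb, 2)
      ) |>
      dplyr::select("replicon_id", "motif", "length", "site_count",
                    "occurrence_count", "per_kb", "per_kb_2dp")
  })
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.25 -> 0.3 at 1 digit), the convention
#' needed to reproduce the printed per-kb and ratio cells exactly; base R's
#' `round()` rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Numeric vector.
#' @examples
#' round_half_up(c(0.245, 2.75), c(2, 1))
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
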