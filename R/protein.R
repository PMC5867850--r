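# MTase signature-motif detection in protein sequences.
#
# Amino-MTases (6mA/4mC) carry the AdoMet-binding signature DPPY and the
# catalytic signature FxGxG ("FGG"); their N->C order distinguishes REBASE
# subtypes (FGG before DPPY in the alpha/beta/gamma orders). 5mC MTases carry
# a different signature set (FGG, PC, ENV, QRR, YGN). Patterns here are small
# fixed-length degenerate amino-acid patterns: a position is either a literal
# residue, a bracketed residue set, or the wildcard x.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default MTase signature patterns
#'
#' The signature set scanned by [find_signature_motifs()]. Residue sets cover
#' the canonical spellings plus the variants observed in characterized MTase
#' alignments: `DPPY_family = [DNSE]PP[YFW]` (covers DPPY, SPPY, NPPY, NPPF),
#' `FGG_family = [FAWY]xGxG` (covers FxGxG and the AGG-spelled variant),
#' the 5mC signatures `PC`, `ENV`, `QRR`, and `YGN_family = [YRL]GN` (covers
#' the (R/L)GN variants). `canonical_order` gives each signature's N->C rank
#' in the 5mC signature architecture.
#'
#' @return A tibble with columns `signature`, `pattern`, `length`,
#'   `canonical_order`.
#' @export
signature_patterns <- function() {
  tibble::tibble(
    signature = c("DPPY_family", "FGG_family", "PC", "ENV", "QRR", "YGN_family"),
    pattern = c("[DNSE]PP[YFW]", "[FAWY]xGxG", "PC", "ENV", "QRR", "[YRL]GN"),
    length = c(4L, 5L, 2L, 3L, 3L, 3L),
    canonical_order = c(NA, 1L, 2L, 3L, 4L, 5L)
  )
}

# Parse a pattern string into a list of residue-set character vectors
# (NULL = wildcard).
parse_aa_pattern <- function(pattern) {
  sets <- list()
  i <- 1L
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      set <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop("unclosed '[' in pattern ", pattern, call. = FALSE)
      sets[[length(sets) + 1L]] <- set
      i <- j + 1L
    } else if (ch == "x") {
      sets[length(sets) + 1L] <- list(NULL)  # wildcard position
      i <- i + 1L
    } else {
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1L
    }
  }
  sets
}

#' Find MTase signature motifs in protein sequences
#'
#' Scans each sequence for every signature pattern and reports all (including
#' overlapping) matches. Sequences must use the 20-letter amino-acid alphabet;
#' `X` is accepted in input but matches nothing, not even wildcard positions.
#'
#' @param proteins A tibble with columns `protein_id` and `sequence`
#'   ([read_fasta_protein()]), or a named character vector of sequences.
#' @param signatures A [signature_patterns()]-shaped tibble; override to
#'   reconfigure residue sets.
#' @return A tibble of hits: `protein_id`, `signature`, `start` (1-based
#'   residue index), `matched_text`.
#' @examples
#' find_signature_motifs(c(p1 = "MKLSPPYAARK"))
#' @export
find_signature_motifs <- function(proteins, signatures = signature_patterns()) {
  if (is.character(proteins)) {
    proteins <- tibble::tibble(
      protein_id = names(proteins) %||% as.character(seq_along(proteins)),
      sequence = unname(proteins)
    )
  }
  seqs <- toupper(proteins$sequence)
  bad_chars <- lapply(strsplit(seqs, "", fixed = TRUE), function(ch) {
    setdiff(unique(ch), c(AA_ALPHABET, "X"))
  })
  offenders <- which(lengths(bad_chars) > 0)
  if (length(offenders) > 0) {
    stop(sprintf("invalid residue character(s) %s in sequence '%s'",
                 paste(bad_chars[[offenders[1]]], collapse = ","),
                 proteins$protein_id[offenders[1]]), call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(signatures)), function(k) {
    sets <- parse_aa_pattern(signatures$pattern[k])
    L <- length(sets)
    purrr::map_dfr(seq_along(seqs), function(i) {
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      n <- length(chars)
      if (L > n) return(NULL)
      ok <- rep(TRUE, n - L + 1L)
      for (j in seq_len(L)) {
        window <- chars[j:(n - L + j)]
        set <- sets[[j]]
        ok <- ok & if (is.null(set)) window != "X" else window %in% set
      }
      starts <- which(ok)
      tibble::tibble(
        protein_id = rep(proteins$protein_id[i], length(starts)),
        signature = rep(signatures$signature[k], length(starts)),
        start = starts,
        matched_text = text_at(seqs[i], starts, L)
      )
    })
  }) |>
    dplyr::arrange(.data$protein_id, .data$start, .data$signature)
}

# Longest selection of 5mC signatures respecting the canonical N->C order,
# one hit per signature category, strictly increasing starts. Small DP over
# the 5 ordered categories.
canonical_chain_length <- function(hits, order_tbl) {
  cats <- order_tbl$signature[order(order_tbl$canonical_order)]
  starts_by_cat <- lapply(cats, function(s) sort(hits$start[hits$signature == s]))
  best <- function(k, min_start) {
    if (k > length(cats)) return(0L)
    skip <- best(k + 1L, min_start)
    avail <- starts_by_cat[[k]][starts_by_cat[[k]] > min_start]
    take <- if (length(avail) > 0) 1L + best(k + 1L, avail[1]) else 0L
    max(skip, take)
  }
  best(1L, -Inf)
}

#' Classify a protein from its signature-motif hits
#'
#' Applies the family rules to one protein's hits: `amino_MTase_like` when
#' both a DPPY-family and an FGG-family motif are present (the 6mA/4mC MTase
#' architecture); `five_mC_like` when at least four of the five 5mC signatures
#' (FGG, PC, ENV, QRR, YGN) occur in their canonical N->C order; otherwise
#' `none`. The `order_string` records FGG/DPPY precedence (first occurrences),
#' and `subtype_note` states when the FGG-before-DPPY order matches the
#' REBASE alpha/beta/gamma conventions — a hint only, since motif order alone
#' does not uniquely determine the subtype.
#'
#' @param hits A [find_signature_motifs()] tibble for one protein (or several;
#'   classified per `protein_id`).
#' @param signatures The signature table used for the scan.
#' @return A tibble with one row per protein: `protein_id`, `n_hits`,
#'   `order_string`, `family_hint`, `subtype_note`.
#' @export
classify_signatures <- function(hits, signatures = signature_patterns()) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(protein_id = character(0), n_hits = integer(0),
                          order_string = character(0),
                          family_hint = character(0),
                          subtype_note = character(0)))
  }
  five_mc <- signatures[!is.na(signatures$canonical_order), ]
  hits |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(h, key) {
      h <- dplyr::arrange(h, .data$start)
      first_start <- function(sig) {
        s <- h$start[h$signature == sig]
        if (length(s) > 0) min(s) else NA_integer_
      }
      fgg <- first_start("FGG_family")
      dppy <- first_start("DPPY_family")
      amino <- !is.na(fgg) && !is.na(dppy)
      chain <- canonical_chain_length(h, five_mc)
      family <- if (amino) "amino_MTase_like"
        else if (chain >= 4) "five_mC_like"
        else "none"
      order_string <- if (amino) {
        if (fgg < dppy) "FGG<DPPY" else "DPPY<FGG"
      } else {
        paste(unique(h$signature[order(h$start)]), collapse = "<")
      }
      note <- if (amino && fgg < dppy) {
        "FGG precedes DPPY: consistent with the REBASE alpha/beta/gamma motif orders"
      } else if (amino) {
        "DPPY precedes FGG: order not among the REBASE alpha/beta/gamma conventions"
      } else if (chain >= 4) {
        sprintf("%d of 5 cytosine-MTase signatures in canonical N->C order", chain)
      } else {
        ""
      }
      tibble::tibble(n_hits = nrow(h), order_string = order_string,
                     family_hint = family, subtype_note = note)
    }) |>
    dplyr::ungroup()
}
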