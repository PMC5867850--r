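# FASTA readers and table writers.

#' Read nucleotide replicons from FASTA
#'
#' Multi-record FASTA, one record per replicon. Ids are the first whitespace-
#' delimited token of each header; sequences are uppercased and `U` normalized
#' to `T`. Empty records, duplicate ids and non-IUPAC characters are errors.
#'
#' @param path FASTA file.
#' @param topology `"linear"` (default) or `"circular"`, applied to all
#'   records.
#' @return A [replicon_table()] tibble.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # read raw so that case/U normalization and IUPAC validation (with the
  # offending record named) happen under the package's rules
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  replicon_table(ids, as.character(set), topology = topology)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return A tibble with columns `protein_id`, `sequence`, `length`.
#' @export
read_fasta_protein <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate protein ids in ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("empty protein record in ", path, call. = FALSE)
  tibble::tibble(protein_id = ids, sequence = unname(seqs),
                 length = nchar(seqs))
}

#' Write replicons to FASTA
#'
#' @param replicons A [replicon_table()] tibble.
#' @param path Output file.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(replicons, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(replicons))) {
    writeLines(paste0(">", replicons$replicon_id[i]), con)
    s <- replicons$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Printed motif counts for sequenced halobacterial chromosomes
#'
#' The published per-chromosome CTAG/GATC motif count table for 47 completely
#' sequenced halobacterial chromosomes, with the *E. coli* K-12 chromosome as
#' a comparison row: total forward-strand CTAG and GATC counts, per-kb
#' frequencies, the printed GATC/CTAG ratio, and whether a Dam
#' methyltransferase match was found. Used as the reference input for the
#' worked ratio/summary examples; no sequence download is required.
#'
#' @return A tibble with columns `accession`, `organism`, `total_ctag`,
#'   `total_gatc`, `ctag_per_kb`, `gatc_per_kb`, `gatc_over_ctag`,
#'   `dam_match`, `group` (`"halobacteria"` or `"comparison"`).
#' @examples
#' halobacterial_motif_counts()
#' @export
halobacterial_motif_counts <- function() {
  path <- system.file("extdata", "halobacterial_chromosome_motif_counts.tsv",
                      package = "halomotif", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    accession = readr::col_character(),
    organism = readr::col_character(),
    total_ctag = readr::col_integer(),
    total_gatc = readr::col_integer(),
    ctag_per_kb = readr::col_double(),
    gatc_per_kb = readr::col_double(),
    gatc_over_ctag = readr::col_double(),
    dam_match = readr::col_logical(),
    group = readr::col_character()
  ))
}

#' Write a result table to TSV or JSON
#'
#' TSV writes the tibble as-is with a header row; JSON round-trips both the
#' display (rounded) and raw numeric columns losslessly.
#'
#' @param x A tibble (e.g. a [ratio_table()] or [summarize_methylome()]
#'   result).
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(x, path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required for JSON output", call. = FALSE)
    }
    jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Export motif hits or enriched windows as BED
#'
#' Strict BED: 0-based half-open coordinates (the in-memory tables are 1-based
#' inclusive).
#'
#' @param x A [scan_motif()] hit tibble (uses `start` and the motif length) or
#'   a [windowed_density()] tibble (uses `window_start`/`window_end`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (all(c("window_start", "window_end") %in% names(x))) {
    bed <- tibble::tibble(
      chrom = x$replicon_id,
      chromStart = x$window_start - 1L,
      chromEnd = x$window_end,
      name = x$motif,
      score = round(-10 * log10(pmax(x$q_value, 1e-30))),
      strand = "."
    )
  } else {
    bed <- tibble::tibble(
      chrom = x$replicon_id,
      chromStart = x$start - 1L,
      chromEnd = x$start - 1L + nchar(x$matched_text),
      name = x$motif,
      score = 0L,
      strand = x$strand
    )
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
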