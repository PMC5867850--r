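# SMRT-style base-modification call handling and per-motif methylome
# summaries: which fraction of a motif's strand-specific occurrences carries a
# modification call of the right type at the motif's methylated position.

MOD_TYPES <- c("6mA", "4mC", "5mC", "modified_base")

# GFF3 feature-type spellings accepted for each modification type
GFF_TYPE_MAP <- c(m6A = "6mA", m4C = "4mC", m5C = "5mC",
                  "6mA" = "6mA", "4mC" = "4mC", "5mC" = "5mC",
                  modified_base = "modified_base")

validate_calls <- function(calls) {
  req <- c("replicon_id", "position", "strand", "type", "qv", "coverage")
  missing <- setdiff(req, names(calls))
  if (length(missing) > 0) {
    stop("modification calls lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(calls$strand %in% c("+", "-"))) {
    bad <- which(!calls$strand %in% c("+", "-"))[1]
    stop(sprintf("unknown strand symbol '%s' in call %d (must be + or -)",
                 calls$strand[bad], bad), call. = FALSE)
  }
  if (!all(calls$type %in% MOD_TYPES)) {
    stop("unknown modification type(s): ",
         paste(setdiff(unique(calls$type), MOD_TYPES), collapse = ", "),
         call. = FALSE)
  }
  if (any(calls$position < 1)) stop("call position must be >= 1", call. = FALSE)
  if (any(calls$qv < 0)) stop("modification QV must be >= 0", call. = FALSE)
  if (any(calls$coverage < 1)) stop("coverage must be >= 1", call. = FALSE)
  tibble::tibble(
    replicon_id = as.character(calls$replicon_id),
    position = as.integer(calls$position),
    strand = calls$strand,
    type = calls$type,
    qv = as.numeric(calls$qv),
    coverage = as.integer(calls$coverage)
  )
}

#' Read base-modification calls
#'
#' Reads per-base modification calls in either of two dialects emulating SMRT
#' modification-and-motif-analysis output:
#' * `csv`: columns `replicon,position,strand,type,qv,coverage` with types
#'   written as `m6A`/`m4C`/`m5C` (or `6mA`/`4mC`/`5mC`) or `modified_base`;
#' * `gff3`: feature type `modified_base`/`m6A`/`m4C`/`m5C`, modification QV in
#'   the score column, read depth in a `coverage` attribute.
#'
#' Strand must be `+` or `-`; a `.` strand is rejected because a modified base
#' is inherently strand-specific.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"gff3"`.
#' @return A tibble of calls: `replicon_id`, `position` (1-based), `strand`,
#'   `type` (`6mA`/`4mC`/`5mC`/`modified_base`), `qv`, `coverage`.
#' @export
read_modification_calls <- function(path, dialect = c("csv", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "csv") {
    raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
      replicon = readr::col_character(),
      position = readr::col_integer(),
      strand = readr::col_character(),
      type = readr::col_character(),
      qv = readr::col_double(),
      coverage = readr::col_integer()
    )))
    probs <- readr::problems(raw)
    if (nrow(probs) > 0) {
      stop(sprintf("malformed modification CSV at line %d: expected %s, got '%s'",
                   probs$row[1], probs$expected[1], probs$actual[1]),
           call. = FALSE)
    }
    if (nrow(raw) == 0) {
      warning("empty modification call file: ", path, call. = FALSE)
      return(validate_calls(tibble::tibble(
        replicon_id = character(0), position = integer(0),
        strand = character(0), type = character(0),
        qv = numeric(0), coverage = integer(0))))
    }
    type <- GFF_TYPE_MAP[raw$type]
    if (anyNA(type)) {
      stop("unknown modification type(s): ",
           paste(unique(raw$type[is.na(type)]), collapse = ", "), call. = FALSE)
    }
    validate_calls(tibble::tibble(
      replicon_id = raw$replicon, position = raw$position,
      strand = raw$strand, type = unname(type),
      qv = raw$qv, coverage = raw$coverage
    ))
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) == 0) {
      warning("empty modification call file: ", path, call. = FALSE)
      return(validate_calls(tibble::tibble(
        replicon_id = character(0), position = integer(0),
        strand = character(0), type = character(0),
        qv = numeric(0), coverage = integer(0))))
    }
    df <- as.data.frame(gr)
    feat <- as.character(df$type)
    type <- GFF_TYPE_MAP[feat]
    if (anyNA(type)) {
      stop("unknown modification feature type(s): ",
           paste(unique(feat[is.na(type)]), collapse = ", "), call. = FALSE)
    }
    if (is.null(df$coverage)) {
      stop("GFF3 calls lack a coverage attribute", call. = FALSE)
    }
    validate_calls(tibble::tibble(
      replicon_id = as.character(df$seqnames),
      position = df$start,
      strand = as.character(df$strand),
      type = unname(type),
      qv = as.numeric(df$score),
      coverage = as.integer(df$coverage)
    ))
  }
}

#' Write base-modification calls
#'
#' Inverse of [read_modification_calls()]; emits the `csv` dialect or the GFF3
#' dialect (feature type from the modification type, QV in the score column,
#' coverage as an attribute).
#'
#' @param calls A call tibble as returned by [read_modification_calls()] or
#'   [simulate_methylome()].
#' @param path Output file.
#' @param dialect `"csv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_modification_calls <- function(calls, path, dialect = c("csv", "gff3")) {
  dialect <- match.arg(dialect)
  calls <- validate_calls(calls)
  if (dialect == "csv") {
    out <- tibble::tibble(
      replicon = calls$replicon_id, position = calls$position,
      strand = calls$strand,
      type = c("6mA" = "m6A", "4mC" = "m4C", "5mC" = "m5C",
               modified_base = "modified_base")[calls$type],
      qv = calls$qv, coverage = calls$coverage
    )
    readr::write_csv(out, path)
  } else {
    lines <- c("##gff-version 3", sprintf(
      "%s\tkinModCall\t%s\t%d\t%d\t%s\t%s\t.\tcoverage=%d",
      calls$replicon_id,
      c("6mA" = "m6A", "4mC" = "m4C", "5mC" = "m5C",
        modified_base = "modified_base")[calls$type],
      calls$position, calls$position,
      format(calls$qv, trim = TRUE, scientific = FALSE),
      calls$strand, calls$coverage
    ))
    writeLines(lines, path)
  }
  invisible(path)
}

# Strand-specific motif occurrences with the forward-strand coordinate of the
# methylated base on each occurrence. A "+" occurrence starting at s has its
# methylated base at s + pos - 1; a "-" occurrence (leftmost forward base s)
# reads the reverse complement, so pattern position pos sits at s + L - pos.
methylated_site_table <- function(replicons, motif) {
  if (is.null(motif$methylated_position) || is.null(motif$methylation_type)) {
    stop("motif must carry a methylated position and methylation type",
         call. = FALSE)
  }
  L <- nchar(motif$pattern)
  pos <- motif$methylated_position
  scan_motif(replicons, motif, strands = "both") |>
    dplyr::mutate(
      methylated_at = ifelse(.data$strand == "+",
                             .data$start + pos - 1L,
                             .data$start + L - pos)
    )
}

#' Summarize a methylome against one motif
#'
#' Rolls per-base modification calls up into the per-motif methylome summary:
#' the denominator `n_genome` is the number of strand-specific occurrences of
#' the motif across the supplied replicons (each strand of a palindromic site
#' counted separately, so the CTAG denominator on a chromosome with 671 sites
#' is 1342); an occurrence counts as methylated when a call of the motif's
#' methylation type sits exactly at its methylated position on its own strand.
#' Mean QV and coverage are arithmetic means over the matched calls and are
#' `NA` when nothing is methylated.
#'
#' @param calls A call tibble ([read_modification_calls()]).
#' @param replicons A [replicon_table()] tibble. To reproduce chromosome-only
#'   denominators, pass only the chromosome row.
#' @param motif A [parse_motif()] object with methylated position and type.
#' @param min_qv,min_coverage Optional thresholds; calls below either are
#'   ignored (default: none, upstream calls taken as-is).
#' @return A one-row tibble: `motif`, `methylated_position`,
#'   `methylation_type`, `n_methylated`, `n_genome`, `percent_methylated`
#'   (raw), `percent_methylated_int` (nearest integer, the reporting
#'   convention), `mean_qv`, `mean_coverage`.
#' @export
summarize_methylome <- function(calls, replicons, motif,
                                min_qv = 0, min_coverage = 1) {
  calls <- validate_calls(calls)
  calls <- calls[calls$qv >= min_qv & calls$coverage >= min_coverage, ]
  occ <- methylated_site_table(replicons, motif)
  matched <- dplyr::inner_join(
    occ,
    calls[calls$type == motif$methylation_type, ],
    by = c("replicon_id", methylated_at = "position", "strand")
  )
  n_genome <- nrow(occ)
  n_meth <- nrow(matched)
  pct <- if (n_genome > 0) 100 * n_meth / n_genome else NA_real_
  meth_pos <- motif$methylated_position
  meth_type <- motif$methylation_type
  tibble::tibble(
    motif = motif$name,
    methylated_position = meth_pos,
    methylation_type = meth_type,
    n_methylated = n_meth,
    n_genome = n_genome,
    percent_methylated = pct,
    percent_methylated_int = round_half_up(pct, 0),
    mean_qv = if (n_meth > 0) mean(matched$qv) else NA_real_,
    mean_coverage = if (n_meth > 0) mean(matched$coverage) else NA_real_
  )
}

#' Percent change between two positive quantities
#'
#' `100 * (observed - reference) / reference`, e.g. the jump of mean motif
#' coverage from 30.7 to 130.4 between sequencing runs is a ~325% increase.
#'
#' @param reference Positive baseline value(s).
#' @param observed Observed value(s).
#' @param round_int Round to the nearest integer (the reporting convention)?
#' @return Numeric vector of percent changes.
#' @examples
#' percent_change(30.7, 130.4)
#' percent_change(57.0, 213.0)
#' @export
percent_change <- function(reference, observed, round_int = TRUE) {
  if (any(reference <= 0)) stop("reference must be positive", call. = FALSE)
  pc <- 100 * (observed - reference) / reference
  if (round_int) round_half_up(pc, 0) else pc
}

#' Compare one motif's methylome summary between two strains
#'
#' Deltas and percent changes of the per-motif summary between a reference
#' strain and an observed strain (e.g. parental vs deletion mutant), plus a
#' status flag: `abolished` when percent methylated drops from positive to
#' zero (the deletion-phenotype signature), otherwise
#' `unchanged`/`reduced`/`increased` by the raw percent.
#'
#' @param reference,observed One-row [summarize_methylome()] tibbles for the
#'   same motif.
#' @return A one-row tibble: `motif`, `percent_reference`, `percent_observed`,
#'   `delta_percent`, `qv_percent_change`, `coverage_percent_change`,
#'   `status`.
#' @export
compare_strains <- function(reference, observed) {
  if (!identical(reference$motif, observed$motif)) {
    stop(sprintf("motif mismatch: '%s' vs '%s'",
                 reference$motif, observed$motif), call. = FALSE)
  }
  pr <- reference$percent_methylated
  po <- observed$percent_methylated
  status <- dplyr::case_when(
    pr > 0 & po == 0 ~ "abolished",
    po == pr ~ "unchanged",
    po < pr ~ "reduced",
    TRUE ~ "increased"
  )
  tibble::tibble(
    motif = reference$motif,
    percent_reference = pr,
    percent_observed = po,
    delta_percent = po - pr,
    qv_percent_change = if (!is.na(reference$mean_qv) && reference$mean_qv > 0 &&
                            !is.na(observed$mean_qv))
      percent_change(reference$mean_qv, observed$mean_qv) else NA_real_,
    coverage_percent_change = if (!is.na(reference$mean_coverage) &&
                                  reference$mean_coverage > 0 &&
                                  !is.na(observed$mean_coverage))
      percent_change(reference$mean_coverage, observed$mean_coverage) else NA_real_,
    status = status
  )
}
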