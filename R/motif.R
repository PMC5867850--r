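#' Define a degenerate nucleotide motif
#'
#' A degenerate motif is an IUPAC pattern with an optional methylated position
#' (1-based index into the pattern) and methylation type (`"6mA"`, `"4mC"` or
#' `"5mC"`). The two motifs methylated in *Haloferax volcanii* are
#' `C(4mC at 1)TAG` and the bipartite Type I target `GCA(6mA at 3)BNNNNNNVTGC`;
#' see [hvo_motifs()] for ready-made constructors.
#'
#' Input is case-insensitive and RNA `U` is normalized to `T`. If a methylated
#' position is given, the base set at that position must contain `A` for 6mA
#' and `C` for 4mC/5mC.
#'
#' @param pattern String over the IUPAC nucleotide alphabet.
#' @param name Short label; defaults to the normalized pattern.
#' @param methylated_position Optional 1-based index of the methylated base.
#' @param methylation_type Optional, one of `"6mA"`, `"4mC"`, `"5mC"`.
#' @return An object of class `degenerate_motif`: a list with elements
#'   `name`, `pattern`, `methylated_position`, `methylation_type`.
#' @examples
#' parse_motif("CTAG", methylated_position = 1, methylation_type = "4mC")
#' parse_motif("gcabnnnnnnvtgc", methylated_position = 3, methylation_type = "6mA")
#' @export
parse_motif <- function(pattern, name = NULL, methylated_position = NULL,
                        methylation_type = NULL) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  if (!nzchar(pattern)) stop("motif pattern must be non-empty", call. = FALSE)
  pattern <- normalize_nt(pattern, what = "motif pattern")
  if (is.null(name)) name <- pattern
  if (!is.null(methylation_type)) {
    methylation_type <- match.arg(methylation_type, c("6mA", "4mC", "5mC"))
    if (is.null(methylated_position)) {
      stop("`methylation_type` given without `methylated_position`", call. = FALSE)
    }
  }
  if (!is.null(methylated_position)) {
    methylated_position <- as.integer(methylated_position)
    if (is.na(methylated_position) || methylated_position < 1 ||
        methylated_position > nchar(pattern)) {
      stop(sprintf("`methylated_position` must lie in [1, %d]", nchar(pattern)),
           call. = FALSE)
    }
    if (!is.null(methylation_type)) {
      code <- substr(pattern, methylated_position, methylated_position)
      target <- if (methylation_type == "6mA") "A" else "C"
      if (!target %in% iupac_bases(code)) {
        stop(sprintf(
          "methylation type %s requires base %s at position %d, but code '%s' excludes it",
          methylation_type, target, methylated_position, code), call. = FALSE)
      }
    }
  }
  structure(
    list(name = name, pattern = pattern,
         methylated_position = methylated_position,
         methylation_type = methylation_type),
    class = "degenerate_motif"
  )
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat("<degenerate_motif> ", x$name, ": ", x$pattern, sep = "")
  if (!is.null(x$methylated_position)) {
    cat(sprintf(" [%s at %d]", x$methylation_type %||% "methylated",
                x$methylated_position))
  }
  cat("\n")
  invisible(x)
}

#' Reverse complement of a degenerate motif
#'
#' Reverses the pattern and complements each code through the IUPAC table
#' (B<->V, D<->H, N<->N, ...). The methylated position, if present, remaps to
#' `length - position + 1`; the methylation type is unchanged (the methylated
#' base on the opposite strand is the complement's partner).
#'
#' @param m A [parse_motif()] object.
#' @return A `degenerate_motif`.
#' @examples
#' motif_revcomp(parse_motif("GCAB"))$pattern  # "VTGC"
#' @export
motif_revcomp <- function(m) {
  stopifnot(inherits(m, "degenerate_motif"))
  pos <- m$methylated_position
  if (!is.null(pos)) pos <- nchar(m$pattern) - pos + 1L
  structure(
    list(name = paste0("revcomp(", m$name, ")"),
         pattern = revcomp_chr(m$pattern),
         methylated_position = pos,
         methylation_type = m$methylation_type),
    class = "degenerate_motif"
  )
}

#' Is a motif its own reverse complement?
#'
#' Self-reverse-complementary (palindromic) motifs such as CTAG, GATC and
#' GCABNNNNNNVTGC yield one occurrence per strand at each site, so their
#' both-strand occurrence count is exactly twice the forward-strand site count
#' on unambiguous sequence.
#'
#' @param m A [parse_motif()] object.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_palindromic(parse_motif("CTAG"))
#' is_palindromic(parse_motif("GCAB"))
#' @export
is_palindromic <- function(m) {
  stopifnot(inherits(m, "degenerate_motif"))
  identical(motif_revcomp(m)$pattern, m$pattern)
}

#' Canonical Haloferax volcanii methylation motifs
#'
#' The motifs detected as methylated on the *H. volcanii* DS2 genome:
#' `CTAG` (4mC at position 1, deposited by the orphan Type II MTase), `GATC`
#' (the Dam target, not methylated in *H. volcanii* but central to the
#' GATC:CTAG ratio analysis), and the bipartite Type I target
#' `GCABNNNNNNVTGC` (6mA at position 3, deposited by the RmeRMS system).
#' `GCABGNNNNNVTGC` is the variant spelling reported in the earlier methylome
#' study; it is carried as a distinct motif, not merged.
#'
#' @return A named list of `degenerate_motif` objects with elements `ctag`,
#'   `gatc`, `gcab6vtgc` and `gcabg5vtgc`.
#' @examples
#' hvo_motifs()$ctag
#' @export
hvo_motifs <- function() {
  list(
    ctag = parse_motif("CTAG", name = "CTAG",
                       methylated_position = 1, methylation_type = "4mC"),
    gatc = parse_motif("GATC", name = "GATC"),
    gcab6vtgc = parse_motif("GCABNNNNNNVTGC", name = "GCABNNNNNNVTGC",
                            methylated_position = 3, methylation_type = "6mA"),
    gcabg5vtgc = parse_motif("GCABGNNNNNVTGC", name = "GCABGNNNNNVTGC",
                             methylated_position = 3, methylation_type = "6mA")
  )
}

#' Parse a motif definition string
#'
#' Parses the compact `NAME=PATTERN[:POS:TYPE]` syntax used by the command-line
#' wrapper and plain-text motif config files (one motif per line; blank lines
#' and `#` comments ignored).
#'
#' @param spec A definition string, e.g. `"CTAG=CTAG:1:4mC"` or `"GATC=GATC"`.
#' @return A `degenerate_motif`.
#' @examples
#' parse_motif_spec("rme=GCABNNNNNNVTGC:3:6mA")
#' @export
parse_motif_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  spec <- trimws(spec)
  parts <- strsplit(spec, "=", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    name <- NULL
    body <- parts[1]
  } else if (length(parts) == 2) {
    name <- parts[1]
    body <- parts[2]
  } else {
    stop("motif spec must be NAME=PATTERN[:POS:TYPE]", call. = FALSE)
  }
  fields <- strsplit(body, ":", fixed = TRUE)[[1]]
  if (!length(fields) %in% c(1L, 3L)) {
    stop("motif spec body must be PATTERN or PATTERN:POS:TYPE", call. = FALSE)
  }
  parse_motif(fields[1], name = name,
              methylated_position = if (length(fields) == 3) as.integer(fields[2]),
              methylation_type = if (length(fields) == 3) fields[3])
}

#' Read motif definitions from a config file
#'
#' @param path Plain-text file, one `NAME=PATTERN[:POS:TYPE]` entry per line.
#' @return A named list of `degenerate_motif` objects.
#' @export
read_motif_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  motifs <- lapply(lines, parse_motif_spec)
  stats::setNames(motifs, vapply(motifs, `[[`, character(1), "name"))
}
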