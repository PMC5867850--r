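# IUPAC nucleotide code tables and matching semantics.
#
# Each code is represented internally as a 4-bit mask over {A=1, C=2, G=4, T=8}.
# A genome code g matches a pattern code p under the SUBSET rule: the base set
# of g must be contained in the base set of p. An unambiguous C therefore
# matches pattern B = {C,G,T}, while a genome N (= any base) matches only a
# pattern N. This is deliberately conservative on assemblies containing
# ambiguity codes: a run of N never inflates motif counts.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' IUPAC base sets and complements
#'
#' Returns the IUPAC nucleotide code table used throughout the package: for
#' each of the 15 codes, the set of unambiguous bases it denotes and its
#' complementary code (A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H; S, W and N
#' are self-complementary).
#'
#' @return A tibble with columns `code`, `bases` (list-column of character
#'   vectors) and `complement`.
#' @examples
#' iupac_table()
#' @export
iupac_table <- function() {
  tibble::tibble(
    code = IUPAC_CODES,
    bases = purrr::map(IUPAC_CODES, iupac_bases),
    complement = unname(IUPAC_COMPLEMENT[IUPAC_CODES])
  )
}

#' @keywords internal
iupac_bases <- function(code) {
  mask <- IUPAC_MASK[[code]]
  c("A", "C", "G", "T")[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Does a genome base match a pattern code?
#'
#' Subset-matching semantics for degenerate motifs: a genome code matches a
#' pattern code when every base the genome code could be is allowed by the
#' pattern code. Vectorized over both arguments.
#'
#' @param genome_code Character vector of IUPAC codes as read from a genome.
#' @param pattern_code Character vector of IUPAC codes from a motif pattern.
#' @return Logical vector.
#' @examples
#' base_matches("T", "B")  # TRUE: B = {C,G,T}
#' base_matches("T", "V")  # FALSE: V = {A,C,G}
#' base_matches("N", "B")  # FALSE: genome N could be A
#' @export
base_matches <- function(genome_code, pattern_code) {
  g <- IUPAC_MASK[toupper(genome_code)]
  p <- IUPAC_MASK[toupper(pattern_code)]
  if (anyNA(g)) stop("invalid IUPAC code in `genome_code`", call. = FALSE)
  if (anyNA(p)) stop("invalid IUPAC code in `pattern_code`", call. = FALSE)
  unname(bitwAnd(g, bitwXor(p, 15L)) == 0L)
}

# Reverse complement of an IUPAC nucleotide string (plain character version;
# complements ambiguity codes through the code table).
#' @keywords internal
revcomp_chr <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Normalize a nucleotide string: uppercase, RNA U -> T. Returns the string or
# stops naming the first offending character and its position.
#' @keywords internal
normalize_nt <- function(x, what = "sequence") {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% IUPAC_CODES)
  if (length(bad) > 0) {
    stop(sprintf("invalid IUPAC character '%s' at position %d of %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  x
}
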