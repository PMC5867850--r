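# Independent oracles: a character-by-character sliding-window matcher built
# on Biostrings' IUPAC_CODE_MAP (not the package's bitmask tables), a
# Biostrings reverse complement, and a regex-based protein matcher. These
# deliberately share no code with the implementation they check.

iupac_set <- function(code) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "", fixed = TRUE)[[1]]
}

# subset semantics: genome code's base set contained in pattern code's set
oracle_base_match <- function(g, p) {
  all(iupac_set(g) %in% iupac_set(p))
}

# forward-strand match starts by brute force
oracle_scan <- function(sequence, pattern) {
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  n <- length(s)
  L <- length(p)
  if (L > n) return(integer(0))
  hits <- integer(0)
  for (i in 1:(n - L + 1)) {
    ok <- TRUE
    for (j in 1:L) {
      if (!oracle_base_match(s[i + j - 1], p[j])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n, ambiguous = FALSE) {
  alphabet <- c("A", "C", "G", "T")
  prob <- rep(0.25, 4)
  if (ambiguous) {
    alphabet <- c(alphabet, "N", "R", "Y")
    prob <- c(rep(0.31, 4), rep(0.08 / 3, 3))
    prob <- prob / sum(prob)
  }
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

random_iupac_motif <- function(len) {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  prob <- c(rep(0.8 / 4, 4), rep(0.2 / 11, 11))
  paste(sample(codes, len, replace = TRUE, prob = prob), collapse = "")
}

# overlapping protein-pattern starts via regex lookahead; package pattern
# syntax translated to POSIX classes (wildcard excludes X)
oracle_protein_starts <- function(sequence, pattern) {
  rx <- gsub("x", "[ACDEFGHIKLMNPQRSTVWY]", pattern, fixed = TRUE)
  m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}
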