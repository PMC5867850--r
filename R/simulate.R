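# Synthetic genomes, methylomes and proteins with known ground truth.
#
# The background genome model is i.i.d. with P(G) = P(C) = gc/2 and
# P(A) = P(T) = (1-gc)/2, so an unambiguous L-mer's expected forward site
# count is (N - L + 1) * prod(p_i) — e.g. CTAG at gc = 0.5 occurs once per 256
# positions. Motif clusters are planted on top of the background by writing
# concrete realizations of the motif at Poisson-many positions inside the
# cluster window; ground truth records exactly what was planted, so scanners
# can be held to recall 1.0 while incidental background hits remain allowed.

local_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::local_seed(as.integer(seed), .local_envir = parent.frame())
}

# One concrete realization of a degenerate pattern (each ambiguous position
# sampled uniformly from its base set).
realize_pattern <- function(pattern) {
  codes <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(codes, function(code) {
    b <- iupac_bases(code)
    if (length(b) == 1) b else sample(b, 1)
  }, character(1)), collapse = "")
}

#' Simulate a genome with optional planted motif clusters
#'
#' Draws an i.i.d. nucleotide sequence at the requested GC content, then
#' plants motif clusters: for each cluster, the number of planted instances is
#' Poisson with mean `(intensity - 1) * background_rate * width` (so the
#' cluster's total expected density is `intensity` times background), at
#' uniform positions inside the cluster window, each a concrete realization of
#' the motif written over the background. Identical `seed` and arguments give
#' byte-identical output.
#'
#' @param length Genome length in nt.
#' @param gc_content GC fraction in (0, 1); default 0.5.
#' @param clusters Optional tibble/data frame with columns `center`, `width`,
#'   `motif` (a [parse_motif()] object in a list-column, or a pattern string)
#'   and `intensity` (multiplier >= 1).
#' @param topology `"linear"` or `"circular"`.
#' @param replicon_id Name of the simulated replicon.
#' @param seed Integer seed (required; the generator is deterministic).
#' @return A list with `replicons` (a [replicon_table()] tibble) and `truth`
#'   (a tibble of planted instances: `replicon_id`, `motif`, `start`,
#'   `planted_text`).
#' @examples
#' g <- simulate_genome(5000, seed = 1)
#' g$replicons$length
#' @export
simulate_genome <- function(length, gc_content = 0.5, clusters = NULL,
                            topology = "linear", replicon_id = "synth",
                            seed) {
  stopifnot(length >= 1, gc_content > 0, gc_content < 1)
  local_seed(seed)
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  truth <- tibble::tibble(replicon_id = character(0), motif = character(0),
                          start = integer(0), planted_text = character(0))
  if (!is.null(clusters) && nrow(clusters) > 0) {
    for (i in seq_len(nrow(clusters))) {
      m <- clusters$motif[[i]]
      if (is.character(m)) m <- parse_motif(m)
      L <- nchar(m$pattern)
      width <- clusters$width[[i]]
      center <- clusters$center[[i]]
      lo <- as.integer(center - floor(width / 2))
      hi <- as.integer(lo + width - 1L)
      if (lo < 1 || hi > length) {
        stop(sprintf("cluster %d window [%d, %d] outside [1, %d]",
                     i, lo, hi, length), call. = FALSE)
      }
      intensity <- clusters$intensity[[i]]
      stopifnot(intensity >= 1)
      # per-position background probability of the degenerate pattern
      rate <- prod(vapply(strsplit(m$pattern, "", fixed = TRUE)[[1]], function(code) {
        sum(p[iupac_bases(code)])
      }, numeric(1)))
      n_plant <- stats::rpois(1, (intensity - 1) * rate * width)
      n_slots <- hi - lo + 1L - L + 1L
      if (n_plant > floor(n_slots / L) + 1L) {
        stop(sprintf("cluster %d infeasible: %d planted instances for %d positions",
                     i, n_plant, n_slots), call. = FALSE)
      }
      if (n_plant > 0) {
        # sample non-overlapping starts so every planted instance survives
        allowed <- lo:(hi - L + 1L)
        starts <- integer(0)
        for (k in seq_len(n_plant)) {
          if (length(allowed) == 0) {
            stop(sprintf("cluster %d infeasible: %d planted instances for %d positions",
                         i, n_plant, n_slots), call. = FALSE)
          }
          s <- if (length(allowed) == 1) allowed else sample(allowed, 1)
          starts <- c(starts, s)
          allowed <- allowed[abs(allowed - s) >= L]
        }
        starts <- sort(starts)
        for (s in starts) {
          text <- realize_pattern(m$pattern)
          bases[s:(s + L - 1L)] <- strsplit(text, "", fixed = TRUE)[[1]]
          truth <- dplyr::bind_rows(truth, tibble::tibble(
            replicon_id = replicon_id, motif = m$name,
            start = as.integer(s), planted_text = text))
        }
      }
    }
  }
  list(
    replicons = replicon_table(replicon_id, paste(bases, collapse = ""),
                               topology = topology),
    truth = truth
  )
}

#' Simulate SMRT-style modification calls for a motif
#'
#' Enumerates the strand-specific occurrences of the motif across the
#' replicons, marks an independent Bernoulli(`fraction_methylated`) subset as
#' methylated, and emits one call per methylated occurrence at the motif's
#' methylated position on the occurrence's own strand, with truncated-normal
#' QV (>= 0) and coverage (integer >= 1). Defaults for the QV and coverage
#' means follow the magnitudes reported for the 6mA motif in a
#' high-coverage run (QV 213, coverage 130.4); the SDs default to 20% of the
#' mean. Deterministic under `seed`.
#'
#' @param replicons A [replicon_table()] tibble.
#' @param motif A [parse_motif()] object with methylated position and type.
#' @param fraction_methylated Fraction in `[0, 1]`.
#' @param qv_mean,qv_sd,coverage_mean,coverage_sd Call-score distribution
#'   parameters.
#' @param seed Integer seed.
#' @return A list with `calls` (a call tibble, possibly empty) and `truth`
#'   (the occurrence table with a logical `methylated` column).
#' @export
simulate_methylome <- function(replicons, motif, fraction_methylated,
                               qv_mean = 213, qv_sd = 0.2 * qv_mean,
                               coverage_mean = 130.4,
                               coverage_sd = 0.2 * coverage_mean,
                               seed) {
  stopifnot(fraction_methylated >= 0, fraction_methylated <= 1)
  local_seed(seed)
  occ <- methylated_site_table(replicons, motif)
  if (nrow(occ) == 0) {
    warning("motif ", motif$name, " has no occurrences; empty methylome",
            call. = FALSE)
    return(list(
      calls = tibble::tibble(replicon_id = character(0), position = integer(0),
                             strand = character(0), type = character(0),
                             qv = numeric(0), coverage = integer(0)),
      truth = dplyr::mutate(occ, methylated = logical(0))
    ))
  }
  occ$methylated <- stats::runif(nrow(occ)) < fraction_methylated
  meth <- occ[occ$methylated, ]
  n <- nrow(meth)
  calls <- tibble::tibble(
    replicon_id = meth$replicon_id,
    position = meth$methylated_at,
    strand = meth$strand,
    type = rep(motif$methylation_type, n),
    qv = pmax(0, stats::rnorm(n, qv_mean, qv_sd)),
    coverage = pmax(1L, as.integer(round(stats::rnorm(n, coverage_mean, coverage_sd))))
  )
  list(calls = calls, truth = occ)
}

#' Simulate a protein with planted signature motifs
#'
#' Draws a background of residues uniform over the 20 amino acids and writes
#' the requested motif texts at the requested positions. Planted windows must
#' not overlap. Deterministic under `seed`.
#'
#' @param length Protein length in residues.
#' @param planted Optional tibble with columns `text` (exact residue string to
#'   plant) and `start` (1-based position).
#' @param protein_id Sequence name.
#' @param seed Integer seed.
#' @return A list with `proteins` (tibble: `protein_id`, `sequence`) and
#'   `truth` (the planted table).
#' @examples
#' simulate_protein(60, tibble::tibble(text = "SPPY", start = 20), seed = 1)
#' @export
simulate_protein <- function(length, planted = NULL, protein_id = "synthprot",
                             seed) {
  local_seed(seed)
  chars <- sample(AA_ALPHABET, length, replace = TRUE)
  truth <- tibble::tibble(protein_id = character(0), text = character(0),
                          start = integer(0))
  if (!is.null(planted) && nrow(planted) > 0) {
    planted <- dplyr::arrange(tibble::as_tibble(planted), .data$start)
    ends <- planted$start + nchar(planted$text) - 1L
    if (any(planted$start < 1) || any(ends > length)) {
      stop("planted motif outside [1, length]", call. = FALSE)
    }
    if (nrow(planted) > 1 && any(planted$start[-1] <= ends[-nrow(planted)])) {
      stop("planted motifs overlap", call. = FALSE)
    }
    for (i in seq_len(nrow(planted))) {
      s <- planted$start[i]
      text <- toupper(planted$text[i])
      chars[s:(s + nchar(text) - 1L)] <- strsplit(text, "", fixed = TRUE)[[1]]
    }
    truth <- tibble::tibble(protein_id = protein_id,
                            text = toupper(planted$text),
                            start = as.integer(planted$start))
  }
  list(
    proteins = tibble::tibble(protein_id = protein_id,
                              sequence = paste(chars, collapse = "")),
    truth = truth
  )
}
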