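---
title: "Motif landscapes and methylome summaries: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif landscapes and methylome summaries: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halomotif)
library(dplyr)
```

## Scope and model

halomotif characterizes the landscape of short degenerate DNA motifs —
chiefly the methylation targets CTAG, GATC and the bipartite Type I target
GCABN₆VTGC — on microbial replicons, and summarizes SMRT-style base
modification calls against those motifs. Its statistics are deliberately
elementary (counts, ratios, Poisson tail tests, binomial proportions); the
value of the package lies in pinning down the counting conventions that make
published per-chromosome tables and methylome tables mutually consistent, and
in making every stage testable against simulated ground truth.

## Matching semantics

A degenerate motif is a string over the 15 IUPAC codes, each denoting a base
set (`B = {C,G,T}`, `V = {A,C,G}`, `N = {A,C,G,T}`). A genome position
matches a pattern code under the **subset rule**: the genome code's base set
must be contained in the pattern code's set. For unambiguous genome sequence
this is ordinary degenerate matching; for assemblies containing ambiguity
codes it is the conservative choice — a run of `N` in a draft assembly can
never create motif hits (a genome `N` matches only a pattern `N`). The
alternative (intersection semantics, as in `Biostrings::matchPattern` with
`fixed = FALSE`) would count an assembly gap as matching every motif
position. Matching is case-insensitive and RNA `U` is normalized to `T`.

Overlapping matches are all counted. That choice matters for correctness (it
makes the scanner equal a position-by-position sliding-window oracle, the
property the test suite enforces on thousands of random instances) and is the
standard convention for motif counting.

## Strand conventions: sites vs occurrences

Two counts coexist in the published tables and are easy to conflate:

* **site count** — forward-strand matches only. This is the convention of the
  per-chromosome frequency table (671 CTAG on the *H. volcanii* DS2
  chromosome) and of the per-kb and ratio columns derived from it.
* **occurrence count** — strand-specific matches on both strands. All three
  motifs here are self-reverse-complementary (palindromic under IUPAC
  complementation, with B↔V), so each site yields exactly one occurrence per
  strand and the occurrence count is `2 × site_count` on unambiguous
  sequence. This is the methylome-table denominator: 1342 CTAG occurrences =
  2 × 671 sites.

Only this pairing makes the two published tables consistent with each other,
which is why `count_motifs()` reports both. Reverse-strand hits are found by
scanning the reverse-complement pattern on the forward strand; `start` is
always the forward-strand coordinate of the leftmost matched base, and for a
reverse-strand occurrence the methylated base at pattern position *p* sits at
forward coordinate `start + L − p` (position 3 of GCABN₆VTGC maps to
forward offset 12).

Replicons are linear by default — matching the behaviour implied by the
published counts — with circular topology available per replicon, in which
case the origin-spanning junction is scanned once without double-reporting.

## Rounding and summary conventions

Printed tables use half-up decimal rounding (2 decimals for per-kb columns, 1
for ratios, nearest integer for percentages); base R's banker's rounding
would disagree on exact ties, so the package exposes `round_half_up()` and
uses it for all display values, always alongside the raw value. All 47
printed ratio cells reproduce from the printed counts under this convention.

The published summary rows posed one genuine ambiguity: whether the SD row
uses the sample (n−1) or population (n) denominator. Recomputing both from
the printed per-chromosome values settles it empirically — the printed SDs
(0.19, 3.35, 12.7) match the population form (0.191, 3.349, 12.673), not the
sample form (0.193, 3.385, 12.810) — so `column_summary()` reports both and
the acceptance checks assert the population SD.

`classify_ratio()` implements the published band scheme: below 5, 5–14
(inclusive at both ends), above 20. The scheme leaves (14, 20] undefined;
rather than force such chromosomes into a neighbouring band the package
labels them `intermediate`. The published prose once lists chromosomes with a
printed ratio of exactly 5.0 among those "below five"; the caption's
thresholds are followed instead, so 5.0 lands in the 5–14 band.

## Window enrichment

`windowed_density()` formalizes the visual claim that motif density rises
near one origin of replication. Each window's forward-site count is tested
against `Poisson(rate × width)` with the replicon-wide rate, upper tail
`P(X ≥ observed)`, BH-adjusted across the windows of one replicon. Defaults
are 10 kb tiling windows (`step = window`), under which window counts sum
exactly to the site count (hits are assigned by their start coordinate, and
the partial tail window is kept). The test is conservative under the null —
discrete p-values plus BH yield an observed false-positive rate well under
the nominal 5%, which the acceptance suite verifies over 200 simulated null
genomes (50 kb each, 5 kb windows; sizes chosen as the package's test scale).
Because the expected count uses the replicon-wide rate, a very large planted
cluster slightly inflates the background rate and the test understates
enrichment; at the cluster intensities simulated here the cluster window
still attains the minimum q-value.

## Methylome summaries

A modification call matches a motif occurrence only when replicon, exact
position, strand and modification type all agree — no positional tolerance.
Strictness keeps the definition testable and reversible; a tolerance could
silently absorb off-by-one errors in either the caller or the scanner. No
QV or coverage thresholding is applied by default, since published
strain-to-strain differences in detection were attributed to coverage rather
than to caller thresholds; `min_qv`/`min_coverage` are exposed for users who
want them. Percentages are displayed to the nearest integer (the convention
of the published strain table: 77, 89, 100) with the raw value retained.

The strain comparison reports deltas, percent changes of mean QV and mean
coverage (e.g. 30.7 → 130.4 is a 325% increase), and a status flag in which
`abolished` — percent methylated dropping from positive to zero — is the
deletion-mutant signature of interest.

Two reference numbers from the predecessor study (the 77% baseline, coverage
30.7, QV 57.0) are treated as external inputs, never recomputed. Likewise the
alternative motif spelling GCABGN₅VTGC reported there is carried as a
distinct motif (`hvo_motifs()$gcabg5vtgc`), not merged with GCABN₆VTGC; the
two strings genuinely differ and the package does not guess which was
intended where.

## Protein signatures

The signature patterns are small fixed-length degenerate amino-acid patterns
chosen to cover exactly the canonical spellings plus the variants observed in
characterized MTase alignments: `[DNSE]PP[YFW]` for the AdoMet-binding
DPPY family (covers SPPY, NPPY, NPPF), `[FAWY]xGxG` for the catalytic
FxGxG/"FGG" family (covers the AGG-spelled variant), and the 5mC signature
set PC, ENV, QRR, `[YRL]GN`. The wildcard `x` matches any of the 20 residues
but never `X` (unknown residue). Residue sets are configurable because no
formal tolerance for these signatures exists.

Classification is a *hint*, not a subtype call: both DPPY- and FGG-family
hits make a protein `amino_MTase_like`, and the FGG-before-DPPY order is
noted as consistent with the REBASE α/β/γ orders — deliberately without
asserting a unique subtype, which would require full motif-order and TRD
context from alignments that this package does not compute. A protein is
`five_mC_like` when at least four of the five 5mC signatures occur in their
canonical N→C order (found by a small dynamic program over the ordered
categories); requiring the order keeps the frequent PC dipeptide from
generating false positives on its own.

## The synthetic-data generator

`simulate_genome()` draws i.i.d. bases with `P(G) = P(C) = gc/2`, so an
unambiguous L-mer's expected forward count is `(N − L + 1)·∏pᵢ` — CTAG at
GC 0.5 occurs once per 256 positions — and Monte-Carlo counts are checked
against that formula within three standard errors. Clusters plant
`Poisson((intensity − 1)·rate·width)` additional motif realizations at
non-overlapping positions inside the window (non-overlap guarantees every
planted instance survives and scanner recall can be held to exactly 1.0;
overlap with incidental background hits is permitted and the ground-truth
table records exactly what was planted). `simulate_methylome()` marks a
Bernoulli(f) subset of strand-specific occurrences methylated and emits one
call per methylated occurrence at the correct position and strand; QV and
coverage are independent truncated normals (QV ≥ 0, coverage ≥ 1) whose
means default to the published high-coverage 6mA magnitudes (213, 130.4) and
whose SDs default to 20% of the mean — the published tables report only
means, so the shape is a free choice made once. All generators are
deterministic under their `seed`.

What the generator does **not** model: dinucleotide/codon structure, GC skew,
replication-strand asymmetries, read-level noise (no FASTQ/BAM), and kinetic
IPD signal. Passing tests therefore demonstrate the counting, enrichment and
summarization machinery — not that real halobacterial genomes are i.i.d.
Real-data idiosyncrasies (compositional bias around origins, coverage dips)
must be judged on real inputs.

## Numerical and degenerate-input choices

* Half-up rounding throughout display columns; raw values always retained.
* A zero CTAG count makes the ratio undefined: the record is flagged
  (`ratio_defined = FALSE`) and kept, never dropped.
* `per_kb` uses the full replicon length including ambiguous bases — the
  simplest reproducible convention.
* A window wider than its replicon degrades to one whole-replicon window with
  a warning; a motif longer than its replicon yields zero hits with a warning.
* Empty modification-call files parse to empty tables with a warning;
  malformed rows and unknown strand symbols (including `.`) are hard errors
  with the offending line identified.
* Poisson tail at zero expectation gives p = 1, so motif-free replicons can
  never be called enriched.

## Problem sizes used in the checks

The automated checks run at desk scale: scanner-vs-oracle equivalence on
1000 random instances (≤ 300 nt), the Monte-Carlo count check on 100
replicates of 256 kb, the null false-positive rate on 200 genomes of 50 kb,
fraction recovery on a 500 kb genome (≈ 4000 CTAG occurrences) across
f ∈ {0, 0.25, 0.5, 0.89, 1}, and signature recall on 20 proteins of 300
residues. One check — the published genome-scale counts (671/1851/1342) on
the real DS2 chromosome — needs the ~2.8 Mb reference sequence on disk and
reports a failure when it is absent; everything required to run it is in
place once `inst/extdata/NC_013967.1.fasta` exists.

## Known limitations

Approximate/mismatch matching, PWM scoring, origin prediction, skew analyses,
homology search, alignment and kinetic modification calling are out of scope;
origins are user-supplied annotation coordinates, and modification calls are
consumed, never produced. The scanner is pure vectorized R — linear in
`N × L` and comfortably fast to tens of megabases, but not the right tool for
metagenome-scale scans.
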