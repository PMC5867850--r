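Package: halomotif
Title: Degenerate Motif Landscapes and SMRT Methylome Summaries for
    Halobacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing DNA methylation motif landscapes in
    archaeal (and other microbial) genomes. Scans replicons for degenerate
    IUPAC motifs such as CTAG, GATC and the bipartite Type I target
    GCABNNNNNNVTGC with explicit strand semantics, computes per-kilobase
    frequencies, GATC:CTAG ratios with ratio classes, cumulative motif
    occurrence profiles and Poisson window-enrichment tests; summarizes
    SMRT-style base-modification calls into per-motif methylome tables
    (percent methylated, mean modification QV, mean coverage) and
    strain-vs-strain comparisons; detects methyltransferase signature motifs
    (DPPY, FxGxG, and the 5mC signature set) in protein sequences; and
    generates synthetic genomes, methylomes and proteins with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
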