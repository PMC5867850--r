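# A tiny replicon with exactly one bipartite 6mA site and two CTAG sites,
# built in code, drives most matching checks.
tiny_replicons <- function() {
  #        1234567890123456789012
  replicon_table("chr", "GCATAAAAAAGTGCCTAGACTAG")
}

test_that("csv dialect reads, validates and round-trips", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("replicon,position,strand,type,qv,coverage",
               "chr,100,+,m6A,213,130"), csv)
  calls <- read_modification_calls(csv, "csv")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "6mA")
  expect_equal(calls$qv, 213)
  expect_equal(calls$coverage, 130L)

  out <- withr::local_tempfile(fileext = ".csv")
  write_modification_calls(calls, out, "csv")
  expect_equal(read_modification_calls(out, "csv"), calls)
})

test_that("malformed csv rows error with their line number", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("replicon,position,strand,type,qv,coverage",
               "chr,100,+,m6A,213,130",
               "chr,oops,+,m6A,10,5"), csv)
  expect_error(read_modification_calls(csv, "csv"), "line 3")
})

test_that("unknown strand and type symbols are rejected", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("replicon,position,strand,type,qv,coverage",
               "chr,100,.,m6A,213,130"), csv)
  expect_error(read_modification_calls(csv, "csv"), "strand")

  csv2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("replicon,position,strand,type,qv,coverage",
               "chr,100,+,m7G,213,130"), csv2)
  expect_error(read_modification_calls(csv2, "csv"), "unknown modification type")
})

test_that("empty call files yield an empty table with a warning", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines("replicon,position,strand,type,qv,coverage", csv)
  expect_warning(calls <- read_modification_calls(csv, "csv"), "empty")
  expect_equal(nrow(calls), 0)
})

test_that("gff3 dialect round-trips and rejects strandless features", {
  calls <- tibble::tibble(
    replicon_id = c("chr", "chr"), position = c(3L, 12L),
    strand = c("+", "-"), type = c("6mA", "6mA"),
    qv = c(213, 120.5), coverage = c(130L, 99L)
  )
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_modification_calls(calls, gff, "gff3")
  back <- read_modification_calls(gff, "gff3")
  expect_equal(back, calls)

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tkinModCall\tm6A\t100\t100\t213\t.\t.\tcoverage=130"), bad)
  expect_error(read_modification_calls(bad, "gff3"), "strand")
})

test_that("occurrences are methylated only by exact position/strand/type calls", {
  reps <- tiny_replicons()
  m6 <- hvo_motifs()$gcab6vtgc
  # one palindromic bipartite site at 1..14: '+' occurrence methylated at 3,
  # '-' occurrence methylated at 1 + 14 - 3 = 12
  both <- tibble::tibble(
    replicon_id = "chr", position = c(3L, 12L), strand = c("+", "-"),
    type = "6mA", qv = c(200, 220), coverage = c(120L, 140L)
  )
  s <- summarize_methylome(both, reps, m6)
  expect_equal(s$n_genome, 2L)
  expect_equal(s$n_methylated, 2L)
  expect_equal(s$percent_methylated_int, 100)
  expect_equal(s$mean_qv, mean(c(200, 220)))
  expect_equal(s$mean_coverage, mean(c(120, 140)))

  # wrong strand, wrong position, wrong type: none count
  wrong <- tibble::tibble(
    replicon_id = "chr", position = c(3L, 11L, 12L), strand = c("-", "-", "-"),
    type = c("6mA", "6mA", "4mC"), qv = 200, coverage = 100L
  )
  s0 <- summarize_methylome(wrong, reps, m6)
  expect_equal(s0$n_methylated, 0L)
  expect_equal(s0$percent_methylated, 0)
  expect_true(is.na(s0$mean_qv) && is.na(s0$mean_coverage))
})

test_that("denominator equals the both-strand occurrence count", {
  withr::local_seed(411)
  g <- simulate_genome(30000, seed = 412)
  m <- hvo_motifs()$ctag
  counts <- count_motifs(g$replicons, m)
  s <- summarize_methylome(
    tibble::tibble(replicon_id = character(0), position = integer(0),
                   strand = character(0), type = character(0),
                   qv = numeric(0), coverage = integer(0)),
    g$replicons, m)
  expect_equal(s$n_genome, counts$occurrence_count)
})

test_that("motifs without methylation metadata are rejected", {
  expect_error(
    summarize_methylome(tibble::tibble(replicon_id = character(0),
                                       position = integer(0),
                                       strand = character(0),
                                       type = character(0), qv = numeric(0),
                                       coverage = integer(0)),
                        tiny_replicons(), parse_motif("GATC")),
    "methylated position"
  )
})

test_that("qv/coverage thresholds filter calls when requested", {
  reps <- tiny_replicons()
  m6 <- hvo_motifs()$gcab6vtgc
  calls <- tibble::tibble(
    replicon_id = "chr", position = c(3L, 12L), strand = c("+", "-"),
    type = "6mA", qv = c(30, 220), coverage = c(120L, 10L)
  )
  expect_equal(summarize_methylome(calls, reps, m6)$n_methylated, 2L)
  expect_equal(summarize_methylome(calls, reps, m6, min_qv = 50)$n_methylated, 1L)
  expect_equal(summarize_methylome(calls, reps, m6,
                                   min_coverage = 50)$n_methylated, 1L)
})

test_that("percent reporting and percent change match the printed conventions", {
  expect_equal(round_half_up(100 * 1199 / 1342), 89)
  expect_equal(round_half_up(100 * 410 / 410), 100)
  expect_equal(percent_change(30.7, 130.4), 325)
  expect_equal(percent_change(57.0, 213.0), 274)
  expect_equal(percent_change(42, 42), 0)
  expect_error(percent_change(0, 10), "positive")
})

test_that("strain comparison flags abolished/unchanged/reduced/increased", {
  reps <- tiny_replicons()
  m6 <- hvo_motifs()$gcab6vtgc
  full <- tibble::tibble(replicon_id = "chr", position = c(3L, 12L),
                         strand = c("+", "-"), type = "6mA",
                         qv = 213, coverage = 130L)
  none <- full[0, ]
  half <- full[1, ]
  a <- summarize_methylome(full, reps, m6)
  b <- summarize_methylome(none, reps, m6)
  h <- summarize_methylome(half, reps, m6)

  expect_equal(compare_strains(a, b)$status, "abolished")
  expect_equal(compare_strains(a, a)$status, "unchanged")
  expect_equal(compare_strains(a, h)$status, "reduced")
  expect_equal(compare_strains(h, a)$status, "increased")
  expect_equal(compare_strains(a, b)$delta_percent, -100)

  cmp <- compare_strains(
    dplyr::mutate(a, mean_coverage = 30.7, mean_qv = 57),
    dplyr::mutate(a, mean_coverage = 130.4, mean_qv = 213))
  expect_equal(cmp$coverage_percent_change, 325)
  expect_equal(cmp$qv_percent_change, 274)

  expect_error(compare_strains(a, summarize_methylome(none, reps,
                                                      hvo_motifs()$ctag)),
               "motif mismatch")
})

test_that("summary means equal a brute-force recomputation over matched calls", {
  g <- simulate_genome(40000, seed = 413)
  m <- hvo_motifs()$ctag
  sim <- simulate_methylome(g$replicons, m, 0.5, seed = 414)
  s <- summarize_methylome(sim$calls, g$replicons, m)
  expect_equal(s$n_methylated, sum(sim$truth$methylated))
  expect_equal(s$mean_qv, mean(sim$calls$qv))
  expect_equal(s$mean_coverage, mean(sim$calls$coverage))
})
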