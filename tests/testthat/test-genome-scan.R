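test_that("scan_motif reports all overlapping matches with strand semantics", {
  expect_equal(
    scan_motif(replicon_table("r", "AAAA"), parse_motif("AA"),
               strands = "forward")$start,
    c(1L, 2L, 3L)
  )
  expect_equal(
    scan_motif(replicon_table("r", "CTAGGCTAGT"), parse_motif("CTAG"),
               strands = "forward")$start,
    c(1L, 6L)
  )
  # bipartite degenerate motif, palindromic: one occurrence per strand
  hits <- scan_motif(replicon_table("r", "GCATAAAAAAGTGC"),
                     parse_motif("GCABNNNNNNVTGC"), strands = "both")
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(hits$start, c(1L, 1L))
})

test_that("production scanner equals the brute-force oracle", {
  withr::local_seed(403)
  for (i in 1:150) {
    n <- sample(20:500, 1)
    s <- random_dna(n, ambiguous = i %% 3 == 0)
    pat <- random_iupac_motif(sample(2:20, 1))
    reps <- replicon_table("r", s)
    got <- scan_motif(reps, parse_motif(pat), strands = "forward")$start
    expect_equal(got, oracle_scan(s, pat))
  }
})

test_that("palindromic motifs double exactly on unambiguous sequence", {
  withr::local_seed(404)
  motifs <- hvo_motifs()[c("ctag", "gatc", "gcab6vtgc")]
  for (i in 1:10) {
    reps <- replicon_table("r", random_dna(5000))
    counts <- count_motifs(reps, motifs)
    expect_equal(counts$occurrence_count, 2L * counts$site_count)
  }
})

test_that("forward count is invariant under joint reverse complement", {
  withr::local_seed(405)
  for (i in 1:20) {
    s <- random_dna(sample(50:300, 1))
    m <- parse_motif(random_iupac_motif(sample(2:6, 1)))
    c1 <- nrow(scan_motif(replicon_table("r", s), m, strands = "forward"))
    c2 <- nrow(scan_motif(replicon_table("r", oracle_revcomp(s)),
                          motif_revcomp(m), strands = "forward"))
    expect_equal(c1, c2)
  }
})

test_that("circular topology scans the junction without double-reporting", {
  # CTAG split across the origin: ...CT | AG...
  reps_circ <- replicon_table("r", "AGGGGGCT", topology = "circular")
  hits <- scan_motif(reps_circ, parse_motif("CTAG"), strands = "forward")
  expect_equal(hits$start, 7L)
  # equivalent linear construction, deduplicated
  withr::local_seed(406)
  for (i in 1:10) {
    s <- random_dna(100)
    pat <- random_iupac_motif(4)
    circ <- scan_motif(replicon_table("r", s, topology = "circular"),
                       parse_motif(pat), strands = "forward")$start
    ext <- oracle_scan(paste0(s, substr(s, 1, 3)), pat)
    expect_equal(circ, as.integer(ext[ext <= 100]))
  }
  # linear scan of same sequence reports no junction hit
  reps_lin <- replicon_table("r", "AGGGGGCT")
  expect_equal(nrow(scan_motif(reps_lin, parse_motif("CTAG"))), 0)
})

test_that("motif longer than replicon warns and returns no hits", {
  expect_warning(
    hits <- scan_motif(replicon_table("r", "ACG"), parse_motif("GCABNNNNNNVTGC")),
    "longer than replicon"
  )
  expect_equal(nrow(hits), 0)
})

test_that("count_motifs reports per-kb frequency with half-up display rounding", {
  # 10 kb with exactly 24 planted CTAG sites and an A-only background
  unit <- paste0("CTAG", strrep("A", 412))
  s <- paste0(strrep(unit, 24), strrep("A", 10000 - 24 * nchar(unit)))
  expect_equal(nchar(s), 10000)
  counts <- count_motifs(replicon_table("r", s), parse_motif("CTAG"))
  expect_equal(counts$site_count, 24L)
  expect_equal(counts$per_kb, 2.4)
  expect_equal(counts$per_kb_2dp, 2.40)
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(0.245, 2), 0.25)
  expect_equal(round_half_up(2.75, 1), 2.8)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  # banker's rounding would give 0.24 / 2.7 here
})

test_that("ratio_table reproduces printed ratio cells from counts", {
  counts <- tibble::tibble(
    replicon_id = rep(c("hvo", "eco", "htr"), each = 2),
    motif = rep(c("CTAG", "GATC"), 3),
    length = 1e6,
    site_count = c(671L, 1851L, 885L, 19124L, 426L, 19948L),
    occurrence_count = 2L * site_count,
    per_kb = 1000 * site_count / length,
    per_kb_2dp = round_half_up(per_kb, 2)
  )
  rt <- ratio_table(counts)
  expect_equal(rt$ratio_1dp[match(c("hvo", "eco", "htr"), rt$replicon_id)],
               c(2.8, 21.6, 46.8))
  expect_equal(as.character(rt$ratio_class[rt$replicon_id == "hvo"]), "below_5")
})

test_that("zero denominator flags the record instead of dropping it", {
  counts <- tibble::tibble(
    replicon_id = rep("r", 2), motif = c("CTAG", "GATC"), length = 1000,
    site_count = c(0L, 10L), occurrence_count = c(0L, 20L),
    per_kb = c(0, 10), per_kb_2dp = c(0, 10)
  )
  expect_warning(rt <- ratio_table(counts), "ratio undefined")
  expect_equal(nrow(rt), 1)
  expect_false(rt$ratio_defined)
  expect_true(is.na(rt$ratio))
})

test_that("classify_ratio follows the band scheme including the unnamed gap", {
  expect_equal(as.character(classify_ratio(c(2.8, 6.3, 17.0, 21.6))),
               c("below_5", "from_5_to_14", "intermediate", "above_20"))
  # boundaries: 5 and 14 belong to the middle band, 20 to the gap
  expect_equal(as.character(classify_ratio(c(4.999, 5, 14, 14.001, 20, 20.001))),
               c("below_5", "from_5_to_14", "from_5_to_14", "intermediate",
                 "intermediate", "above_20"))
  expect_error(classify_ratio(0), "positive")
  expect_error(classify_ratio(-1), "positive")
})

test_that("cumulative occurrence is a conserved non-decreasing step function", {
  cum <- cumulative_occurrence(replicon_table("r", "CTAGCTAG"),
                               parse_motif("CTAG"))
  expect_equal(cum$position, c(1L, 5L))
  expect_equal(cum$cumulative, c(1L, 2L))

  empty <- cumulative_occurrence(replicon_table("r", strrep("A", 100)),
                                 parse_motif("CTAG"))
  expect_equal(nrow(empty), 0)

  withr::local_seed(407)
  for (i in 1:10) {
    reps <- replicon_table("r", random_dna(3000))
    m <- parse_motif(random_iupac_motif(3))
    cum <- cumulative_occurrence(reps, m)
    counts <- count_motifs(reps, m)
    expect_equal(nrow(cum), counts$site_count)
    if (nrow(cum) > 0) {
      expect_true(all(diff(cum$cumulative) == 1))
      expect_true(!is.unsorted(cum$position))
      expect_equal(max(cum$cumulative), counts$site_count)
    }
  }
})

test_that("a planted cluster steepens the cumulative slope above background", {
  cl <- tibble::tibble(center = 45001, width = 10000,
                       motif = list(parse_motif("CTAG")), intensity = 5)
  g <- simulate_genome(100000, clusters = cl, seed = 408)
  cum <- cumulative_occurrence(g$replicons, parse_motif("CTAG"))
  in_cluster <- sum(cum$position >= 40001 & cum$position <= 50000)
  global_rate <- nrow(cum) / 100000
  expect_gt(in_cluster / 10000, global_rate)
})

test_that("windowed density conserves counts over a tiling and bounds p in (0,1]", {
  withr::local_seed(409)
  reps <- replicon_table("r", random_dna(25000))
  m <- parse_motif("CTAG")
  wd <- windowed_density(reps, m, window = 4000)  # partial tail window
  expect_equal(sum(wd$observed), count_motifs(reps, m)$site_count)
  expect_true(all(wd$p_value > 0 & wd$p_value <= 1))
  expect_true(all(wd$q_value >= wd$p_value))
  expect_equal(wd$window_start[2], 4001)
  expect_equal(max(wd$window_end), 25000)
})

test_that("window wider than the replicon falls back to one window with warning", {
  reps <- replicon_table("r", strrep("ACTG", 100))
  expect_warning(wd <- windowed_density(reps, parse_motif("CTAG"),
                                        window = 10000), "whole-replicon")
  expect_equal(nrow(wd), 1)
  expect_equal(c(wd$window_start, wd$window_end), c(1L, 400L))
})

test_that("column_summary reports mean with sample and population SDs", {
  cs <- column_summary(c(1, 1, 1), name = "const")
  expect_equal(cs$mean, 1)
  expect_equal(cs$sd_sample, 0)
  expect_equal(cs$sd_population, 0)

  withr::local_seed(410)
  v <- rnorm(20)
  cs <- column_summary(v)
  expect_equal(cs$mean, mean(v))
  expect_equal(cs$sd_sample, sd(v))
  expect_equal(cs$sd_population, sd(v) * sqrt(19 / 20))
  expect_gte(cs$sd_sample, cs$sd_population)

  expect_true(is.na(column_summary(5)$sd_sample))
})
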