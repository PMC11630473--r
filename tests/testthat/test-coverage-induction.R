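# Detection stage: alignment filters, segmenting, background statistics,
# window calling, merging and border refinement.

test_that("alignment filtering applies all four thresholds", {
  rec <- data.frame(
    read_id = paste0("r", 1:5), contig = "c1", start = 0L,
    end = c(120L, 120L, 40L, 120L, 120L),
    identity = c(0.995, 0.985, 0.999, 0.999, 0.995),
    read_fraction = c(0.9, 0.9, 0.9, 0.7, 0.9),
    is_primary = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  kept <- filter_alignments(rec)
  expect_equal(kept$read_id, "r1")
  # boundary values are inclusive
  edge <- data.frame(read_id = "e", contig = "c1", start = 0L, end = 50L,
                     identity = 0.99, read_fraction = 0.80,
                     is_primary = TRUE)
  expect_equal(nrow(filter_alignments(edge)), 1L)
  # malformed records skipped with a warning, not an error
  bad <- rbind(rec, data.frame(read_id = "x", contig = "c1", start = 0L,
                               end = NA, identity = 1, read_fraction = 1,
                               is_primary = TRUE))
  expect_warning(out <- filter_alignments(bad), "malformed")
  expect_equal(attr(out, "n_malformed"), 1L)
})

test_that("sample QC uses a strict read-count threshold", {
  expect_false(sample_qc(250000))
  expect_true(sample_qc(250001))
  expect_false(sample_qc(0))
})

test_that("contig segmenting slices long contigs and assigns roles", {
  segs <- segment_contigs(c(chr = 900000L))
  expect_equal(nrow(segs), 3L)
  expect_equal(segs$end - segs$start, rep(300000L, 3))
  expect_true(all(segs$role == "background_eligible"))

  expect_equal(segment_contigs(c(a = 300000L))$role, "background_eligible")
  expect_equal(segment_contigs(c(a = 60000L))$role, "plasmid_candidate")
  expect_equal(segment_contigs(c(a = 3000L))$role, "too_short")

  # remainder is absorbed by the last slice; slices tile the contig
  s2 <- segment_contigs(c(b = 700001L))
  expect_equal(nrow(s2), 3L)
  expect_equal(s2$start[1], 0L)
  expect_equal(s2$end[3], 700001L)
  expect_true(all(s2$start[-1] == s2$end[-3]))
})

test_that("background statistics match their definition on known cases", {
  expect_equal(background_stats(rep(10, 100)),
               list(median = 10, corrected_std = 0, n_bases_used = 100L))
  st <- background_stats(c(10, 10, 10, 100))
  expect_equal(st$median, 10)
  expect_equal(st$corrected_std, 0)
  expect_equal(st$n_bases_used, 3L)
  st2 <- background_stats(c(4, 6, 8, 10, 12))
  expect_equal(st2$median, 8)
  expect_equal(st2$corrected_std, sqrt(8))
  expect_error(background_stats(integer(0)), "empty")
})

test_that("background statistics equal the filter-then-SD oracle", {
  set.seed(31)
  for (i in 1:50) {
    d <- rnbinom(sample(50:500, 1), mu = runif(1, 5, 80),
                 size = runif(1, 1, 30))
    got <- background_stats(d)
    want <- oracle_background_stats(d)
    expect_equal(got$median, want$median)
    expect_equal(got$corrected_std, want$corrected_std)
    expect_equal(got$n_bases_used, want$n_bases_used)
  }
})

test_that("plasmid rule compares contig median against genome median + 1 SD", {
  mk <- function(med, spread) rep(c(med - spread, med, med + spread), 4000)
  expect_true(call_plasmid_contig(mk(120, 30), genome_median = 50))
  expect_false(call_plasmid_contig(mk(60, 30), genome_median = 50))
  # exactly median + 1 SD is not flagged (strict >)
  d <- rep(50, 12000)
  expect_false(call_plasmid_contig(d, genome_median = 50))
  expect_error(call_plasmid_contig(rep(10, 1000), 50), "size range")
})

test_that("sliding windows cover full windows only", {
  w <- sliding_window_means(rep(20, 1000))
  expect_true(all(w$mean == 20))
  expect_equal(nrow(sliding_window_means(rep(5, 250))), 1L)
  expect_equal(sliding_window_means(rep(5, 300))$start, c(0L, 50L))
  expect_equal(nrow(sliding_window_means(rep(5, 249))), 0L)
  # window means average exactly their 250 bases
  d <- c(rep(10, 250), rep(20, 250))
  w2 <- sliding_window_means(d)
  expect_equal(w2$mean[1], 10)
  expect_equal(w2$mean[w2$start == 250], 20)
})

test_that("two-pass region calling uses length-dependent stringency", {
  stats <- list(median = 50, corrected_std = 10)
  mkwin <- function(n_above, level, n_total = 100, at = 40) {
    m <- rep(50, n_total)
    m[at:(at + n_above - 1)] <- level
    data.frame(start = seq(0, by = 50, length.out = n_total), mean = m)
  }
  # 2200 bp span at median + 2 SD -> pass 1
  r1 <- call_high_coverage_regions(mkwin(40, 70), stats)
  expect_equal(nrow(r1), 1L)
  expect_gt(r1$end - r1$start, 1500)
  # 800 bp span at median + 2 SD -> nothing (short elements need 3 SD)
  expect_equal(nrow(call_high_coverage_regions(mkwin(12, 70), stats)), 0L)
  # 800 bp span at median + 4 SD -> pass 2
  r2 <- call_high_coverage_regions(mkwin(12, 90), stats)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$end - r2$start, 12 * 50 + 200)
  # no element is ever shorter than 500 bp
  for (k in 1:10) {
    r <- call_high_coverage_regions(mkwin(k, 95), stats)
    if (nrow(r)) expect_true(all(r$end - r$start >= 500))
  }
})

test_that("element merging combines close calls and links across contigs", {
  els <- data.frame(contig = "c1", start = c(1000, 2500), end = c(2000, 4000),
                    source = "induction", mean_coverage = c(100, 200))
  m <- merge_elements(els, c(c1 = 10000L))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1000, 4000))
  expect_equal(m$mean_coverage, (100 * 1000 + 200 * 1500) / 2500)

  # gap of exactly 1000 is not merged (strictly less than)
  els2 <- data.frame(contig = "c1", start = c(1000, 3000),
                     end = c(2000, 4000), source = "induction",
                     mean_coverage = 100)
  expect_equal(nrow(merge_elements(els2, c(c1 = 10000L))), 2L)

  # cross-contig neighbours are linked, never concatenated
  els3 <- data.frame(contig = c("c1", "c2"), start = c(8000, 0),
                     end = c(9900, 1500), source = "induction",
                     mean_coverage = 100)
  m3 <- merge_elements(els3, c(c1 = 10000L, c2 = 50000L))
  expect_equal(nrow(m3), 2L)
  expect_equal(m3$cross_contig_link[1], m3$element_id[2])
  expect_equal(m3$cross_contig_link[2], m3$element_id[1])

  # idempotent
  m_again <- merge_elements(m3[, c("contig", "start", "end", "source",
                                   "mean_coverage")],
                            c(c1 = 10000L, c2 = 50000L))
  expect_equal(m_again$start, m3$start)
  expect_equal(m_again$end, m3$end)
})

test_that("border refinement follows the clip > coverage > gene-span hierarchy", {
  cfg <- simulation_config(
    seed = 41, contig_lengths = 100000L, background_mean = 50,
    dispersion = 20,
    planted_elements = data.frame(contig = 1, start = 10000, end = 25000,
                                  fold = 5, realm = "tailed"))
  sim <- simulate_depth_profile(cfg)
  clips <- simulate_clipped_alignments(sim$truth, 3, 150, seed = 42)
  el <- list(start = 9900, end = 25150, source = "induction")

  # tier 1: clips recover the planted borders exactly
  b1 <- refine_borders(el, clips = clips, depths = sim$depth[[1]])
  expect_equal(b1[c("start", "end")], list(start = 10000L, end = 25000L))
  expect_equal(b1$border_method, "clip")

  # tier 2: a sharp coverage step is recovered within one window step
  b2 <- refine_borders(el, clips = NULL, depths = sim$depth[[1]])
  expect_equal(b2$border_method, "coverage")
  expect_lt(abs(b2$start - 10000), 50)
  expect_lt(abs(b2$end - 25000), 50)

  # tier 3: inactive island falls back to the first-to-last gene span
  genes <- data.frame(start = c(7000, 9000, 14100), end = c(7900, 9800, 14950))
  b3 <- refine_borders(list(start = 6800, end = 15200, source = "island"),
                       island = c(6800, 15200), genes = genes)
  expect_equal(b3[c("start", "end")], list(start = 7000, end = 14950))
  expect_equal(b3$border_method, "gene_span")

  # nothing available: raw borders kept with a warning
  expect_warning(
    b4 <- refine_borders(list(start = 100, end = 900, source = "island")),
    "no border evidence")
  expect_equal(b4$border_method, "raw")
})

test_that("detection finds planted elements and nothing on null genomes", {
  cfg <- simulation_config(
    seed = 43, contig_lengths = 400000L, background_mean = 50,
    dispersion = 5,
    planted_elements = data.frame(contig = 1,
                                  start = c(50000, 200000),
                                  end = c(60000, 204000),
                                  fold = c(8, 5),
                                  realm = c("tailed", "tailless")))
  det <- detect_induced_elements(simulate_depth_profile(cfg)$depth)
  expect_equal(nrow(det$elements), 2L)
  expect_lt(abs(det$elements$start[1] - 50000), 300)
  expect_lt(abs(det$elements$end[1] - 60000), 300)

  null_cfg <- simulation_config(seed = 44, contig_lengths = 400000L,
                                background_mean = 50, dispersion = 5)
  det0 <- detect_induced_elements(simulate_depth_profile(null_cfg)$depth)
  expect_equal(nrow(det0$elements), 0L)
})

test_that("elevated plasmid contigs are recorded whole", {
  cfg <- simulation_config(seed = 45, contig_lengths = 200000L,
                           background_mean = 50, dispersion = 20,
                           plasmids = data.frame(length = 30000,
                                                 copy_number = 5))
  det <- detect_induced_elements(simulate_depth_profile(cfg)$depth)
  pl <- det$elements[det$elements$contig == "plasmid_1", ]
  expect_equal(nrow(pl), 1L)
  expect_equal(c(pl$start, pl$end), c(0L, 30000L))
  expect_equal(pl$border_method, "contig_whole")
})
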