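# The domain caller is exercised on hand-built tracks for its linking rules
# and on seeded simulations for calibration/recovery; scoring, filtering,
# merging, taxonomy and normalization are checked against brute force.

test_that("weak-bin linking bridges gaps up to max_gap and requires a strong seed", {
  # two enriched runs separated by a 400-bp clean gap -> one peak
  counts <- rep(10, 1000)
  counts[301:305] <- 60   # strong run
  counts[310:314] <- 60   # second run; gap bins 306-309 = 400 bp
  chip <- toy_track(as.numeric(counts))
  input <- toy_track(rep(10, 1000))
  pk <- call_enriched_domains(chip, input)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 30000)
  expect_equal(pk$end, 31400)
  # a 600-bp gap exceeds max_gap 500 -> two peaks
  counts2 <- rep(10, 1000)
  counts2[301:305] <- 60
  counts2[312:316] <- 60
  pk2 <- call_enriched_domains(toy_track(as.numeric(counts2)), input)
  expect_equal(nrow(pk2), 2)
  # weak-only candidates (no strong bin) are dropped
  counts3 <- rep(10, 1000)
  counts3[500] <- 19      # p ~ 6e-3: weak but not strong at lambda 10
  pk3 <- call_enriched_domains(toy_track(as.numeric(counts3)), input)
  expect_equal(nrow(pk3), 0)
  expect_error(call_enriched_domains(toy_track(counts, bin = 50), input),
               "bin width")
})

test_that("caller is calibrated under a chip = input null", {
  cfg <- simulation_config(seed = 301, n_broad = 0, n_narrow = 0)
  sim <- simulate_chip(cfg, "2cell")
  chip <- bin_fragments(sim$chip, cfg$genome, 100)
  input <- bin_fragments(sim$input, cfg$genome, 100)
  p <- enrichment_pvalues(chip, input)
  expect_lte(mean(unlist(p) <= 1e-3), 2e-3)
})

test_that("planted domains are recovered with high reciprocal overlap", {
  cfg <- simulation_config(seed = 302, n_broad = 20, broad_fold = 4, n_narrow = 0)
  sim <- simulate_chip(cfg, "2cell")
  pk <- call_enriched_domains(bin_fragments(sim$chip, cfg$genome, 100),
                              bin_fragments(sim$input, cfg$genome, 100))
  tr <- cfg$broad_truth
  recovered <- vapply(seq_len(nrow(tr)), function(i) {
    plant <- tr[i, , drop = FALSE]
    ov <- .overlap_bp_test(pk, plant)
    j <- which.max(ov)
    ov[j] >= 0.8 * (plant$end - plant$start) &&
      ov[j] >= 0.8 * (pk$end[j] - pk$start[j])
  }, TRUE)
  expect_gte(mean(recovered), 0.9)
  # called genome coverage tracks the planted coverage within one point
  expect_lt(abs(coverage_fraction(pk, cfg$genome) -
                  coverage_fraction(tr, cfg$genome)), 0.01)
})

test_that("peak scoring matches brute-force bin enumeration", {
  fp <- toy_track(c(1.0, 2.0, 3.0, 4.0, 5.0), semantics = "counts")
  fp$semantics <- "fpkm"
  pk <- data.frame(chrom = "chrT", start = 0, end = 300)
  s <- score_peaks(pk, fp)
  expect_equal(s$signal_sum, 6.0)
  expect_equal(s$signal_mean, 2.0)
  one <- score_peaks(data.frame(chrom = "chrT", start = 100, end = 200), fp)
  expect_equal(one$signal_sum, one$signal_mean)
  expect_equal(one$signal_sum, 2.0)
  # random peaks vs direct enumeration of bin midpoints
  set.seed(5)
  vals <- runif(500)
  tr <- toy_track(vals, semantics = "counts"); tr$semantics <- "fpkm"
  rp <- random_intervals(40, chrom_sizes("chrT", 50000), max_len = 3000)
  got <- score_peaks(rp, tr)
  mids <- (seq_along(vals) - 1) * 100 + 50
  for (i in seq_len(nrow(rp))) {
    inb <- mids >= rp$start[i] & mids < rp$end[i]
    expect_equal(got$signal_sum[i], sum(vals[inb]))
  }
})

test_that("top-signal filter uses nearest-rank with ties kept", {
  pk <- data.frame(chrom = "chrT", start = (0:3) * 1000, end = (0:3) * 1000 + 500,
                   signal_sum = c(10, 8, 5, 1), signal_mean = 1)
  expect_equal(nrow(filter_top_signal(pk, 0.75)), 3)
  expect_equal(sort(filter_top_signal(pk, 0.75)$signal_sum), c(5, 8, 10))
  tied <- pk; tied$signal_sum <- rep(4, 4)
  expect_equal(nrow(filter_top_signal(tied, 0.75)), 4)
  expect_identical(filter_top_signal(pk, 1), pk)
  expect_equal(nrow(filter_top_signal(pk[0, ], 0.75)), 0)
  expect_error(filter_top_signal(data.frame(chrom = "chrT", start = 0, end = 1)),
               "scored")
})

test_that("merge_within_gap merges at 5 kb and re-scores when given a track", {
  pk <- data.frame(chrom = "chrT", start = c(0, 5500), end = c(500, 6000))
  expect_equal(nrow(merge_within_gap(pk)), 1)
  expect_equal(nrow(merge_within_gap(pk, gap = 4000)), 2)
  fp <- toy_track(rep(1, 100), semantics = "counts"); fp$semantics <- "fpkm"
  m <- merge_within_gap(pk, fpkm100 = fp)
  expect_equal(m$signal_sum, 60)  # 60 bins over the merged 6-kb span
})

test_that("length taxonomy uses strict thresholds and nests", {
  pk <- data.frame(chrom = "chrT",
                   start = c(0, 20000, 100000),
                   end = c(9999, 30001, 160000))
  s <- summarize_peaks(pk, chrom_sizes("chrT", 1e6))
  expect_equal(s$typical, 1)
  expect_equal(s$broad, 2)
  expect_equal(s$broad20, 1)
  expect_equal(s$broad50, 1)
  expect_equal(s$coverage, (9999 + 10001 + 60000) / 1e6)
  s0 <- summarize_peaks(pk[0, ], chrom_sizes("chrT", 1e6))
  expect_equal(s0$n, 0)
  expect_equal(s0$coverage, 0)
  # exactly 10 kb is typical (strict >)
  expect_equal(peak_length_class(data.frame(chrom = "chrT", start = 0, end = 10000)),
               "typical")
})

test_that("overlap tables match a brute-force pairwise check", {
  g <- toy_genome(10000)
  a <- data.frame(chrom = "chrT", start = c(0, 2000), end = c(1000, 3000))
  expect_equal(overlap_table(a, a)$a_overlap, 2)
  expect_equal(overlap_table(a, a)$a_only, 0)
  b <- data.frame(chrom = "chrT", start = 5000, end = 6000)
  expect_equal(overlap_table(a, b)$a_overlap, 0)
  expect_equal(overlap_table(a, b)$b_only, 1)
  set.seed(9)
  for (i in 1:20) {
    x <- random_intervals(20, g); y <- random_intervals(20, g)
    got <- overlap_table(x, y)
    brute <- sum(vapply(seq_len(nrow(x)), function(i)
      any(y$start < x$end[i] & y$end > x$start[i] & y$chrom == x$chrom[i]), TRUE))
    expect_equal(got$a_overlap, brute)
  }
  expect_error(overlap_table(a, b, criterion = "nope"))
})

test_that("inheritance labels follow gamete overlap logic", {
  zy <- data.frame(chrom = "chrT", start = c(0, 2000, 4000, 6000),
                   end = c(1000, 3000, 5000, 7000))
  oo <- data.frame(chrom = "chrT", start = c(0, 4000), end = c(500, 4500))
  sp <- data.frame(chrom = "chrT", start = c(2000, 4600), end = c(2500, 4900))
  lab <- classify_inheritance(zy, oo, sp)$inheritance
  expect_equal(as.character(lab), c("oocyte-only", "sperm-only", "shared", "de novo"))
  expect_equal(sum(table(lab)), nrow(zy))
})

test_that("stage scale factors equalize top-quartile medians", {
  mk <- function(means) data.frame(chrom = "chrT", start = seq_along(means) * 1000,
                                   end = seq_along(means) * 1000 + 500,
                                   signal_sum = means, signal_mean = means)
  ref <- mk(c(2, 2, 2, 2, 1, 1, 1, 1))
  oth <- mk(c(4, 4, 4, 4, 1, 1, 1, 1))
  expect_equal(stage_scale_factor(ref, oth), 0.5)
  expect_equal(stage_scale_factor(ref, ref), 1.0)
  tripled <- apply_scale_factor(ref, 3)
  f <- stage_scale_factor(ref, tripled)
  expect_equal(f, 1 / 3)
  rescaled <- apply_scale_factor(tripled, f)
  top_med <- function(p) median(sort(p$signal_mean, decreasing = TRUE)[
    seq_len(ceiling(0.25 * nrow(p)))])
  expect_equal(top_med(rescaled), top_med(ref))
  expect_error(stage_scale_factor(ref[1:3, ], oth), "at least 4")
})
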