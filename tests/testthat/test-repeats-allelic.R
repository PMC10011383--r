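test_that("repeat enrichment follows the observed/expected length ratio", {
  g <- chrom_sizes("chrT", 100000)
  # family X totals 10 kb of a 100-kb genome; peaks 10 kb total, 1 kb on X
  reps <- data.frame(chrom = "chrT", start = seq(0, 90000, 10000), end = seq(1000, 91000, 10000),
                     family = "X", class = "retro", stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chrT", start = c(500, 20000), end = c(1500, 29000))
  out <- repeat_enrichment(peaks, reps, g)
  expect_equal(out$expected, 0.1)
  expect_equal(out$observed, intersect_length(peaks, reps[, 1:3]) / 10000)
  expect_equal(out$ratio, out$observed / out$expected)
  # peaks entirely inside the family -> observed 1, ratio 10
  inside <- data.frame(chrom = "chrT", start = c(0, 10000), end = c(1000, 11000))
  out2 <- repeat_enrichment(inside, reps, g)
  expect_equal(out2$observed, 1)
  expect_equal(out2$ratio, 10)
  expect_error(repeat_enrichment(peaks, reps, g, families = "Y"),
               "absent.*Y")
  # agreement with the per-base mask oracle
  set.seed(21)
  for (i in 1:10) {
    rp <- random_intervals(30, g, max_len = 2000)
    obs_mask <- mask_intersect_length(rp, reps[, 1:3], g) /
      sum(mask_coverage_fraction(rp, g) * sum(g))
    got <- repeat_enrichment(rp, reps, g)
    expect_equal(got$observed, obs_mask)
  }
})

test_that("uniform random peaks give enrichment ratios near 1", {
  g <- chrom_sizes("chrT", 1e6)
  set.seed(33)
  fam_start <- sort(sample.int(1e6 - 2000, 100))
  reps <- data.frame(chrom = "chrT", start = fam_start, end = fam_start + 1000,
                     family = "ERVK", class = "retro", stringsAsFactors = FALSE)
  ratios <- vapply(1:50, function(i) {
    pk <- random_intervals(50, g, max_len = 2000)
    repeat_enrichment(pk, reps, g)$ratio
  }, 0)
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("repeat expression excludes exonic elements and z-scores across stages", {
  g <- chrom_sizes("chrT", 100000)
  reps <- data.frame(chrom = "chrT", start = c(10000, 50000, 80000),
                     end = c(11000, 51000, 81000),
                     family = c("A", "A", "B"), class = "retro",
                     stringsAsFactors = FALSE)
  exons <- data.frame(chrom = "chrT", start = 50000, end = 51000)
  frag <- function(centers) data.frame(chrom = "chrT", start = centers - 50,
                                       end = centers + 50)
  # family A expressed only at stage 2 (element 1); element 2 is exonic:
  # fragments over it contribute nothing
  stages <- list(
    s1 = frag(c(90000, 95000)),
    s2 = frag(c(rep(10500, 5), rep(50500, 7), 90000)),
    s3 = frag(c(90000, 95000)),
    s4 = frag(c(90000, 95000))
  )
  out <- repeat_expression_profile(stages, reps, exons)
  expect_equal(unname(which.max(out$zscore["A", ])), 2)
  # library size 13 fragments; 5 of them hit the retained element of A
  expect_equal(unname(out$normalized["A", "s2"]), 5 / (13 / 1e6))
  # family B never seen -> constant, flagged zero vector
  expect_true("B" %in% out$flagged)
  expect_true(all(out$zscore["B", ] == 0))
  expect_error(repeat_expression_profile(stages[1], reps, exons), ">= 2 stages")
})

test_that("allelic classification applies density, chi-square and fold rules", {
  tab <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                    length = c(1000, 2000, 1000, 1000),
                    maternal = c(50, 10, 60, 4),
                    paternal = c(50, 5, 0, 56))
  out <- classify_allelic(tab, rho = 0.5)
  # p1: perfectly balanced -> chi-square 0, biallelic
  expect_equal(out$chisq[1], 0)
  expect_equal(as.character(out$call[1]), "biallelic")
  # p2: 15 reads over 2 kb -> density 7.5 < 10 -> untested
  expect_equal(out$density[2], 7.5)
  expect_equal(as.character(out$call[2]), "untested")
  # p3: 60 vs 0 -> statistic 60, fold infinite -> maternal
  expect_equal(out$chisq[3], 60)
  expect_equal(out$fold[3], Inf)
  expect_equal(as.character(out$call[3]), "maternal")
  # p4: strong paternal skew -> paternal
  expect_equal(as.character(out$call[4]), "paternal")
  expect_error(classify_allelic(tab, rho = 0), "rho")
})

test_that("allelic test is calibrated under the null and powered for planted bias", {
  cfg <- simulation_config(seed = 81, allelic_biased_fraction = 0)
  pk <- data.frame(chrom = "chrS", start = (1:5000) * 1900,
                   end = (1:5000) * 1900 + 1000)
  tab <- simulate_allelic(cfg, pk)
  out <- classify_allelic(tab, rho = 0.5)
  expect_lte(sum(out$call %in% c("maternal", "paternal")), 1)
  # planted 95:5 peaks with >= 30 informative reads: sensitivity >= 0.95
  cfgb <- simulation_config(seed = 82, allelic_biased_fraction = 1)
  tabb <- simulate_allelic(cfgb, pk[1:500, ])
  outb <- classify_allelic(tabb, rho = 0.5)
  deep <- tabb$maternal + tabb$paternal >= 30
  called <- outb$call %in% c("maternal", "paternal")
  expect_gte(mean(called[deep]), 0.95)
  # and the called direction matches the planted one
  m_called <- outb$call == "maternal"
  expect_true(all(tabb$true_fraction[m_called & deep] > 0.5))
})

test_that("background rho is estimated from the table when not supplied", {
  tab <- data.frame(length = rep(1000, 100), maternal = rep(60, 100),
                    paternal = rep(40, 100))
  out <- classify_allelic(tab)
  # at the dataset-wide background (0.6), a 60:40 split is unremarkable
  expect_equal(out$chisq[1], 0)
  expect_true(all(out$call == "biallelic"))
})
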