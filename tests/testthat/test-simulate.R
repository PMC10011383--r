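# The generator's contracts: determinism under the seed, closed-form
# fragment expectations, planted methylation/expression structure.

test_that("identical seeds reproduce identical datasets end-to-end", {
  c1 <- simulation_config(seed = 5)
  c2 <- simulation_config(seed = 5)
  expect_identical(c1$domains, c2$domains)
  expect_identical(simulate_chip(c1, "2cell")$chip, simulate_chip(c2, "2cell")$chip)
  expect_identical(simulate_methylome(c1)$cpgs, simulate_methylome(c2)$cpgs)
  expect_identical(simulate_expression(c1)$expr, simulate_expression(c2)$expr)
  a1 <- simulate_annotation(c1); a2 <- simulate_annotation(c2)
  expect_identical(a1$genes, a2$genes)
  pk <- data.frame(chrom = "chrS", start = (1:50) * 1e5, end = (1:50) * 1e5 + 2000)
  expect_identical(simulate_allelic(c1, pk), simulate_allelic(c2, pk))
  c3 <- simulation_config(seed = 6)
  expect_false(identical(c1$domains, c3$domains))
})

test_that("fragment counts in a planted region match the closed-form expectation", {
  g <- chrom_sizes("chrS", 1e7)
  cfg <- simulation_config(seed = 17, genome = g, n_broad = 1,
                           broad_range = c(20000, 20001), broad_fold = 5,
                           n_narrow = 0)
  sim <- simulate_chip(cfg, "2cell")
  plant <- cfg$broad_truth
  w_in <- (plant$end - plant$start) * 5
  p_in <- w_in / (1e7 - (plant$end - plant$start) + w_in)
  expected <- 1e6 * p_in
  got <- sum(sim$chip$start >= plant$start & sim$chip$start < plant$end &
               sim$chip$chrom == plant$chrom)
  sigma <- sqrt(1e6 * p_in * (1 - p_in))
  expect_lt(abs(got - expected), 3 * sigma)
  # null fold: chip and input both uniform, in-region counts comparable
  cfg0 <- simulation_config(seed = 18, n_broad = 0, n_narrow = 0)
  sim0 <- simulate_chip(cfg0, "2cell")
  expect_equal(nrow(sim0$chip), nrow(sim0$input))
})

test_that("simulated methylomes carry the planted PMD structure", {
  cfg <- simulation_config(seed = 23)
  meth <- simulate_methylome(cfg)
  cpgs <- meth$cpgs
  # density ~ 2 per 100 bp genome-wide
  expect_equal(nrow(cpgs) / (sum(cfg$genome) / 100), 2, tolerance = 0.05)
  pmd <- cfg$pmds[1, ]
  inside <- cpgs$pos >= pmd$start & cpgs$pos < pmd$end
  expect_gt(sum(inside), 50)
  expect_equal(mean(cpgs$meth[inside]), 0.35, tolerance = 0.05)
  # outside all PMDs the genome sits at the high baseline
  out <- rep(TRUE, nrow(cpgs))
  for (i in seq_len(nrow(cfg$pmds)))
    out <- out & !(cpgs$pos >= cfg$pmds$start[i] & cpgs$pos < cfg$pmds$end[i])
  expect_equal(mean(cpgs$meth[out]), 0.85, tolerance = 0.05)
  # no PMDs planted -> flat high methylome
  cfg0 <- simulation_config(seed = 24, n_broad = 0, n_narrow = 0)
  m0 <- simulate_methylome(cfg0)
  expect_equal(mean(m0$cpgs$meth), 0.85, tolerance = 0.05)
})

test_that("allelic counts follow the configured background and bias", {
  cfg <- simulation_config(seed = 31, allelic_biased_fraction = 0)
  pk <- data.frame(chrom = "chrS", start = (1:2000) * 4000,
                   end = (1:2000) * 4000 + 1000)
  tab <- simulate_allelic(cfg, pk)
  expect_false(any(tab$biased))
  expect_equal(mean(tab$maternal / pmax(tab$maternal + tab$paternal, 1)), 0.5,
               tolerance = 0.02)
  cfgb <- simulation_config(seed = 31, allelic_biased_fraction = 1,
                            allelic_bias = 0.95)
  tabb <- simulate_allelic(cfgb, pk)
  expect_true(all(tabb$biased))
  frac <- ifelse(tabb$true_fraction > 0.5,
                 tabb$maternal / (tabb$maternal + tabb$paternal),
                 tabb$paternal / (tabb$maternal + tabb$paternal))
  expect_equal(mean(frac), 0.95, tolerance = 0.01)
})

test_that("planted expression passes the ZGA and specificity rules by construction", {
  cfg <- simulation_config(seed = 41)
  sim <- simulate_expression(cfg)
  expr <- sim$expr
  pre <- cfg$pre_zga[length(cfg$pre_zga)]
  post <- cfg$post_zga[1]
  for (g in cfg$zga_genes) {
    expect_lt(expr[g, pre], 0.5)
    expect_gt(expr[g, post], 1)
    expect_gt(expr[g, post] / expr[g, pre], 3)
  }
  es <- entropy_score(expr[cfg$specific_genes, ])
  expect_true(all(es$H < 0.5))
  truth <- sim$truth[match(cfg$specific_genes, sim$truth$gene_id), ]
  expect_equal(es$stage, truth$stage)
  # a uniform housekeeping profile scores log2(N) exactly
  expect_equal(entropy_score(rep(7, length(cfg$stages)))$H,
               log2(length(cfg$stages)))
})

test_that("annotation respects configured geometry and fractions", {
  cfg <- simulation_config(seed = 51, n_genes = 50)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 50)
  # gene bodies non-overlapping
  bodies <- data.frame(chrom = ann$genes$chrom, start = ann$genes$tx_start,
                       end = ann$genes$tx_end)
  expect_equal(nrow(merge_intervals(bodies)), 50)
  # promoters away from edges are exactly 5 kb wide
  prom <- promoter_regions(ann$genes, cfg$genome)
  expect_true(all(prom$end - prom$start == 5000))
  # repeat families occupy their configured fractions up to one element
  # (<= 3000 bp) of placement granularity
  for (fam in names(cfg$repeat_fractions)) {
    fl <- ann$repeats[ann$repeats$family == fam, ]
    expect_lt(abs(sum(fl$end - fl$start) - cfg$repeat_fractions[fam] * sum(cfg$genome)),
              3000)
  }
  # DHSs sit on every narrow plant center
  narrow <- cfg$narrow_truth
  centers <- data.frame(chrom = narrow$chrom,
                        start = floor((narrow$start + narrow$end) / 2),
                        end = floor((narrow$start + narrow$end) / 2) + 1)
  expect_equal(overlap_table(centers, ann$dhs)$a_overlap, nrow(narrow))
  expect_error(simulation_config(repeat_fractions = c(A = 0.6, B = 0.5)),
               "sum to < 1")
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(rho = 1.2), "rho")
  expect_error(simulation_config(allelic_bias = 0), "allelic_bias")
  expect_error(simulation_config(meth_in = 1.5), "methylation")
  expect_error(simulation_config(broad_fold = 0.5), "folds")
  expect_error(simulation_config(stages = character()), "stage")
  expect_error(simulate_chip(simulation_config(), "16cell"), "unknown stage")
})
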