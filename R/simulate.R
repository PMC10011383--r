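# Deterministic generator of multi-stage embryo-like datasets with known
# ground truth: stage-series ChIP fragments in which pre-ZGA stages carry
# planted broad domains (10-60 kb) that transition to narrow peaks after
# ZGA, matched input, methylomes with planted PMDs, allelic read counts
# with planted biases, and expression matrices with planted ZGA and
# stage-specific genes.  All randomness flows from the single config seed
# through R's default Mersenne-Twister stream; every operation scopes its
# own sub-seed so outputs are reproducible independent of call order.

# Place n non-overlapping intervals of the given lengths on the genome,
# keeping at least `sep` bp between them (and from chromosome ends).
.place_intervals <- function(lengths, genome, sep) {
  n <- length(lengths)
  if (n == 0) return(.empty_intervals())
  chrom <- names(genome)[sample.int(length(genome), n, replace = TRUE,
                                    prob = unclass(genome))]
  out <- lapply(names(genome), function(ch) {
    idx <- which(chrom == ch)
    len <- lengths[idx]
    k <- length(len)
    if (!k) return(NULL)
    free <- genome[ch] - sum(len) - sep * (k + 1)
    if (free < 0) stop("planted intervals do not fit on ", ch)
    cuts <- sort(stats::runif(k))
    gaps <- sep + free * diff(c(0, cuts, 1))  # k+1 gaps; the last pads the end
    start <- cumsum(gaps[seq_len(k)]) + c(0, cumsum(len))[seq_len(k)]
    data.frame(chrom = ch, start = floor(start), end = floor(start) + len,
               id = idx, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Configuration of the synthetic embryo dataset
#'
#' Builds the full planted ground truth for a toy multi-stage dataset on a
#' deterministic single-seed stream: per-stage enrichment plants (broad
#' domains at pre-ZGA stages, narrow peaks plus transcribed-enhancer plants
#' after ZGA), PMDs containing every pre-ZGA broad domain, allelic bias
#' settings and planted ZGA / stage-specific gene ids.
#'
#' @param seed Integer seed fixing all randomness end-to-end.
#' @param genome [chrom_sizes()]; default a 10-Mb single chromosome, large
#'   enough for stable Poisson statistics at the default library size.
#' @param stages Ordered stage labels.
#' @param pre_zga Stage labels preceding zygotic genome activation (they
#'   carry the broad plants).
#' @param n_fragments Fragments per library (default 1e6).
#' @param fragment_length Fragment length in bp (default 200).
#' @param n_broad,broad_range Number and length range (bp) of broad plants
#'   per pre-ZGA stage (default 40 domains of 10-60 kb, about 14% of the
#'   default genome).
#' @param broad_fold Enrichment fold of broad plants (default 5).
#' @param n_narrow,narrow_range,narrow_fold Narrow plants at post-ZGA stages
#'   (default 80 peaks of 1-3 kb at fold 8).
#' @param narrow_exclusive_fraction Fraction of narrow plants enriched at
#'   only one (randomly assigned) post-ZGA stage; the rest are planted at
#'   every post-ZGA stage (default 0.25). Exclusive plants are the
#'   ground-truth stage-specific enhancers.
#' @param erna_fraction Fraction of each post-ZGA stage's narrow plants that
#'   are transcribed (planted eRNAs; default 0.3).
#' @param rna_fold Per-base weight of transcribed regions (exons and planted
#'   eRNAs) relative to intergenic background in RNA libraries (default
#'   5000). RNA-seq mass concentrates almost entirely in transcribed
#'   sequence, so intergenic RNA FPKM stays far below the eRNA cutoff.
#' @param pmd_pad Padding (bp) around each pre-ZGA broad plant when deriving
#'   the planted PMDs (default 25 kb, giving PMDs of 60-110 kb).
#' @param cpg_per_100bp CpG density, sites per 100 bp (default 2).
#' @param meth_in,meth_out Mean methylation inside/outside PMDs (defaults
#'   0.35 and 0.85).
#' @param meth_conc Beta concentration of per-CpG methylation noise
#'   (default 10).
#' @param cpg_depth Mean per-CpG sequencing coverage (default 15).
#' @param rho Background maternal read fraction (default 0.5).
#' @param allelic_depth Mean SNP-informative reads per peak (default 50).
#' @param allelic_bias Maternal fraction of planted biased peaks
#'   (default 0.95).
#' @param allelic_biased_fraction Fraction of peaks planted with bias
#'   (default 0.05).
#' @param n_genes Number of genes (default 200).
#' @param n_zga,n_stage_specific Planted ZGA and stage-specific gene counts
#'   (default: 20% of `n_genes` each).
#' @param specific_share Signal share of the assigned stage for planted
#'   stage-specific genes (default 0.95, entropy about 0.39 bits).
#' @param repeat_fractions Named genome fractions per repeat family
#'   (default ERVK 0.03, SVA 0.01, ERV1 0.02, Alu 0.05); must sum to < 1.
#' @return List of class `simulation_config` including `domains` (the
#'   planted enrichment truth: stage/chrom/start/end/fold/type/erna) and
#'   `pmds` (planted PMD intervals).
#' @export
simulation_config <- function(seed = 1,
                              genome = chrom_sizes("chrS", 1e7),
                              stages = c("2cell", "4cell", "8cell", "morula"),
                              pre_zga = c("2cell", "4cell"),
                              n_fragments = 1e6,
                              fragment_length = 200,
                              n_broad = 40, broad_range = c(10000, 60000),
                              broad_fold = 5,
                              n_narrow = 80, narrow_range = c(1000, 3000),
                              narrow_fold = 8, narrow_exclusive_fraction = 0.25,
                              erna_fraction = 0.3, rna_fold = 5000,
                              pmd_pad = 25000,
                              cpg_per_100bp = 2,
                              meth_in = 0.35, meth_out = 0.85, meth_conc = 10,
                              cpg_depth = 15,
                              rho = 0.5, allelic_depth = 50,
                              allelic_bias = 0.95, allelic_biased_fraction = 0.05,
                              n_genes = 200, n_zga = round(0.2 * n_genes),
                              n_stage_specific = round(0.2 * n_genes),
                              specific_share = 0.95,
                              repeat_fractions = c(ERVK = 0.03, SVA = 0.01,
                                                   ERV1 = 0.02, Alu = 0.05)) {
  if (rho <= 0 || rho >= 1) stop("rho must lie strictly between 0 and 1")
  if (allelic_bias <= 0 || allelic_bias >= 1) stop("allelic_bias must lie in (0, 1)")
  if (meth_in < 0 || meth_in > 1 || meth_out < 0 || meth_out > 1)
    stop("methylation means must lie in [0, 1]")
  if (broad_fold < 1 || narrow_fold < 1) stop("enrichment folds must be >= 1")
  if (sum(repeat_fractions) >= 1) stop("repeat fractions must sum to < 1")
  if (!length(stages)) stop("need at least one stage")
  post_zga <- setdiff(stages, pre_zga)

  old <- .save_seed(seed)
  on.exit(.restore_seed(old))

  # broad (pre-ZGA) and narrow (post-ZGA) plants are placed jointly with a
  # separation exceeding the PMD pad, so narrow plants never sit inside a
  # broad domain or its flanking PMD and the planted stage labels are
  # unambiguous ground truth
  lens <- c(floor(stats::runif(n_broad, broad_range[1], broad_range[2])),
            floor(stats::runif(n_narrow, narrow_range[1], narrow_range[2])))
  placed <- .place_intervals(lens, genome, sep = pmd_pad + 5000)
  broad <- sort_intervals(placed[placed$id <= n_broad, c("chrom", "start", "end")])
  narrow <- sort_intervals(placed[placed$id > n_broad, c("chrom", "start", "end")])
  exclusive <- rep(NA_character_, nrow(narrow))
  k_excl <- round(narrow_exclusive_fraction * nrow(narrow))
  if (k_excl > 0 && length(post_zga))
    exclusive[sample.int(nrow(narrow), k_excl)] <-
      sample(post_zga, k_excl, replace = TRUE)
  domains <- NULL
  for (st in pre_zga)
    if (nrow(broad))
      domains <- rbind(domains, cbind(stage = st, broad, fold = broad_fold,
                                      type = "broad", erna = FALSE))
  for (st in post_zga) {
    sub <- narrow[is.na(exclusive) | exclusive == st, , drop = FALSE]
    if (!nrow(sub)) next
    erna <- rep(FALSE, nrow(sub))
    n_erna <- round(erna_fraction * nrow(sub))
    if (n_erna > 0) erna[sample.int(nrow(sub), n_erna)] <- TRUE
    domains <- rbind(domains, cbind(stage = st, sub, fold = narrow_fold,
                                    type = "narrow", erna = erna))
  }
  if (is.null(domains))
    domains <- data.frame(stage = character(), chrom = character(),
                          start = numeric(), end = numeric(), fold = numeric(),
                          type = character(), erna = logical())
  rownames(domains) <- NULL
  narrow_truth <- cbind(narrow, exclusive = exclusive)

  # planted PMDs: every pre-ZGA broad plant padded outward (clipped to the
  # chromosome); padding keeps PMDs at realistic 60-110 kb scale.  Padded
  # plants closer than two 10-kb windows are unified into one PMD so that
  # distinct planted PMDs are always separated by at least 20 kb of fully
  # methylated sequence and remain individually resolvable.
  pmds <- if (nrow(broad)) merge_intervals(data.frame(
    chrom = broad$chrom,
    start = pmax(broad$start - pmd_pad, 0),
    end = pmin(broad$end + pmd_pad, unclass(genome)[broad$chrom]),
    stringsAsFactors = FALSE), gap = 20000) else .empty_intervals()

  if (n_zga + n_stage_specific > n_genes)
    stop("n_zga + n_stage_specific must not exceed n_genes")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  zga_genes <- sample(gene_ids, n_zga)
  specific_genes <- sample(setdiff(gene_ids, zga_genes), n_stage_specific)

  structure(list(
    seed = seed, genome = genome, stages = stages, pre_zga = pre_zga,
    post_zga = post_zga, n_fragments = n_fragments,
    fragment_length = fragment_length, domains = domains, pmds = pmds,
    broad_truth = broad, narrow_truth = narrow_truth,
    broad_fold = broad_fold, narrow_fold = narrow_fold, rna_fold = rna_fold,
    cpg_per_100bp = cpg_per_100bp, meth_in = meth_in, meth_out = meth_out,
    meth_conc = meth_conc, cpg_depth = cpg_depth,
    rho = rho, allelic_depth = allelic_depth, allelic_bias = allelic_bias,
    allelic_biased_fraction = allelic_biased_fraction,
    n_genes = n_genes, gene_ids = gene_ids, zga_genes = zga_genes,
    specific_genes = specific_genes, specific_share = specific_share,
    repeat_fractions = repeat_fractions
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: seed %d, %s bp genome, stages %s (pre-ZGA: %s)\n",
    x$seed, format(sum(x$genome), big.mark = ",", scientific = FALSE),
    paste(x$stages, collapse = " > "), paste(x$pre_zga, collapse = ", ")))
  cat(sprintf("  planted: %d enrichment regions, %d PMDs, %d ZGA + %d stage-specific genes\n",
              nrow(x$domains), nrow(x$pmds), length(x$zga_genes),
              length(x$specific_genes)))
  invisible(x)
}

# Stable per-operation sub-seeds derived from the config seed (kept < 2^31).
.sub_seed <- function(config, op, stage = "") {
  key <- paste(op, stage, sep = ":")
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  (config$seed * 10007 + h) %% 2147483647
}

# Draw n fragment start positions from a piecewise-constant per-base weight
# field (weight 1 outside `regions`, `fold` inside), then extend by the
# fragment length.
.draw_fragments <- function(n, genome, fragment_length, regions = NULL) {
  segs <- lapply(names(genome), function(ch) {
    g <- unclass(genome)[ch]
    r <- if (is.null(regions)) NULL else regions[regions$chrom == ch, , drop = FALSE]
    if (is.null(r) || nrow(r) == 0)
      return(data.frame(chrom = ch, start = 0, end = g, w = 1))
    r <- r[order(r$start), , drop = FALSE]
    bounds <- sort(unique(c(0, r$start, r$end, g)))
    seg <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                      end = bounds[-1], w = 1, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(r)))
      seg$w[seg$start >= r$start[i] & seg$end <= r$end[i]] <- r$fold[i]
    seg
  })
  segs <- do.call(rbind, segs)
  len <- segs$end - segs$start
  cnt <- as.vector(stats::rmultinom(1, n, prob = len * segs$w))
  start <- floor(rep(segs$start, cnt) + stats::runif(n) * rep(len, cnt))
  chrom <- rep(segs$chrom, cnt)
  out <- data.frame(chrom = chrom, start = start,
                    end = pmin(start + fragment_length, unclass(genome)[chrom]),
                    stringsAsFactors = FALSE)
  sort_intervals(out)
}

#' Simulate a ChIP (or RNA) library and its matched input for one stage
#'
#' Fragment starts are drawn from a per-base weight field: weight 1 outside
#' the stage's planted regions and the planted fold inside; input fragments
#' are drawn uniformly.
#'
#' @param config A [simulation_config()].
#' @param stage Stage label.
#' @param assay `"chip"` (enrichment over all of the stage's plants, with a
#'   uniform matched input) or `"rna"` (mass concentrated at `rna_fold` in
#'   exons and the stage's transcribed plants, leaving near-zero intergenic
#'   background).
#' @return List with `chip` and `input` fragment data.frames and `truth`
#'   (the planted regions used; for `"rna"`, the planted eRNA regions).
#' @export
simulate_chip <- function(config, stage, assay = c("chip", "rna")) {
  assay <- match.arg(assay)
  if (!stage %in% config$stages) stop("unknown stage: ", stage)
  plants <- config$domains[config$domains$stage == stage, , drop = FALSE]
  truth <- plants
  if (assay == "rna") {
    ernas <- plants[plants$erna, c("chrom", "start", "end"), drop = FALSE]
    exons <- exon_regions(simulate_annotation(config)$genes)
    plants <- merge_intervals(rbind(ernas, exons[, c("chrom", "start", "end")]))
    plants$fold <- config$rna_fold
    truth <- ernas
  }
  .check_intervals(plants, config$genome, what = "planted regions")
  old <- .save_seed(.sub_seed(config, assay, stage))
  on.exit(.restore_seed(old))
  chip <- .draw_fragments(config$n_fragments, config$genome,
                          config$fragment_length, plants)
  input <- .draw_fragments(config$n_fragments, config$genome,
                           config$fragment_length, NULL)
  list(chip = chip, input = input, truth = truth)
}

#' Simulate annotation: genes, repeats and DHSs
#'
#' Gene bodies are placed without overlap; repeat families occupy their
#' configured genome fractions; DHSs sit at the centers of the post-ZGA
#' narrow plants (plus uniform decoys), so planted enhancers carry open
#' chromatin.
#'
#' @param config A [simulation_config()].
#' @return List with `genes` (gene table), `repeats` (repeat table) and
#'   `dhs` (interval data.frame).
#' @export
simulate_annotation <- function(config) {
  old <- .save_seed(.sub_seed(config, "annotation"))
  on.exit(.restore_seed(old))
  genome <- config$genome

  body_len <- floor(stats::runif(config$n_genes, 5000, 30000))
  bodies <- .place_intervals(body_len, genome, sep = 6000)
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  exons <- lapply(seq_len(nrow(bodies)), function(i) {
    k <- sample(3:8, 1)
    len <- bodies$end[i] - bodies$start[i]
    cuts <- sort(sample.int(len - 2, 2 * k)) + bodies$start[i]
    list(starts = cuts[seq(1, 2 * k, 2)], ends = cuts[seq(2, 2 * k, 2)])
  })
  genes <- data.frame(gene_id = config$gene_ids, chrom = bodies$chrom,
                      strand = strand, tx_start = bodies$start,
                      tx_end = bodies$end, stringsAsFactors = FALSE)
  genes$exon_starts <- I(lapply(exons, `[[`, "starts"))
  genes$exon_ends <- I(lapply(exons, `[[`, "ends"))

  reps <- lapply(names(config$repeat_fractions), function(fam) {
    target <- config$repeat_fractions[[fam]] * sum(genome)
    lens <- c()
    while (sum(lens) < target) lens <- c(lens, floor(stats::runif(50, 300, 3000)))
    lens <- lens[cumsum(lens) <= target + 3000]
    chrom <- names(genome)[sample.int(length(genome), length(lens), replace = TRUE,
                                      prob = unclass(genome))]
    start <- floor(stats::runif(length(lens)) * (unclass(genome)[chrom] - lens))
    data.frame(chrom = chrom, start = start, end = start + lens,
               family = fam, class = "retrotransposon", stringsAsFactors = FALSE)
  })
  repeats <- sort_intervals(do.call(rbind, reps))

  narrow <- unique(config$domains[config$domains$type == "narrow",
                                  c("chrom", "start", "end")])
  center <- floor((narrow$start + narrow$end) / 2)
  dhs_peak <- data.frame(chrom = narrow$chrom, start = center - 150,
                         end = center + 150, stringsAsFactors = FALSE)
  n_decoy <- nrow(narrow)
  chrom <- names(genome)[sample.int(length(genome), n_decoy, replace = TRUE,
                                    prob = unclass(genome))]
  start <- floor(stats::runif(n_decoy) * (unclass(genome)[chrom] - 300))
  dhs <- sort_intervals(rbind(dhs_peak,
                              data.frame(chrom = chrom, start = start,
                                         end = start + 300, stringsAsFactors = FALSE)))
  list(genes = genes, repeats = repeats, dhs = dhs)
}

#' Simulate a methylome with planted PMDs
#'
#' CpG sites are placed at the configured density; per-CpG methylation is
#' Beta-distributed (bounded in \[0,1\]) with mean `meth_in` inside planted
#' PMDs and `meth_out` outside; coverage is Poisson around `cpg_depth`.
#'
#' @param config A [simulation_config()].
#' @return List with `cpgs` (CpG table) and `truth` (planted PMD intervals).
#' @export
simulate_methylome <- function(config) {
  old <- .save_seed(.sub_seed(config, "methylome"))
  on.exit(.restore_seed(old))
  genome <- config$genome
  out <- lapply(names(genome), function(ch) {
    g <- unclass(genome)[ch]
    n <- round(g * config$cpg_per_100bp / 100)
    pos <- sort(sample.int(g, n)) - 1
    pmd <- config$pmds[config$pmds$chrom == ch, , drop = FALSE]
    inside <- rep(FALSE, n)
    for (i in seq_len(nrow(pmd)))
      inside <- inside | (pos >= pmd$start[i] & pos < pmd$end[i])
    mu <- ifelse(inside, config$meth_in, config$meth_out)
    meth <- stats::rbeta(n, mu * config$meth_conc, (1 - mu) * config$meth_conc)
    data.frame(chrom = ch, pos = pos, meth = meth,
               cov = stats::rpois(n, config$cpg_depth), stringsAsFactors = FALSE)
  })
  list(cpgs = do.call(rbind, out), truth = config$pmds)
}

#' Simulate allelic read counts over a peak set
#'
#' Each peak receives Poisson-distributed SNP-informative reads around the
#' configured depth; maternal reads are binomial with the background
#' fraction `rho` for null peaks. Planted biased peaks use `allelic_bias`
#' toward the maternal or paternal allele (direction drawn uniformly).
#'
#' @param config A [simulation_config()].
#' @param peaks Peak data.frame.
#' @return data.frame peak_id/chrom/start/end/length/maternal/paternal with
#'   the planted truth columns `biased` and `true_fraction`.
#' @export
simulate_allelic <- function(config, peaks) {
  old <- .save_seed(.sub_seed(config, "allelic"))
  on.exit(.restore_seed(old))
  n <- nrow(peaks)
  biased <- rep(FALSE, n)
  k <- round(config$allelic_biased_fraction * n)
  if (k > 0) biased[sample.int(n, k)] <- TRUE
  total <- stats::rpois(n, config$allelic_depth)
  toward_m <- sample(c(TRUE, FALSE), n, replace = TRUE)
  frac <- ifelse(biased, ifelse(toward_m, config$allelic_bias, 1 - config$allelic_bias),
                 config$rho)
  m <- stats::rbinom(n, total, frac)
  data.frame(peak_id = sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end),
             chrom = peaks$chrom, start = peaks$start, end = peaks$end,
             length = peaks$end - peaks$start,
             maternal = m, paternal = total - m,
             biased = biased, true_fraction = frac, stringsAsFactors = FALSE)
}

#' Simulate a gene expression matrix with planted ZGA and stage-specific genes
#'
#' Baseline genes draw log-normal FPKM at every stage. Planted ZGA genes are
#' silent before ZGA (FPKM < 0.5) and jump above both the FPKM and
#' fold-change cutoffs afterwards; planted stage-specific genes concentrate
#' `specific_share` of their signal at one assigned stage.
#'
#' @param config A [simulation_config()].
#' @return List with `expr` (gene x stage FPKM matrix) and `truth`
#'   (data.frame gene_id/type/stage).
#' @export
simulate_expression <- function(config) {
  if (!length(config$stages)) stop("no stages configured")
  old <- .save_seed(.sub_seed(config, "expression"))
  on.exit(.restore_seed(old))
  stages <- config$stages
  n <- config$n_genes
  expr <- matrix(stats::rlnorm(n * length(stages), meanlog = 1, sdlog = 1),
                 nrow = n, dimnames = list(config$gene_ids, stages))
  truth <- data.frame(gene_id = config$gene_ids, type = "baseline",
                      stage = NA_character_, stringsAsFactors = FALSE)

  pre <- config$pre_zga
  post <- config$post_zga
  for (g in config$zga_genes) {
    base <- stats::runif(1, 0.05, 0.4)
    expr[g, pre] <- base
    expr[g, post] <- stats::runif(length(post), pmax(4 * base, 1.5), 20)
    truth$type[truth$gene_id == g] <- "zga"
  }
  for (g in config$specific_genes) {
    st <- sample(stages, 1)
    total <- stats::rlnorm(1, meanlog = 2.5, sdlog = 0.5)
    share <- rep((1 - config$specific_share) / (length(stages) - 1), length(stages))
    share[stages == st] <- config$specific_share
    expr[g, ] <- total * share
    truth$type[truth$gene_id == g] <- "stage_specific"
    truth$stage[truth$gene_id == g] <- st
  }
  list(expr = expr, truth = truth)
}
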