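# End-to-end synthetic-to-report workflow: simulate, bin, call, filter,
# merge, normalize, annotate, PMDs, entropy/enhancers/eRNA, repeats,
# allelic — in the canonical order (top-signal filter before the 5-kb
# merge), with every artifact and threshold recorded in a run manifest.

#' Run the full synthetic pipeline
#'
#' Sequences the analyses in dependency order: per-stage domain calling
#' (call, top-75% filter, 5-kb merge, re-score), cross-stage normalization
#' to the reference stage's top-quartile median, genomic-element
#' annotation, PMD calling and broad-domain/PMD overlap, putative-enhancer
#' definition with entropy-based stage specificity, eRNA calling from
#' simulated RNA libraries, ZGA genes from the expression matrix, repeat
#' enrichment and allelic classification. Deterministic under the config
#' seed; rerunning an identical config reproduces identical artifacts.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed); artifacts and
#'   planted-truth TSVs are written there.
#' @param params [caller_params()] for domain calling.
#' @param keep_fraction Top-signal fraction kept per stage (default 0.75).
#' @param merge_gap Post-filter merge distance in bp (default 5000).
#' @param reference_stage Stage whose top-quartile median anchors the
#'   cross-stage scaling (default: first post-ZGA stage).
#' @return A `run_manifest` (list of stage results, artifact paths, seed
#'   and thresholds), invisibly printable.
#' @export
run_pipeline <- function(config, outdir, params = caller_params(),
                         keep_fraction = 0.75, merge_gap = 5000,
                         reference_stage = NULL) {
  t0 <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- config$genome
  if (is.null(reference_stage))
    reference_stage <- if (length(config$post_zga)) config$post_zga[1] else config$stages[1]
  paths <- character()
  emit <- function(x, name, kind) {
    p <- file.path(outdir, name)
    write_table(x, p, kind)
    paths[[name]] <<- p
    p
  }

  ann <- simulate_annotation(config)
  emit(ann$genes, "genes.tsv", "genes")
  emit(ann$repeats, "repeats.tsv", "repeats")
  emit(ann$dhs, "dhs.bed", "bed")
  emit(config$domains[, c("chrom", "start", "end", "stage", "fold", "type", "erna")],
       "truth_domains.tsv", "peaks")
  emit(config$pmds, "truth_pmds.bed", "bed")

  # --- per-stage domain calling: call -> filter top signal -> merge -> score
  stage_res <- list()
  for (st in config$stages) {
    sim <- simulate_chip(config, st)
    chip_counts <- bin_fragments(sim$chip, genome, params$bin)
    input_counts <- bin_fragments(sim$input, genome, params$bin)
    fpkm100 <- fpkm_normalize(chip_counts, nrow(sim$chip))
    called <- call_enriched_domains(chip_counts, input_counts, params)
    scored <- score_peaks(called, fpkm100)
    kept <- filter_top_signal(scored, q = keep_fraction)
    peaks <- merge_within_gap(kept, gap = merge_gap, fpkm100 = fpkm100)
    stage_res[[st]] <- list(called = called, peaks = peaks, fpkm100 = fpkm100,
                            input_fpkm100 = fpkm_normalize(input_counts, nrow(sim$input)),
                            summary = summarize_peaks(peaks, genome))
  }

  # --- cross-stage normalization against the reference stage
  ref_peaks <- stage_res[[reference_stage]]$peaks
  scale_factors <- vapply(config$stages, function(st) {
    if (st == reference_stage) return(1)
    stage_scale_factor(ref_peaks, stage_res[[st]]$peaks)
  }, 0)
  for (st in config$stages)
    stage_res[[st]]$peaks <- apply_scale_factor(stage_res[[st]]$peaks,
                                                scale_factors[[st]])

  # --- genomic annotation; per-stage artifacts carry the final scaled,
  # annotated peaks
  for (st in config$stages) {
    stage_res[[st]]$peaks <- assign_elements(stage_res[[st]]$peaks, ann$genes, genome)
    emit(stage_res[[st]]$peaks, paste0("peaks_", st, ".tsv"), "peaks")
  }

  # --- methylome: PMDs and broad-domain overlap
  meth <- simulate_methylome(config)
  emit(meth$cpgs, "methylome.tsv", "cpg")
  pmds <- call_pmds(meth$cpgs, genome)
  emit(pmds, "pmds.bed", "bed")
  pre_peaks <- do.call(rbind, lapply(config$pre_zga, function(st)
    stage_res[[st]]$peaks[, c("chrom", "start", "end")]))
  broad_called <- if (is.null(pre_peaks)) .empty_intervals() else
    pre_peaks[pre_peaks$end - pre_peaks$start > 10000, , drop = FALSE]
  broad_pmd_fraction <- if (nrow(broad_called))
    mean(.overlap_bp(broad_called, pmds) >= 1) else NA_real_

  # --- putative enhancers and stage specificity (input-subtracted FPKM)
  post <- config$post_zga
  union_peaks <- merge_intervals(do.call(rbind, lapply(post, function(st)
    stage_res[[st]]$peaks[, c("chrom", "start", "end")])))
  distal <- distal_peaks(union_peaks, ann$genes, genome)
  enhancers <- define_putative_enhancers(distal, ann$dhs)
  # stage signal = region-level input-subtracted mean FPKM (the promoter
  # convention: subtract the region's input FPKM, floor at zero)
  enh_signal <- vapply(config$stages, function(st) {
    s <- score_peaks(enhancers, stage_res[[st]]$fpkm100)$signal_mean
    b <- score_peaks(enhancers, stage_res[[st]]$input_fpkm100)$signal_mean
    pmax(s - b, 0)
  }, numeric(nrow(enhancers)))
  enh_signal <- matrix(enh_signal, nrow = nrow(enhancers),
                       dimnames = list(sprintf("%s:%d-%d", enhancers$chrom,
                                               enhancers$start, enhancers$end),
                                       config$stages))
  specific_enh <- select_stage_specific(enh_signal)
  emit(enhancers, "putative_enhancers.tsv", "peaks")

  # --- eRNAs from simulated RNA libraries at post-ZGA stages
  rna_fpkm <- vapply(post, function(st) {
    rna <- simulate_chip(config, st, assay = "rna")
    score_peaks(distal, fpkm_normalize(bin_fragments(rna$chip, genome, params$bin),
                                       nrow(rna$chip)))$signal_mean
  }, numeric(nrow(distal)))
  rna_fpkm <- matrix(rna_fpkm, nrow = nrow(distal),
                     dimnames = list(NULL, post))
  k4_none <- .empty_intervals()
  ernas <- call_ernas(distal, k4_none, ann$genes, genome, rna_fpkm)

  # --- expression: ZGA and stage-specific genes
  expr <- simulate_expression(config)
  emit(expr$expr, "expression.tsv", "matrix")
  emit(expr$truth, "truth_genes.tsv", "peaks")
  zga <- define_zga_genes(expr$expr, pre = config$pre_zga[length(config$pre_zga)],
                          post = post[1])
  specific_genes <- select_stage_specific(expr$expr)

  # --- repeat enrichment over pre-ZGA broad domains
  enrich <- if (nrow(broad_called))
    repeat_enrichment(broad_called, ann$repeats, genome) else NULL

  # --- allelic classification over reference-stage peaks
  allelic_counts <- simulate_allelic(config, stage_res[[reference_stage]]$peaks)
  emit(allelic_counts, "truth_allelic.tsv", "peaks")
  allelic <- classify_allelic(allelic_counts, rho = config$rho)
  emit(allelic, "allelic_calls.tsv", "peaks")

  manifest <- structure(list(
    seed = config$seed,
    config_hash = .config_hash(config),
    stages = config$stages,
    reference_stage = reference_stage,
    thresholds = list(p_strong = params$p_strong, p_weak = params$p_weak,
                      max_gap = params$max_gap, bin = params$bin,
                      keep_fraction = keep_fraction, merge_gap = merge_gap,
                      pmd_meth = 0.5, pmd_cpg = 20, entropy = 0.5,
                      erna_fpkm = 0.5, zga_fpkm = 1, zga_fold = 3,
                      allelic_alpha = 0.001, allelic_fold = 5,
                      allelic_density = 10),
    scale_factors = scale_factors,
    summaries = lapply(stage_res, `[[`, "summary"),
    stage_peaks = lapply(stage_res, `[[`, "peaks"),
    pmds = pmds,
    broad_pmd_fraction = broad_pmd_fraction,
    enhancers = enhancers,
    enhancer_entropy = entropy_score(enh_signal),
    specific_enhancers = specific_enh,
    ernas = ernas,
    zga_genes = zga,
    specific_genes = specific_genes,
    repeat_enrichment = enrich,
    allelic = allelic,
    artifacts = paths,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "run_manifest")
  yaml::write_yaml(list(seed = manifest$seed, config_hash = manifest$config_hash,
                        stages = as.list(manifest$stages),
                        reference_stage = reference_stage,
                        thresholds = manifest$thresholds,
                        scale_factors = as.list(manifest$scale_factors),
                        artifacts = as.list(manifest$artifacts),
                        elapsed_s = manifest$elapsed_s),
                   file.path(outdir, "manifest.yaml"))
  manifest
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- lapply(config, function(x) {
    if (is.data.frame(x)) lapply(x, function(col) unname(unclass(col))) else unclass(x)
  })
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: seed %d, %d stages (reference %s), %.1f s\n",
              x$seed, length(x$stages), x$reference_stage, x$elapsed_s))
  for (st in x$stages) {
    s <- x$summaries[[st]]
    cat(sprintf("  %-8s peaks %4d | broad>10kb %3d | >50kb %2d | coverage %5.1f%% | scale %.3f\n",
                st, s$n, s$broad, s$broad50, 100 * s$coverage, x$scale_factors[[st]]))
  }
  cat(sprintf("  PMDs: %d (broad-domain overlap %.1f%%); enhancers: %d (%d stage-specific)\n",
              nrow(x$pmds), 100 * x$broad_pmd_fraction, nrow(x$enhancers),
              nrow(x$specific_enhancers)))
  cat(sprintf("  eRNAs: %d; ZGA genes: %d; allelic calls: %d maternal / %d paternal\n",
              sum(x$ernas$erna_any), length(x$zga_genes),
              sum(x$allelic$call == "maternal"), sum(x$allelic$call == "paternal")))
  invisible(x)
}

#' Load a simulation config from a YAML file
#'
#' Thin wrapper mapping a flat YAML block onto [simulation_config()]
#' arguments; `genome` is given as a name-to-length map.
#'
#' @param path YAML file.
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$genome))
    y$genome <- chrom_sizes(names(y$genome), unlist(y$genome))
  if (!is.null(y$repeat_fractions))
    y$repeat_fractions <- unlist(y$repeat_fractions)
  do.call(simulation_config, y)
}
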