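# Transposon enrichment/expression statistics and allele-specific peak
# classification.

#' Observed/expected enrichment of peaks in repeat families
#'
#' For each family, the observed probability is the peak length covering the
#' family's elements over the total peak length; the expected probability is
#' the family's total length over the genome length; the enrichment ratio is
#' observed/expected.
#'
#' @param peaks Peak data.frame (total length > 0).
#' @param repeats Repeat table (chrom/start/end/family/class).
#' @param genome [chrom_sizes()].
#' @param families Families to report (default: all present); a requested
#'   family absent from the annotation is an error naming it.
#' @return data.frame family/observed/expected/ratio.
#' @export
repeat_enrichment <- function(peaks, repeats, genome, families = NULL) {
  if (is.null(families)) families <- sort(unique(repeats$family))
  missing <- setdiff(families, unique(repeats$family))
  if (length(missing)) stop("family absent from annotation: ", paste(missing, collapse = ", "))
  pk <- merge_intervals(peaks[, c("chrom", "start", "end"), drop = FALSE])
  peak_len <- sum(pk$end - pk$start)
  if (peak_len <= 0) stop("total peak length must be > 0")
  genome_len <- sum(genome)
  out <- lapply(families, function(fam) {
    fm <- merge_intervals(repeats[repeats$family == fam, c("chrom", "start", "end"), drop = FALSE])
    fam_len <- sum(fm$end - fm$start)
    obs <- intersect_length(pk, fm) / peak_len
    exp <- fam_len / genome_len
    data.frame(family = fam, observed = obs, expected = exp,
               ratio = if (exp > 0) obs / exp else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Repeat-family expression across stages
#'
#' Elements lying in exons (by default, at least half of the element) are
#' excluded; for each family, fragments are counted by midpoint over the
#' remaining elements, normalized by library size (per million fragments),
#' then z-scored across stages per family.
#'
#' @param fragments_by_stage Named list of fragment data.frames, one per
#'   stage (>= 2 stages).
#' @param repeats Repeat table.
#' @param exons Exon interval data.frame (e.g. [exon_regions()]).
#' @param exon_max_fraction An element is excluded when at least this
#'   fraction of it lies in exons (default 0.5).
#' @return List with `normalized` (family x stage, counts per million
#'   library fragments), `zscore` (same shape; zero-variance families set to
#'   0) and `flagged` (families with zero variance across stages).
#' @export
repeat_expression_profile <- function(fragments_by_stage, repeats, exons,
                                      exon_max_fraction = 0.5) {
  if (length(fragments_by_stage) < 2) stop("need >= 2 stages for z-scoring")
  exonic <- .overlap_bp(repeats, exons) >= exon_max_fraction * (repeats$end - repeats$start)
  kept <- repeats[!exonic, , drop = FALSE]
  fams <- sort(unique(repeats$family))
  counts <- vapply(fragments_by_stage, function(fr) {
    mid <- data.frame(chrom = fr$chrom, start = floor((fr$start + fr$end) / 2),
                      end = floor((fr$start + fr$end) / 2) + 1, stringsAsFactors = FALSE)
    vapply(fams, function(fam) {
      el <- kept[kept$family == fam, c("chrom", "start", "end"), drop = FALSE]
      sum(.overlap_bp(mid, el) >= 1)
    }, 0)
  }, numeric(length(fams)))
  counts <- matrix(counts, nrow = length(fams),
                   dimnames = list(fams, names(fragments_by_stage)))
  libs <- vapply(fragments_by_stage, nrow, 0L)
  normalized <- sweep(counts, 2, libs / 1e6, `/`)
  mu <- rowMeans(normalized)
  sdv <- apply(normalized, 1, stats::sd)
  z <- (normalized - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  list(normalized = normalized, zscore = z, flagged = fams[sdv == 0])
}

#' Classify allele-specific peaks
#'
#' Peaks with at least `min_density` SNP-informative reads per kb are tested
#' for parental bias with a one-degree chi-square test of the observed
#' maternal/paternal split against the background ratio `rho`; p-values are
#' Benjamini-Hochberg adjusted across tested peaks. A tested peak is called
#' maternal when adjusted p < `alpha` and the maternal:paternal read ratio
#' exceeds `fold_min` (paternal symmetric; a zero denominator counts as
#' infinite fold); otherwise it is biallelic. Peaks below the density cutoff
#' are untested.
#'
#' @param table data.frame with `length` (peak length, bp), `maternal` and
#'   `paternal` read counts (and any id columns, which are carried through).
#' @param rho Background maternal fraction in (0, 1); default `NULL`
#'   estimates it from the table's total maternal/(maternal+paternal).
#' @param alpha Adjusted-p cutoff (default 0.001).
#' @param fold_min Allelic ratio cutoff (default 5, strict `>`).
#' @param min_density Informative reads per kb required to test (default 10).
#' @param yates Apply Yates continuity correction (default FALSE).
#' @return `table` with `density`, `chisq`, `pvalue`, `fdr`, `fold`
#'   (max of the two allelic ratios) and `call` (factor maternal / paternal
#'   / biallelic / untested).
#' @export
classify_allelic <- function(table, rho = NULL, alpha = 0.001, fold_min = 5,
                             min_density = 10, yates = FALSE) {
  m <- table$maternal; p <- table$paternal; n <- m + p
  if (is.null(rho)) rho <- sum(m) / sum(n)
  if (rho <= 0 || rho >= 1) stop("rho must lie strictly between 0 and 1")
  table$density <- n * 1000 / table$length
  tested <- table$density >= min_density & n > 0
  em <- n * rho; ep <- n * (1 - rho)
  dev_m <- abs(m - em); dev_p <- abs(p - ep)
  if (yates) { dev_m <- pmax(dev_m - 0.5, 0); dev_p <- pmax(dev_p - 0.5, 0) }
  stat <- dev_m^2 / em + dev_p^2 / ep
  table$chisq <- ifelse(tested, stat, NA)
  table$pvalue <- ifelse(tested, stats::pchisq(stat, df = 1, lower.tail = FALSE), NA)
  table$fdr <- NA_real_
  table$fdr[tested] <- stats::p.adjust(table$pvalue[tested], method = "BH")
  fold_m <- ifelse(p > 0, m / p, Inf)
  fold_p <- ifelse(m > 0, p / m, Inf)
  table$fold <- pmax(ifelse(n > 0, fold_m, NA), ifelse(n > 0, fold_p, NA))
  call <- rep("untested", nrow(table))
  sig <- tested & !is.na(table$fdr) & table$fdr < alpha
  call[tested] <- "biallelic"
  call[sig & fold_m > fold_min] <- "maternal"
  call[sig & fold_p > fold_min] <- "paternal"
  table$call <- factor(call, levels = c("maternal", "paternal", "biallelic", "untested"))
  table
}
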