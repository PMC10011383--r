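# Enriched-domain calling and the peak/domain layer: a self-contained
# local-Poisson re-expression of broad-mode peak calling (strong/weak bin
# thresholds, gap linking), followed by the signal scoring, top-signal
# filtering, 5-kb merging, length taxonomy and cross-stage normalization
# the downstream analyses are built on.

#' Parameters of the enriched-domain caller
#'
#' Defaults mirror broad-mode calling with a strong threshold of 1e-3, a
#' weak (linking) threshold of 0.01 and a 500-bp maximum gap, evaluated on
#' 100-bp bins against the larger of the genome-wide rate and local input
#' background over 5-kb and 10-kb windows.
#'
#' @param p_strong Upper-tail Poisson p-value a bin must reach to seed a
#'   domain (default 1e-3).
#' @param p_weak Linking threshold; weak bins (p <= p_weak) are chained into
#'   candidate domains (default 0.01). Must satisfy `p_strong <= p_weak`.
#' @param max_gap Maximum clean gap (bp) bridged when linking weak bins
#'   (default 500).
#' @param bin Bin width in bp (default 100).
#' @param local_windows Local background window widths in bp (default 5 kb
#'   and 10 kb), centered on each bin.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(p_strong = 1e-3, p_weak = 0.01, max_gap = 500,
                          bin = 100, local_windows = c(5000, 10000)) {
  if (p_strong > p_weak) stop("p_strong must be <= p_weak")
  if (max_gap < 0) stop("max_gap must be >= 0")
  structure(list(p_strong = p_strong, p_weak = p_weak, max_gap = max_gap,
                 bin = bin, local_windows = local_windows),
            class = "caller_params")
}

# Centered running mean with edge-corrected window sizes (cumsum trick).
.running_mean <- function(v, k) {
  n <- length(v)
  half <- floor(k / 2)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Call enriched domains from chip and input count tracks
#'
#' A simplified local-Poisson caller: input counts are scaled to the chip
#' library depth; each bin's background rate is the maximum of the
#' genome-wide mean chip rate and the scaled-input mean over each local
#' window centered on the bin; bins are scored by the upper-tail Poisson
#' p-value of the chip count. Weak bins (p <= `p_weak`) separated by at most
#' `max_gap` bp are linked into candidates, and candidates containing at
#' least one strong bin (p <= `p_strong`) are emitted as peaks.
#'
#' Per-bin Poisson enrichment p-values
#'
#' The scoring stage of [call_enriched_domains()], exposed for calibration
#' checks: input counts are scaled to the chip depth, the per-bin
#' background rate is the maximum of the genome-wide mean chip rate and the
#' scaled-input means over the local windows, and each bin receives the
#' upper-tail Poisson p-value of its chip count.
#'
#' @inheritParams call_enriched_domains
#' @return Named list of per-chromosome p-value vectors (one per bin).
#' @export
enrichment_pvalues <- function(chip, input, params = caller_params()) {
  if (chip$bin != params$bin || input$bin != params$bin)
    stop("track bin width must equal params$bin")
  chip_total <- sum(unlist(chip$values))
  input_total <- sum(unlist(input$values))
  if (chip_total <= 0 || input_total <= 0) stop("both libraries must be non-empty")
  scale <- chip_total / input_total
  lambda_bg <- chip_total / sum(lengths(chip$values))
  out <- lapply(names(chip$values), function(ch) {
    cc <- chip$values[[ch]]
    lambda <- rep(lambda_bg, length(cc))
    for (w in params$local_windows)
      lambda <- pmax(lambda, .running_mean(input$values[[ch]] * scale,
                                           round(w / params$bin)))
    stats::ppois(cc - 1, lambda, lower.tail = FALSE)
  })
  names(out) <- names(chip$values)
  out
}

#' @param chip,input Count `binned_track`s with bin width `params$bin`.
#' @param params A [caller_params()] list.
#' @return Peak data.frame (chrom/start/end), sorted and non-overlapping.
#' @export
call_enriched_domains <- function(chip, input, params = caller_params()) {
  pvals <- enrichment_pvalues(chip, input, params)
  out <- lapply(names(chip$values), function(ch) {
    p <- pvals[[ch]]
    weak <- which(p <= params$p_weak)
    if (!length(weak)) return(NULL)
    strong <- p <= params$p_strong
    cand <- merge_intervals(data.frame(chrom = ch, start = (weak - 1) * params$bin,
                                       end = pmin(weak * params$bin, chip$genome[ch]),
                                       stringsAsFactors = FALSE),
                            gap = params$max_gap)
    strong_idx <- which(strong)
    strong_start <- (strong_idx - 1) * params$bin
    has_strong <- vapply(seq_len(nrow(cand)), function(i)
      any(strong_start >= cand$start[i] & strong_start < cand$end[i]), TRUE)
    cand[has_strong, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out)) .empty_intervals() else sort_intervals(out)
}

#' Score peaks by 100-bp bin FPKM
#'
#' The signal of a peak or domain is the sum of FPKM values of the 100-bp
#' bins located in it (bins assigned by midpoint); the mean over the same
#' bins is the per-bp-scale signal used for cross-stage normalization.
#'
#' @param peaks Peak data.frame.
#' @param fpkm100 FPKM `binned_track` with 100-bp bins (or matching the
#'   caller's bin width).
#' @return `peaks` with `signal_sum`, `signal_mean` and `n_bins` columns.
#' @export
score_peaks <- function(peaks, fpkm100) {
  .check_intervals(peaks, fpkm100$genome, what = "peaks")
  peaks$signal_sum <- 0
  peaks$signal_mean <- 0
  peaks$n_bins <- 0L
  if (nrow(peaks) == 0) return(peaks)
  bin <- fpkm100$bin
  for (ch in unique(peaks$chrom)) {
    v <- fpkm100$values[[ch]]
    mids <- (seq_along(v) - 1) * bin + .bin_lengths(fpkm100, ch) / 2
    cs <- c(0, cumsum(v))
    rows <- which(peaks$chrom == ch)
    lo <- findInterval(peaks$start[rows] - 0.25, mids)   # bins with mid <  start
    hi <- findInterval(peaks$end[rows] - 0.25, mids)     # bins with mid <  end
    n <- hi - lo
    s <- cs[hi + 1] - cs[lo + 1]
    peaks$signal_sum[rows] <- s
    peaks$signal_mean[rows] <- ifelse(n > 0, s / n, 0)
    peaks$n_bins[rows] <- as.integer(n)
  }
  peaks
}

#' Keep the peaks with top signal
#'
#' Retains the peaks whose `signal_sum` reaches the nearest-rank top-`q`
#' threshold; ties at the threshold are kept.
#'
#' @param peaks Scored peak data.frame (from [score_peaks()]).
#' @param q Fraction to keep (default 0.75).
#' @return Filtered peak data.frame (empty input gives empty output).
#' @export
filter_top_signal <- function(peaks, q = 0.75) {
  if (nrow(peaks) == 0) return(peaks)
  if (is.null(peaks$signal_sum)) stop("peaks must be scored before filtering")
  k <- ceiling(q * nrow(peaks))
  if (k == 0) return(peaks[0, , drop = FALSE])
  thr <- sort(peaks$signal_sum, decreasing = TRUE)[k]
  out <- peaks[peaks$signal_sum >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge peaks within a gap and re-score
#'
#' @param peaks Peak data.frame.
#' @param gap Merge distance in bp (default 5000: "within 5 kb").
#' @param fpkm100 Optional FPKM track; when given, merged peaks are
#'   re-scored with [score_peaks()].
#' @return Merged (and re-scored) peak data.frame.
#' @export
merge_within_gap <- function(peaks, gap = 5000, fpkm100 = NULL) {
  out <- merge_intervals(peaks[, c("chrom", "start", "end")], gap = gap)
  if (!is.null(fpkm100)) out <- score_peaks(out, fpkm100)
  out
}

#' Peak length classes
#'
#' Strict thresholds: typical <= 10 kb; broad > 10 kb; nested sub-classes
#' broad20 (> 20 kb) and broad50 (> 50 kb).
#'
#' @param peaks Peak data.frame.
#' @return Character vector `"typical"`/`"broad"` per peak.
#' @export
peak_length_class <- function(peaks) {
  ifelse(peaks$end - peaks$start > 10000, "broad", "typical")
}

#' Summarize a peak set
#'
#' @param peaks Peak data.frame.
#' @param genome [chrom_sizes()].
#' @return List of class `peak_summary`: `n`, counts per nested length class
#'   (`typical` <= 10 kb, `broad` > 10 kb, `broad20` > 20 kb, `broad50`
#'   > 50 kb) and `coverage` (fraction of genome covered).
#' @export
summarize_peaks <- function(peaks, genome) {
  len <- peaks$end - peaks$start
  structure(list(
    n = nrow(peaks),
    typical = sum(len <= 10000),
    broad = sum(len > 10000),
    broad20 = sum(len > 20000),
    broad50 = sum(len > 50000),
    coverage = coverage_fraction(peaks[, c("chrom", "start", "end"), drop = FALSE], genome)
  ), class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf("peaks: %d (typical %d, broad>10kb %d, >20kb %d, >50kb %d); genome coverage %.1f%%\n",
              x$n, x$typical, x$broad, x$broad20, x$broad50, 100 * x$coverage))
  invisible(x)
}

# Does each row of `a` overlap `b` under the chosen criterion?
.overlaps_set <- function(a, b, criterion = c("any", "fraction"), min_fraction = 0.5) {
  criterion <- match.arg(criterion)
  ov <- .overlap_bp(a, b)
  if (criterion == "any") ov >= 1 else ov >= min_fraction * (a$end - a$start)
}

#' Overlap (Venn) table between two peak sets
#'
#' @param a,b Peak data.frames.
#' @param criterion `"any"` (>= 1 bp, symmetric) or `"fraction"` (overlap
#'   covering at least `min_fraction` of the query peak).
#' @param min_fraction Fraction threshold for `criterion = "fraction"`.
#' @return List with `a_total`, `b_total`, `a_overlap`, `b_overlap`,
#'   `a_only`, `b_only` counts.
#' @export
overlap_table <- function(a, b, criterion = c("any", "fraction"), min_fraction = 0.5) {
  criterion <- match.arg(criterion)
  a_hit <- .overlaps_set(a, b, criterion, min_fraction)
  b_hit <- .overlaps_set(b, a, criterion, min_fraction)
  list(a_total = nrow(a), b_total = nrow(b),
       a_overlap = sum(a_hit), b_overlap = sum(b_hit),
       a_only = sum(!a_hit), b_only = sum(!b_hit))
}

#' Classify zygotic peaks by gametic inheritance
#'
#' Each zygotic peak is labeled by whether it overlaps oocyte and/or sperm
#' peak sets (called under the same parameters): `oocyte-only`,
#' `sperm-only`, `shared`, or `de novo`.
#'
#' @param zygote,oocyte,sperm Peak data.frames.
#' @param criterion,min_fraction Overlap criterion as in [overlap_table()].
#' @return `zygote` with an `inheritance` factor column; label fractions sum
#'   to 1.
#' @export
classify_inheritance <- function(zygote, oocyte, sperm,
                                 criterion = c("any", "fraction"), min_fraction = 0.5) {
  criterion <- match.arg(criterion)
  in_o <- .overlaps_set(zygote, oocyte, criterion, min_fraction)
  in_s <- .overlaps_set(zygote, sperm, criterion, min_fraction)
  lab <- ifelse(in_o & in_s, "shared",
         ifelse(in_o, "oocyte-only",
         ifelse(in_s, "sperm-only", "de novo")))
  zygote$inheritance <- factor(lab, levels = c("oocyte-only", "sperm-only", "shared", "de novo"))
  zygote
}

#' Cross-stage scale factor from top-quartile medians
#'
#' Broadly distributed signal depresses per-bin FPKM, so stages are put on a
#' common scale by assuming the most strongly modified regions are fully
#' modified everywhere: the median `signal_mean` of the top-25% peaks (by
#' `signal_mean`) should be equal between the reference stage and each other
#' stage. Multiplying `other`'s signal by the returned factor equalizes the
#' two medians exactly.
#'
#' @param reference,other Scored peak data.frames (>= 4 peaks each).
#' @param top Top fraction defining the fully-modified peak set (default 0.25).
#' @param center Summary statistic, `"median"` (default) or `"mean"`.
#' @return Scalar scale factor for `other`.
#' @export
stage_scale_factor <- function(reference, other, top = 0.25,
                               center = c("median", "mean")) {
  center <- match.arg(center)
  if (nrow(reference) < 4 || nrow(other) < 4)
    stop("need at least 4 scored peaks in each set")
  fun <- if (center == "median") stats::median else mean
  top_stat <- function(p) {
    k <- ceiling(top * nrow(p))
    fun(sort(p$signal_mean, decreasing = TRUE)[seq_len(k)])
  }
  top_stat(reference) / top_stat(other)
}

#' Apply a scale factor to peak signals
#'
#' @param peaks Scored peak data.frame.
#' @param factor Scale factor from [stage_scale_factor()].
#' @return `peaks` with `signal_sum` and `signal_mean` multiplied by `factor`.
#' @export
apply_scale_factor <- function(peaks, factor) {
  peaks$signal_sum <- peaks$signal_sum * factor
  peaks$signal_mean <- peaks$signal_mean * factor
  peaks
}
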