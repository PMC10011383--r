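#' Chromosome sizes
#'
#' A named integer vector mapping chromosome names to lengths in bp, the
#' coordinate frame every interval operation validates against.
#'
#' @param names Character vector of chromosome names (unique).
#' @param lengths Positive integer lengths in bp, one per name.
#' @return Named numeric vector of class `chrom_sizes`.
#' @examples
#' chrom_sizes("chrS", 1e7)
#' @export
chrom_sizes <- function(names, lengths) {
  if (anyDuplicated(names)) stop("chromosome names must be unique")
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths)) stop("names and lengths differ in length")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) stop("chromosome lengths must be positive")
  structure(stats::setNames(lengths, as.character(names)), class = "chrom_sizes")
}

#' @export
print.chrom_sizes <- function(x, ...) {
  cat("chrom_sizes:", length(x), "chromosome(s),", format(sum(x), big.mark = ","), "bp total\n")
  print(unclass(x))
  invisible(x)
}

# ---- internal interval plumbing ---------------------------------------------
# Intervals travel as data.frames with columns chrom/start/end in the BED
# convention (0-based half-open).  GRanges (1-based closed) is the engine
# behind merge/intersect/coverage; conversion happens only here.

.empty_intervals <- function(extra = character()) {
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    stringsAsFactors = FALSE)
  for (nm in extra) out[[nm]] <- character()
  out
}

.check_intervals <- function(x, genome = NULL, what = "interval set") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop(what, " must be a data.frame with chrom/start/end columns")
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0) || any(x$start >= x$end))
    stop(what, ": intervals must satisfy 0 <= start < end")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(x$chrom), names(genome))
    if (length(unknown))
      stop(what, ": unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(x$end > genome[x$chrom]))
      stop(what, ": interval exceeds chromosome length")
  }
  invisible(x)
}

.as_gr <- function(x, genome = NULL) {
  sl <- if (is.null(genome)) NA else unclass(genome)
  lev <- if (is.null(genome)) unique(x$chrom) else names(genome)
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = lev),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    seqlengths = if (is.null(genome)) NULL else sl
  )
}

.gr_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Sort an interval table by chromosome then start
#'
#' @param x Interval data.frame (chrom/start/end).
#' @return The same data.frame sorted; row names dropped.
#' @export
sort_intervals <- function(x) {
  .check_intervals(x)
  if (nrow(x) == 0) return(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Merge intervals closer than a gap
#'
#' Unions intervals whose separation (`next start - previous end`) is at most
#' `gap` bp, so "within 5 kb" merges at exactly 5000 bp. Idempotent; the
#' result is sorted and pairwise disjoint.
#'
#' @param x Interval data.frame (chrom/start/end, 0-based half-open).
#' @param gap Non-negative merge distance in bp. With `gap = 0` only
#'   overlapping or abutting intervals are unioned; positive `gap`
#'   additionally bridges clean gaps of at most `gap` bp (inclusive).
#' @return Merged interval data.frame.
#' @examples
#' merge_intervals(data.frame(chrom = "chr1", start = c(100, 150), end = c(200, 300)))
#' @export
merge_intervals <- function(x, gap = 0) {
  if (length(gap) != 1 || !is.finite(gap) || gap < 0) stop("gap must be a single non-negative number")
  .check_intervals(x)
  if (nrow(x) == 0) return(.empty_intervals())
  gr <- GenomicRanges::reduce(.as_gr(x), min.gapwidth = gap + 1)
  sort_intervals(.gr_df(gr))
}

#' Total overlap between two interval sets
#'
#' @param a,b Interval data.frames; merged internally so duplicated coverage
#'   is not double counted.
#' @return Total overlapping bases (numeric scalar). Symmetric in `a`, `b`.
#' @export
intersect_length <- function(a, b) {
  .check_intervals(a); .check_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  lev <- union(unique(a$chrom), unique(b$chrom))
  gra <- GenomicRanges::GRanges(factor(a$chrom, lev), IRanges::IRanges(a$start + 1, a$end))
  grb <- GenomicRanges::GRanges(factor(b$chrom, lev), IRanges::IRanges(b$start + 1, b$end))
  ov <- GenomicRanges::intersect(GenomicRanges::reduce(gra), GenomicRanges::reduce(grb))
  sum(as.numeric(GenomicRanges::width(ov)))
}

#' Fraction of the genome covered by an interval set
#'
#' @param x Interval data.frame.
#' @param genome A [chrom_sizes()] vector; intervals on unknown chromosomes
#'   are an error.
#' @return Covered bp / genome bp, in \[0, 1\].
#' @export
coverage_fraction <- function(x, genome) {
  .check_intervals(x, genome)
  if (nrow(x) == 0) return(0)
  m <- merge_intervals(x)
  sum(as.numeric(m$end - m$start)) / sum(genome)
}

# Per-row overlap of `a` with the merged union of `b`, in bp.  Workhorse for
# the 150-bp assignment rule and repeat enrichment.
.overlap_bp <- function(a, b) {
  if (nrow(a) == 0) return(numeric(0))
  if (nrow(b) == 0) return(rep(0, nrow(a)))
  lev <- union(unique(a$chrom), unique(b$chrom))
  gra <- GenomicRanges::GRanges(factor(a$chrom, lev), IRanges::IRanges(a$start + 1, a$end))
  grb <- GenomicRanges::reduce(
    GenomicRanges::GRanges(factor(b$chrom, lev), IRanges::IRanges(b$start + 1, b$end)))
  hits <- GenomicRanges::findOverlaps(gra, grb)
  if (length(hits) == 0) return(rep(0, nrow(a)))
  w <- GenomicRanges::width(IRanges::pintersect(
    gra[S4Vectors::queryHits(hits)], grb[S4Vectors::subjectHits(hits)]))
  out <- rep(0, nrow(a))
  agg <- rowsum(as.numeric(w), S4Vectors::queryHits(hits))
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
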