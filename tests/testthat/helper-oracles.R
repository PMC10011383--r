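# Brute-force per-base oracles and tiny fixture builders, independent of
# the interval engine they check.

toy_genome <- function(size = 10000, chroms = "chrT") {
  chrom_sizes(chroms, rep(size, length(chroms)))
}

# per-chromosome logical base mask of an interval set
interval_mask <- function(x, genome) {
  lapply(names(genome), function(ch) {
    m <- logical(genome[[ch]])
    rows <- which(x$chrom == ch)
    for (i in rows) m[(x$start[i] + 1):x$end[i]] <- TRUE
    m
  }) |> stats::setNames(names(genome))
}

mask_intersect_length <- function(a, b, genome) {
  ma <- interval_mask(a, genome); mb <- interval_mask(b, genome)
  sum(vapply(names(genome), function(ch) sum(ma[[ch]] & mb[[ch]]), 0))
}

mask_coverage_fraction <- function(x, genome) {
  m <- interval_mask(x, genome)
  sum(vapply(m, sum, 0)) / sum(genome)
}

# merge oracle: bridge gaps of <= gap bases between covered runs, then read
# the runs back off the mask
mask_merge <- function(x, genome, gap = 0) {
  out <- lapply(names(genome), function(ch) {
    m <- interval_mask(x, genome)[[ch]]
    if (!any(m)) return(NULL)
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    inner_gap <- !r$values & r$lengths <= gap &
      seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
    for (i in which(inner_gap)) m[starts[i]:ends[i]] <- TRUE
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    data.frame(chrom = ch, start = starts[r$values] - 1, end = ends[r$values],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric())
  rownames(out) <- NULL
  out
}

random_intervals <- function(n, genome, max_len = 500) {
  ch <- sample(names(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (unclass(genome)[ch] - len))
  data.frame(chrom = ch, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# direct evaluation of the Shannon stage-specificity entropy, kept separate
# from the package implementation
entropy_direct <- function(v) {
  r <- v / sum(v)
  r <- r[r > 0]
  -sum(r * log(r) / log(2))
}

# per-row overlap of peaks `a` with a single interval `b`, by direct
# coordinate arithmetic
.overlap_bp_test <- function(a, b) {
  pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start)) *
    as.numeric(a$chrom == b$chrom)
}

# small count track built by hand: one chromosome, explicit per-bin counts
toy_track <- function(counts, bin = 100, semantics = "counts") {
  g <- chrom_sizes("chrT", length(counts) * bin)
  binned_track(g, bin, values = list(chrT = counts), semantics = semantics)
}
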