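# Binned tag densities: the FPKM tag-density layer the peak caller, promoter
# scoring and profile plots are built on.

#' Fixed-width binned signal track
#'
#' @param genome [chrom_sizes()].
#' @param bin Bin width in bp (> 0).
#' @param values Named list of per-chromosome numeric vectors; each vector
#'   has `ceiling(chrom_length / bin)` entries. Missing chromosomes are
#'   filled with zeros.
#' @param semantics One of `"counts"`, `"fpkm"`, `"subtracted"`.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(genome, bin, values = NULL,
                         semantics = c("counts", "fpkm", "subtracted")) {
  semantics <- match.arg(semantics)
  if (length(bin) != 1 || bin <= 0) stop("bin width must be positive")
  nbins <- ceiling(unclass(genome) / bin)
  vals <- lapply(names(genome), function(ch) {
    v <- if (!is.null(values) && !is.null(values[[ch]])) values[[ch]] else numeric(nbins[ch])
    if (length(v) != nbins[ch])
      stop("track for ", ch, " has ", length(v), " bins, expected ", nbins[ch])
    v
  })
  names(vals) <- names(genome)
  structure(list(genome = genome, bin = bin, values = vals, semantics = semantics),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %d-bp bins (%s), %d chromosome(s), %d bins total\n",
              x$bin, x$semantics, length(x$values),
              sum(lengths(x$values))))
  invisible(x)
}

# Bin lengths in bp; the terminal bin may be partial.
.bin_lengths <- function(track, chrom) {
  n <- length(track$values[[chrom]])
  len <- rep(track$bin, n)
  len[n] <- track$genome[chrom] - (n - 1) * track$bin
  len
}

#' Convert a track to bedGraph rows (non-zero bins only)
#'
#' @param track A [binned_track()].
#' @return data.frame chrom/start/end/value, one row per non-zero bin.
#' @export
track_to_bedgraph <- function(track) {
  out <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    i <- which(v != 0)
    if (!length(i)) return(NULL)
    data.frame(chrom = ch, start = (i - 1) * track$bin,
               end = pmin(i * track$bin, track$genome[ch]),
               value = v[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) .empty_intervals("value") else { rownames(out) <- NULL; out }
}

#' Bin fragments into a count track
#'
#' Each fragment is assigned to the bin containing its midpoint (floor
#' convention: a midpoint exactly on a bin boundary belongs to the
#' right-hand bin), so the track sum equals the fragment count.
#'
#' @param fragments Interval data.frame of aligned-fragment surrogates.
#' @param genome [chrom_sizes()].
#' @param bin Bin width in bp.
#' @return A `binned_track` with counts semantics.
#' @export
bin_fragments <- function(fragments, genome, bin) {
  .check_intervals(fragments, genome, what = "fragments")
  track <- binned_track(genome, bin, semantics = "counts")
  if (nrow(fragments) == 0) return(track)
  mid <- floor((fragments$start + fragments$end) / 2)
  idx <- floor(mid / bin) + 1
  for (ch in unique(fragments$chrom)) {
    sel <- fragments$chrom == ch
    track$values[[ch]] <- as.numeric(
      tabulate(idx[sel], nbins = length(track$values[[ch]])))
  }
  track
}

#' FPKM-normalize a count track
#'
#' value = count / (bin length in kb x library size in millions). The
#' terminal partial bin is normalized by its actual length, so edge bins are
#' not inflated.
#'
#' @param track Count `binned_track`.
#' @param library_size Total mapped fragments in the library (> 0).
#' @return FPKM `binned_track`.
#' @export
fpkm_normalize <- function(track, library_size) {
  if (length(library_size) != 1 || library_size <= 0) stop("library_size must be positive")
  if (track$semantics != "counts") stop("fpkm_normalize expects a counts track")
  out <- track
  for (ch in names(track$values)) {
    kb <- .bin_lengths(track, ch) / 1000
    out$values[[ch]] <- track$values[[ch]] / (kb * library_size / 1e6)
  }
  out$semantics <- "fpkm"
  out
}

#' Subtract an input track, floored at zero
#'
#' Per-bin `max(sample - input, 0)`; the floor mirrors the convention that
#' promoters with less ChIP than input signal carry zero signal.
#'
#' @param sample,input FPKM `binned_track`s with identical genome and bin.
#' @return `binned_track` with subtracted semantics (everywhere >= 0).
#' @export
subtract_input <- function(sample, input) {
  if (sample$bin != input$bin || !identical(names(sample$genome), names(input$genome)) ||
      !all(unclass(sample$genome) == unclass(input$genome)))
    stop("sample and input tracks must share genome and bin width")
  out <- sample
  for (ch in names(sample$values))
    out$values[[ch]] <- pmax(sample$values[[ch]] - input$values[[ch]], 0)
  out$semantics <- "subtracted"
  out
}

#' Subsample fragments without replacement
#'
#' @param fragments Interval data.frame.
#' @param n Number of fragments to keep (`0 <= n <= nrow(fragments)`).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Subsampled fragment data.frame (original order retained).
#' @export
subsample_fragments <- function(fragments, n, seed) {
  if (n > nrow(fragments)) stop("cannot subsample ", n, " from ", nrow(fragments), " fragments")
  if (n == nrow(fragments)) return(fragments)
  old <- .save_seed(seed)
  on.exit(.restore_seed(old))
  idx <- sort(sample.int(nrow(fragments), n))
  out <- fragments[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Seed scoping: set the RNG inside an operation without disturbing the
# caller's stream.
.save_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Pearson correlation between tracks
#'
#' Reproducibility statistic between replicate (or stage) tag-density
#' tracks, computed over all genome bins (zeros included).
#'
#' @param tracks Named list of `binned_track`s with identical binning.
#' @return Symmetric matrix of Pearson r; a constant track yields `NA` in
#'   its row/column (flagged with a warning), never a silent 0.
#' @export
correlation_matrix <- function(tracks) {
  if (length(tracks) < 2) stop("need at least two tracks")
  bins <- vapply(tracks, function(t) t$bin, 0)
  if (length(unique(bins)) != 1) stop("tracks must share bin width")
  m <- vapply(tracks, function(t) unlist(t$values, use.names = FALSE),
              numeric(sum(lengths(tracks[[1]]$values))))
  const <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (any(const)) warning("constant track(s): correlation undefined, returning NA")
  r <- suppressWarnings(stats::cor(m))
  r[const, ] <- NA; r[, const] <- NA
  d <- diag(r); d[!const] <- 1; diag(r) <- d
  r
}

#' Average signal profile around anchor points
#'
#' The window from `half_window` upstream to `half_window` downstream of
#' each anchor is segmented into non-overlapping `profile_bin`-bp bins
#' (e.g. +/-2 kb in 20-bp bins gives 200 entries). Each profile bin takes the
#' mean track value over the genome bins whose midpoints fall inside it;
#' entries are then averaged across anchors. Minus-strand anchors are
#' flipped so the profile reads 5'->3'.
#'
#' @param anchors data.frame with chrom and pos (bp), optional strand.
#' @param track A `binned_track` whose bin width is <= `profile_bin`.
#' @param half_window Half-window in bp.
#' @param profile_bin Profile bin width in bp; must divide `half_window`.
#' @return Numeric vector of length `2 * half_window / profile_bin`.
#'   Out-of-range bins of anchors near chromosome edges are excluded from
#'   the averages.
#' @export
profile_around <- function(anchors, track, half_window = 2000, profile_bin = 20) {
  if (half_window %% profile_bin != 0) stop("half_window must be divisible by profile_bin")
  if (track$bin > profile_bin) stop("track bin must be <= profile_bin")
  nb <- 2 * half_window / profile_bin
  acc <- numeric(nb); cnt <- numeric(nb)
  # genome-bin midpoints, computed once per chromosome
  mids_by_chrom <- lapply(names(track$values), function(ch) {
    n <- length(track$values[[ch]])
    (seq_len(n) - 1) * track$bin + .bin_lengths(track, ch) / 2
  })
  names(mids_by_chrom) <- names(track$values)
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) stop("anchor on unknown chromosome ", ch)
    mids <- mids_by_chrom[[ch]]
    lo <- anchors$pos[i] - half_window
    in_win <- which(mids >= lo & mids < lo + 2 * half_window)
    if (!length(in_win)) next
    j <- floor((mids[in_win] - lo) / profile_bin) + 1
    sums <- rowsum(v[in_win], j)
    nper <- rowsum(rep(1, length(j)), j)
    jj <- as.integer(rownames(sums))
    vals <- rep(NA_real_, nb); vals[jj] <- sums[, 1] / nper[, 1]
    if (!is.null(anchors$strand) && anchors$strand[i] == "-") vals <- rev(vals)
    ok <- !is.na(vals)
    acc[ok] <- acc[ok] + vals[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA
  out
}
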