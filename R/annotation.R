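# Peak-to-element assignment, promoter marking/scoring and distal linking.

#' Assign peaks to genomic elements
#'
#' Each peak is assigned to the highest-priority element class with which it
#' overlaps by at least `min_overlap` bp; the priority ranking is promoter,
#' TES, exon, intron, then intergenic for peaks matching none.
#'
#' @param peaks Peak data.frame.
#' @param genes Gene table.
#' @param genome [chrom_sizes()].
#' @param min_overlap Minimum overlap in bp (default 150).
#' @param promoter_half Promoter/TES half-window in bp (default 2500).
#' @return `peaks` with an `element` factor column (levels promoter, TES,
#'   exon, intron, intergenic) — exactly one label per peak.
#' @export
assign_elements <- function(peaks, genes, genome, min_overlap = 150,
                            promoter_half = 2500) {
  sets <- .element_sets(genes, genome, promoter_half)
  lab <- rep("intergenic", nrow(peaks))
  for (cls in rev(names(sets))) {  # lowest priority first; later writes win
    hit <- .overlap_bp(peaks, sets[[cls]]) >= min_overlap
    lab[hit] <- cls
  }
  peaks$element <- factor(lab, levels = c(names(sets), "intergenic"))
  peaks
}

#' Input-subtracted promoter signal
#'
#' Mean FPKM over the promoter window in the sample track minus the same
#' quantity in the input track, floored at 0.
#'
#' @param genes Gene table.
#' @param sample,input FPKM `binned_track`s with identical binning.
#' @param genome [chrom_sizes()].
#' @param promoter_half Promoter half-window in bp (default 2500).
#' @return Named numeric vector of subtracted promoter FPKM, one per gene.
#' @export
promoter_signal <- function(genes, sample, input, genome, promoter_half = 2500) {
  prom <- promoter_regions(genes, genome, promoter_half)
  if (any(prom$end <= prom$start)) stop("promoter clipped to empty window")
  mean_over <- function(track, region) {
    s <- score_peaks(region[, c("chrom", "start", "end")], track)
    ifelse(s$n_bins > 0, s$signal_sum / s$n_bins, 0)
  }
  out <- pmax(mean_over(sample, prom) - mean_over(input, prom), 0)
  names(out) <- genes$gene_id
  out
}

#' Mark promoters overlapped by peaks
#'
#' @param genes Gene table.
#' @param peaks Peak data.frame.
#' @param genome [chrom_sizes()].
#' @param min_overlap Minimum overlap in bp; the default 1 marks a promoter
#'   touched by any peak, 150 applies the element-assignment rule instead.
#' @param promoter_half Promoter half-window in bp.
#' @return Named logical vector (marked promoters), one entry per gene.
#' @export
mark_promoters <- function(genes, peaks, genome, min_overlap = 1,
                           promoter_half = 2500) {
  prom <- promoter_regions(genes, genome, promoter_half)
  out <- .overlap_bp(prom, peaks) >= min_overlap
  names(out) <- genes$gene_id
  out
}

#' Distal peaks (outside promoters)
#'
#' @param peaks Peak data.frame.
#' @param genes Gene table.
#' @param genome [chrom_sizes()].
#' @param promoter_half Promoter half-window in bp.
#' @return The subset of `peaks` not overlapping any promoter window.
#' @export
distal_peaks <- function(peaks, genes, genome, promoter_half = 2500) {
  prom <- promoter_regions(genes, genome, promoter_half)
  out <- peaks[.overlap_bp(peaks, prom) == 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link distal peaks to genes within a TSS radius
#'
#' A distal peak is linked to every gene whose TSS lies within `radius` of
#' the peak center; the single closest-TSS gene is reported as well, with
#' equidistant ties broken by gene id order.
#'
#' @param peaks Distal peak data.frame.
#' @param genes Gene table.
#' @param radius Linking radius in bp (default 300 kb).
#' @return List with `links` (data.frame peak_id/gene_id/distance, all genes
#'   within radius) and `closest` (data.frame peak_id/gene_id/distance, one
#'   row per peak with at least one gene on its chromosome).
#' @export
link_distal_peaks <- function(peaks, genes, radius = 3e5) {
  if (nrow(peaks) == 0)
    return(list(links = data.frame(peak_id = character(), gene_id = character(),
                                   distance = numeric()),
                closest = data.frame(peak_id = character(), gene_id = character(),
                                     distance = numeric())))
  peak_id <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  center <- (peaks$start + peaks$end) / 2
  tss <- gene_tss(genes)
  links <- list(); closest <- list()
  for (i in seq_len(nrow(peaks))) {
    same <- which(genes$chrom == peaks$chrom[i])
    if (!length(same)) next
    d <- abs(tss[same] - center[i])
    hit <- same[d <= radius]
    if (length(hit))
      links[[length(links) + 1]] <- data.frame(
        peak_id = peak_id[i], gene_id = genes$gene_id[hit],
        distance = d[d <= radius], stringsAsFactors = FALSE)
    ord <- order(d, genes$gene_id[same])
    closest[[length(closest) + 1]] <- data.frame(
      peak_id = peak_id[i], gene_id = genes$gene_id[same][ord[1]],
      distance = d[ord[1]], stringsAsFactors = FALSE)
  }
  empty <- data.frame(peak_id = character(), gene_id = character(), distance = numeric())
  list(links = if (length(links)) do.call(rbind, links) else empty,
       closest = if (length(closest)) do.call(rbind, closest) else empty)
}
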