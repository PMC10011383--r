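# Gene-model geometry: strand-aware TSS/TTS, promoter and TES windows, and
# the five-class element partition used for peak assignment.

#' Transcription start sites of a gene table
#'
#' The TSS of a minus-strand gene is its rightmost transcript coordinate.
#'
#' @param genes Gene table as returned by `read_table(kind = "genes")`.
#' @return Numeric vector of TSS positions (bp), one per gene.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
}

#' @rdname gene_tss
#' @return For `gene_tts`, the transcription termination sites.
#' @export
gene_tts <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_end, genes$tx_start)
}

.window_around <- function(pos, half, chrom, genome) {
  start <- pmax(pos - half, 0)
  end <- pmin(pos + half, genome[chrom])
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

#' Promoter and TES windows
#'
#' Promoters are TSS +/- 2.5 kb; TES regions are TTS +/- 2.5 kb. Windows are
#' clipped at chromosome edges rather than rejected.
#'
#' @param genes Gene table.
#' @param genome [chrom_sizes()].
#' @param half Half-window in bp (default 2500).
#' @return Interval data.frame with a `gene_id` column, one row per gene.
#' @export
promoter_regions <- function(genes, genome, half = 2500) {
  out <- .window_around(gene_tss(genes), half, genes$chrom, genome)
  out$gene_id <- genes$gene_id
  out
}

#' @rdname promoter_regions
#' @export
tes_regions <- function(genes, genome, half = 2500) {
  out <- .window_around(gene_tts(genes), half, genes$chrom, genome)
  out$gene_id <- genes$gene_id
  out
}

#' Exon intervals of a gene table
#'
#' @param genes Gene table.
#' @return Interval data.frame of all exons with `gene_id`.
#' @export
exon_regions <- function(genes) {
  if (nrow(genes) == 0) return(.empty_intervals("gene_id"))
  n <- vapply(genes$exon_starts, length, 0L)
  data.frame(chrom = rep(genes$chrom, n),
             start = unlist(genes$exon_starts),
             end = unlist(genes$exon_ends),
             gene_id = rep(genes$gene_id, n),
             stringsAsFactors = FALSE)
}

# The five-class genomic element partition: promoter > TES > exon > intron >
# intergenic.  Element sets are built gene-wise then unioned per class;
# introns are gene bodies minus exons minus promoter/TES windows.
.element_sets <- function(genes, genome, half = 2500) {
  prom <- merge_intervals(promoter_regions(genes, genome, half))
  tes <- merge_intervals(tes_regions(genes, genome, half))
  exon <- merge_intervals(exon_regions(genes))
  body <- merge_intervals(data.frame(chrom = genes$chrom, start = genes$tx_start,
                                     end = genes$tx_end, stringsAsFactors = FALSE))
  intron <- .setdiff_intervals(.setdiff_intervals(.setdiff_intervals(body, exon), prom), tes)
  list(promoter = prom, TES = tes, exon = exon, intron = intron)
}

.setdiff_intervals <- function(a, b) {
  if (nrow(a) == 0) return(.empty_intervals())
  if (nrow(b) == 0) return(a)
  lev <- union(unique(a$chrom), unique(b$chrom))
  gra <- GenomicRanges::GRanges(factor(a$chrom, lev), IRanges::IRanges(a$start + 1, a$end))
  grb <- GenomicRanges::GRanges(factor(b$chrom, lev), IRanges::IRanges(b$start + 1, b$end))
  sort_intervals(.gr_df(GenomicRanges::setdiff(gra, grb)))
}
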