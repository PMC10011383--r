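# Shannon-entropy stage specificity, putative enhancers, eRNAs, ZGA genes
# and fold-change differential rules.

#' Shannon-entropy stage-specificity score
#'
#' For a feature with signal `Ei` at stage i, the relative signal is
#' `Ri = Ei / sum(E)` and the entropy `H = -sum(Ri * log2(Ri))` (with
#' `0 * log2(0) = 0`). H ranges from 0 (all signal at one stage) to
#' `log2(N)` (uniform across N stages); low H marks stage-specific
#' features.
#'
#' @param x Numeric matrix, features x stages (all values >= 0, >= 2
#'   stages), or a single numeric vector.
#' @return data.frame with `feature`, `H` (bits) and `stage` (the argmax-R
#'   stage label). All-zero features are flagged with `H = NA` and excluded
#'   from specificity calls, never scored as 0.
#' @examples
#' entropy_score(rbind(uniform = c(1, 1, 1, 1), onehot = c(5, 0, 0, 0)))
#' @export
entropy_score <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list("feature", names(x)))
  if (ncol(x) < 2) stop("need at least two stages")
  if (any(x < 0)) stop("stage values must be >= 0")
  tot <- rowSums(x)
  r <- x / ifelse(tot > 0, tot, NA)
  h <- -rowSums(ifelse(r > 0, r * log2(r), 0))
  stage_lab <- colnames(x)
  if (is.null(stage_lab)) stage_lab <- as.character(seq_len(ncol(x)))
  amax <- stage_lab[max.col(replace(r, is.na(r), 0), ties.method = "first")]
  amax[tot == 0] <- NA
  feat <- rownames(x)
  if (is.null(feat)) feat <- as.character(seq_len(nrow(x)))
  data.frame(feature = feat, H = as.numeric(h), stage = amax,
             stringsAsFactors = FALSE)
}

#' Select stage-specific features by entropy
#'
#' @param x Feature x stage matrix.
#' @param threshold Entropy cutoff in bits (default 0.5, strict `<`).
#' @return Subset of the [entropy_score()] table with `H < threshold`
#'   (all-zero features excluded), each with its assigned (argmax) stage.
#' @export
select_stage_specific <- function(x, threshold = 0.5) {
  es <- entropy_score(x)
  out <- es[!is.na(es$H) & es$H < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define putative enhancers: distal peaks with nearby DHSs
#'
#' A distal peak is a putative enhancer when a DNase I hypersensitive site
#' overlaps it or lies within `radius` bp of either edge.
#'
#' @param peaks Distal (non-promoter) peak data.frame, typically the
#'   cross-stage peak union.
#' @param dhs DHS interval data.frame.
#' @param radius Distance in bp (default 500).
#' @return The subset of `peaks` with a DHS within reach.
#' @export
define_putative_enhancers <- function(peaks, dhs, radius = 500) {
  if (nrow(peaks) == 0) return(peaks)
  widened <- data.frame(chrom = peaks$chrom,
                        start = pmax(peaks$start - radius, 0),
                        end = peaks$end + radius, stringsAsFactors = FALSE)
  out <- peaks[.overlap_bp(widened, dhs) >= 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call eRNAs: transcribed distal H3K27ac peaks without H3K4me3
#'
#' H3K27ac peaks lacking any H3K4me3 overlap and not overlapping promoters
#' or exons are tested for transcription; a peak with RNA FPKM above
#' `fpkm_min` at a stage is an eRNA at that stage.
#'
#' @param k27_peaks H3K27ac peak data.frame.
#' @param k4_peaks H3K4me3 peak data.frame (any overlap excludes a peak).
#' @param genes Gene table (provides promoter and exon exclusion zones).
#' @param genome [chrom_sizes()].
#' @param rna_fpkm Numeric matrix, one row per row of `k27_peaks`, one
#'   column per stage: RNA FPKM over the peak interval.
#' @param fpkm_min Expression cutoff (default 0.5, strict `>`).
#' @return data.frame of candidate peaks with logical `erna_<stage>` columns
#'   and an `erna_any` flag.
#' @export
call_ernas <- function(k27_peaks, k4_peaks, genes, genome, rna_fpkm,
                       fpkm_min = 0.5) {
  if (nrow(k27_peaks) != nrow(rna_fpkm))
    stop("rna_fpkm must have one row per peak")
  prom <- promoter_regions(genes, genome)
  exon <- exon_regions(genes)
  keep <- .overlap_bp(k27_peaks, k4_peaks) == 0 &
    .overlap_bp(k27_peaks, prom) == 0 &
    .overlap_bp(k27_peaks, exon) == 0
  out <- k27_peaks[keep, , drop = FALSE]
  expr <- rna_fpkm[keep, , drop = FALSE] > fpkm_min
  colnames(expr) <- paste0("erna_", colnames(rna_fpkm))
  out <- cbind(out, as.data.frame(expr))
  out$erna_any <- rowSums(expr) > 0
  rownames(out) <- NULL
  out
}

#' Define ZGA genes
#'
#' Genes upregulated at the zygotic-genome-activation stage: post-ZGA FPKM
#' above `fpkm_min` and fold change above `fold_min` relative to the
#' pre-ZGA stage (pseudocount `c` guards zero denominators).
#'
#' @param expr Feature x stage matrix of FPKM.
#' @param pre,post Stage column names (e.g. 2-cell and 8-cell).
#' @param fpkm_min Post-stage expression cutoff (default 1, strict `>`).
#' @param fold_min Fold-change cutoff (default 3, strict `>`).
#' @param pseudocount Added to both stages before the ratio (default 0.1).
#' @return Character vector of ZGA gene ids.
#' @export
define_zga_genes <- function(expr, pre, post, fpkm_min = 1, fold_min = 3,
                             pseudocount = 0.1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (!all(c(pre, post) %in% colnames(expr))) stop("pre/post stages not in matrix")
  fold <- (expr[, post] + pseudocount) / (expr[, pre] + pseudocount)
  rownames(expr)[expr[, post] > fpkm_min & fold > fold_min]
}

#' Fold-change (and FDR) differential features
#'
#' Fold-only mode classifies features by the pseudocounted ratio of the two
#' conditions. Statistical mode additionally requires a per-feature
#' count-test FDR: replicate counts are scaled to a common library size,
#' pooled per condition, and each feature is tested with a two-sided
#' binomial test of the condition-1 share against the null share implied by
#' the pooled library sizes; p-values are Benjamini-Hochberg adjusted.
#'
#' @param a,b Numeric vectors of per-feature signal (or raw counts in
#'   statistical mode) for the two conditions; in statistical mode,
#'   matrices with one column per replicate.
#' @param fold_min Fold-change cutoff (strict `>`, default 2).
#' @param fdr_max Optional FDR cutoff; requires replicate matrices with
#'   >= 2 columns each.
#' @param pseudocount Pseudocount for the fold change (default 0.1).
#' @return data.frame with `fold` (b over a), `direction`
#'   (`"up"`/`"down"`/`"ns"`) and, in statistical mode, `pvalue` and `fdr`.
#' @export
fold_change_differential <- function(a, b, fold_min = 2, fdr_max = NULL,
                                     pseudocount = 0.1) {
  stat_mode <- !is.null(fdr_max)
  if (stat_mode && (is.null(dim(a)) || is.null(dim(b)) || ncol(a) < 2 || ncol(b) < 2))
    stop("fdr_max requires replicate count matrices (>= 2 columns per condition)")
  av <- if (is.null(dim(a))) a else rowSums(a)
  bv <- if (is.null(dim(b))) b else rowSums(b)
  fold <- (bv + pseudocount) / (av + pseudocount)
  dir <- ifelse(fold > fold_min, "up", ifelse(fold < 1 / fold_min, "down", "ns"))
  out <- data.frame(fold = fold, direction = dir, stringsAsFactors = FALSE)
  if (stat_mode) {
    # scale each replicate to the mean library size, pool per condition
    libs <- c(colSums(a), colSums(b))
    target <- mean(libs)
    an <- round(rowSums(sweep(a, 2, target / colSums(a), `*`)))
    bn <- round(rowSums(sweep(b, 2, target / colSums(b), `*`)))
    n <- an + bn
    p0 <- ncol(a) / (ncol(a) + ncol(b))  # equal scaled libraries per replicate
    pv <- vapply(seq_along(n), function(i) {
      if (n[i] == 0) return(1)
      stats::binom.test(an[i], n[i], p = p0)$p.value
    }, 0)
    out$pvalue <- pv
    out$fdr <- stats::p.adjust(pv, method = "BH")
    out$direction[out$fdr >= fdr_max] <- "ns"
  }
  out
}
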