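# PMD detection and region methylation summaries from per-CpG tables.

#' Per-window methylation summary
#'
#' Tiles each chromosome with fixed windows from coordinate 0 (the terminal
#' partial window is evaluated with its actual CpG content) and reports the
#' unweighted mean methylation and the number of covered CpGs per window.
#'
#' @param cpgs CpG table (chrom, pos, meth, cov).
#' @param genome [chrom_sizes()].
#' @param window Window width in bp (default 10 kb).
#' @param min_cov Minimum per-CpG coverage for a CpG to count as covered
#'   (default 1).
#' @return data.frame chrom/start/end/mean_meth/n_cpg; windows with no
#'   covered CpG have `mean_meth = NA`.
#' @export
methylation_windows <- function(cpgs, genome, window = 10000, min_cov = 1) {
  if (window <= 0) stop("window must be positive")
  cpgs <- cpgs[cpgs$cov >= min_cov, , drop = FALSE]
  out <- lapply(names(genome), function(ch) {
    n <- ceiling(genome[ch] / window)
    df <- data.frame(chrom = ch, start = (seq_len(n) - 1) * window,
                     end = pmin(seq_len(n) * window, genome[ch]),
                     mean_meth = NA_real_, n_cpg = 0L, stringsAsFactors = FALSE)
    sel <- cpgs$chrom == ch
    if (any(sel)) {
      idx <- floor(cpgs$pos[sel] / window) + 1
      s <- rowsum(cpgs$meth[sel], idx)
      k <- rowsum(rep(1L, sum(sel)), idx)
      i <- as.integer(rownames(s))
      df$mean_meth[i] <- s[, 1] / k[, 1]
      df$n_cpg[i] <- as.integer(k[, 1])
    }
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call partially methylated domains (PMDs)
#'
#' Windows with mean methylation below `max_meth` and more than `min_cpg`
#' covered CpGs are selected and adjacent selected windows merged (gap 0)
#' into PMDs.
#'
#' @inheritParams methylation_windows
#' @param max_meth Methylation threshold (default 0.5, strict `<`).
#' @param min_cpg Covered-CpG threshold (default 20, strict `>`).
#' @return Interval data.frame of PMDs.
#' @export
call_pmds <- function(cpgs, genome, window = 10000, max_meth = 0.5,
                      min_cpg = 20, min_cov = 1) {
  w <- methylation_windows(cpgs, genome, window, min_cov)
  sel <- !is.na(w$mean_meth) & w$mean_meth < max_meth & w$n_cpg > min_cpg
  merge_intervals(w[sel, c("chrom", "start", "end"), drop = FALSE], gap = 0)
}

#' CpG density of a region
#'
#' @param region One-row interval data.frame (or list with chrom/start/end).
#' @param cpgs CpG table.
#' @return Average number of CpG sites per 100 bp.
#' @export
cpg_density <- function(region, cpgs) {
  len <- region$end - region$start
  if (length(len) != 1 || len <= 0) stop("region must be a single non-empty interval")
  n <- sum(cpgs$chrom == region$chrom & cpgs$pos >= region$start & cpgs$pos < region$end)
  n * 100 / len
}

#' Mean methylation of a region
#'
#' Unweighted mean of per-CpG methylation levels over the CpGs in the
#' region; `NA` when the region contains no CpG.
#'
#' @inheritParams cpg_density
#' @return Fraction in \[0, 1\], or `NA` for a CpG-free region.
#' @export
region_methylation <- function(region, cpgs) {
  sel <- cpgs$chrom == region$chrom & cpgs$pos >= region$start & cpgs$pos < region$end
  if (!any(sel)) return(NA_real_)
  mean(cpgs$meth[sel])
}
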