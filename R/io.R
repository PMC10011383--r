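# Readers and writers for the plain-text dialects the pipeline exchanges.
# All genomic coordinates are 0-based half-open (BED convention) on disk and
# in memory; refGene-style gene tables already use that convention.

.io_kinds <- c("bed", "bedgraph", "genes", "repeats", "cpg", "matrix",
               "chromsizes", "peaks")

.read_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines[nzchar(lines)]
}

.split_fields <- function(lines, n_min, kind) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < n_min)
  if (length(bad))
    stop(sprintf("malformed %s line %d: expected >= %d tab-separated fields",
                 kind, bad[1], n_min))
  fields
}

.num_field <- function(fields, i, kind, lines) {
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  bad <- which(is.na(v))
  if (length(bad))
    stop(sprintf("malformed %s line %d: field %d is not numeric", kind, bad[1], i))
  v
}

#' Read a standard-format table
#'
#' One entry point for every text dialect the pipeline consumes. Coordinates
#' are kept 0-based half-open.
#'
#' @param path Path to the file.
#' @param kind One of `"bed"` (chrom/start/end, optional name/score/strand),
#'   `"bedgraph"` (chrom/start/end/value), `"genes"` (headered TSV: gene_id,
#'   chrom, strand, tx_start, tx_end, exon_starts, exon_ends with
#'   comma-separated exon lists), `"repeats"` (headered TSV: chrom, start,
#'   end, family, class), `"cpg"` (headered TSV: chrom, pos, meth, cov),
#'   `"matrix"` (headered TSV: feature id column then one numeric column per
#'   stage), `"chromsizes"` (name TAB length) or `"peaks"` (headered TSV as
#'   written by [write_table()]).
#' @param genome Optional [chrom_sizes()]; when given, intervals are checked
#'   against chromosome bounds.
#' @return A validated collection of the corresponding type: interval
#'   data.frame, gene table, CpG table, numeric matrix, or `chrom_sizes`.
#' @export
read_table <- function(path, kind = c("bed", "bedgraph", "genes", "repeats",
                                      "cpg", "matrix", "chromsizes", "peaks"),
                       genome = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- .read_tsv_lines(path)
  out <- switch(kind,
    bed = {
      if (!length(lines)) return(.empty_intervals())
      f <- .split_fields(lines, 3, kind)
      df <- data.frame(chrom = vapply(f, `[[`, "", 1),
                       start = .num_field(f, 2, kind, lines),
                       end = .num_field(f, 3, kind, lines),
                       stringsAsFactors = FALSE)
      if (all(vapply(f, length, 0L) >= 6)) {
        df$name <- vapply(f, `[[`, "", 4)
        df$score <- .num_field(f, 5, kind, lines)
        df$strand <- vapply(f, `[[`, "", 6)
      }
      bad <- which(df$start >= df$end | df$start < 0)
      if (length(bad)) stop(sprintf("malformed bed line %d: start >= end", bad[1]))
      sort_intervals(df)
    },
    bedgraph = {
      if (!length(lines)) return(.empty_intervals("value")[, c("chrom", "start", "end", "value")])
      f <- .split_fields(lines, 4, kind)
      df <- data.frame(chrom = vapply(f, `[[`, "", 1),
                       start = .num_field(f, 2, kind, lines),
                       end = .num_field(f, 3, kind, lines),
                       value = .num_field(f, 4, kind, lines),
                       stringsAsFactors = FALSE)
      bad <- which(df$start >= df$end | df$start < 0)
      if (length(bad)) stop(sprintf("malformed bedgraph line %d: start >= end", bad[1]))
      sort_intervals(df)
    },
    chromsizes = {
      f <- .split_fields(lines, 2, kind)
      chrom_sizes(vapply(f, `[[`, "", 1), .num_field(f, 2, kind, lines))
    },
    genes = .read_genes(lines),
    repeats = {
      f <- .split_fields(lines[-1], 5, kind)
      if (!length(f)) return(.empty_intervals(c("family", "class")))
      df <- data.frame(chrom = vapply(f, `[[`, "", 1),
                       start = .num_field(f, 2, kind, lines),
                       end = .num_field(f, 3, kind, lines),
                       family = vapply(f, `[[`, "", 4),
                       class = vapply(f, `[[`, "", 5),
                       stringsAsFactors = FALSE)
      if (any(!nzchar(df$family))) stop("repeats: empty family label")
      sort_intervals(df)
    },
    cpg = {
      f <- .split_fields(lines[-1], 4, kind)
      df <- data.frame(chrom = vapply(f, `[[`, "", 1),
                       pos = .num_field(f, 2, kind, lines),
                       meth = .num_field(f, 3, kind, lines),
                       cov = .num_field(f, 4, kind, lines),
                       stringsAsFactors = FALSE)
      if (any(df$meth < 0 | df$meth > 1))
        stop("cpg: methylation level outside [0, 1]")
      if (any(df$cov < 0)) stop("cpg: negative coverage")
      df[order(df$chrom, df$pos), , drop = FALSE]
    },
    matrix = {
      m <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
      rn <- m[[1]]
      m <- as.matrix(m[, -1, drop = FALSE])
      if (!is.numeric(m)) stop("matrix: non-numeric stage columns")
      rownames(m) <- rn
      m
    },
    peaks = {
      df <- utils::read.delim(path, stringsAsFactors = FALSE)
      need <- c("chrom", "start", "end")
      if (!all(need %in% names(df))) stop("peaks: missing chrom/start/end columns")
      sort_intervals(df)
    }
  )
  if (!is.null(genome) && is.data.frame(out) && all(c("chrom", "start", "end") %in% names(out)))
    .check_intervals(out, genome, what = basename(path))
  out
}

.read_genes <- function(lines) {
  f <- .split_fields(lines[-1], 7, "genes")
  if (!length(f))
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tx_start = numeric(),
                      tx_end = numeric(), stringsAsFactors = FALSE))
  parse_list <- function(s) as.numeric(strsplit(sub(",$", "", s), ",", fixed = TRUE)[[1]])
  df <- data.frame(gene_id = vapply(f, `[[`, "", 1),
                   chrom = vapply(f, `[[`, "", 2),
                   strand = vapply(f, `[[`, "", 3),
                   tx_start = .num_field(f, 4, "genes", lines),
                   tx_end = .num_field(f, 5, "genes", lines),
                   stringsAsFactors = FALSE)
  df$exon_starts <- I(lapply(f, function(x) parse_list(x[[6]])))
  df$exon_ends <- I(lapply(f, function(x) parse_list(x[[7]])))
  if (any(!df$strand %in% c("+", "-")))
    stop("genes: strand must be + or -")
  if (any(df$tx_start >= df$tx_end)) stop("genes: tx_start >= tx_end")
  ok <- mapply(function(s, e, a, b) length(s) == length(e) && all(s < e) &&
                 all(s >= a) && all(e <= b),
               df$exon_starts, df$exon_ends, df$tx_start, df$tx_end)
  if (any(!ok)) stop("genes: exons outside transcript bounds on line ",
                     which(!ok)[1] + 1)
  df[order(df$chrom, df$tx_start), , drop = FALSE]
}

#' Write a collection to its standard text dialect
#'
#' Inverse of [read_table()]: `read_table(write_table(x, p, k), k)` restores
#' `x` for every dialect.
#'
#' @param x The collection (interval data.frame, gene table, CpG table,
#'   matrix, `chrom_sizes`, or [binned_track()] for `"bedgraph"`).
#' @param path Output path.
#' @param kind Dialect; see [read_table()]. `"bedgraph"` accepts a
#'   `binned_track` and writes one line per non-zero bin.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, kind = c("bed", "bedgraph", "genes", "repeats",
                                          "cpg", "matrix", "chromsizes", "peaks")) {
  kind <- match.arg(kind)
  con <- file(path, "w")
  on.exit(close(con))
  fmt_num <- function(v) formatC(v, format = "g", digits = 15)
  switch(kind,
    bed = {
      .check_intervals(x)
      x <- sort_intervals(x)
      cols <- if (all(c("name", "score", "strand") %in% names(x)))
        cbind(x$chrom, fmt_num(x$start), fmt_num(x$end), x$name, fmt_num(x$score), x$strand)
      else cbind(x$chrom, fmt_num(x$start), fmt_num(x$end))
      if (nrow(x)) writeLines(apply(cols, 1, paste, collapse = "\t"), con)
    },
    bedgraph = {
      if (inherits(x, "binned_track")) x <- track_to_bedgraph(x)
      if (nrow(x)) writeLines(paste(x$chrom, fmt_num(x$start), fmt_num(x$end),
                                    fmt_num(x$value), sep = "\t"), con)
    },
    chromsizes = writeLines(paste(names(x), fmt_num(as.numeric(x)), sep = "\t"), con),
    repeats = {
      writeLines("chrom\tstart\tend\tfamily\tclass", con)
      if (nrow(x)) writeLines(paste(x$chrom, fmt_num(x$start), fmt_num(x$end),
                                    x$family, x$class, sep = "\t"), con)
    },
    cpg = {
      writeLines("chrom\tpos\tmeth\tcov", con)
      if (nrow(x)) writeLines(paste(x$chrom, fmt_num(x$pos), fmt_num(x$meth),
                                    fmt_num(x$cov), sep = "\t"), con)
    },
    genes = {
      writeLines("gene_id\tchrom\tstrand\ttx_start\ttx_end\texon_starts\texon_ends", con)
      if (nrow(x)) {
        es <- vapply(x$exon_starts, function(v) paste0(paste(fmt_num(v), collapse = ","), ","), "")
        ee <- vapply(x$exon_ends, function(v) paste0(paste(fmt_num(v), collapse = ","), ","), "")
        writeLines(paste(x$gene_id, x$chrom, x$strand, fmt_num(x$tx_start),
                         fmt_num(x$tx_end), es, ee, sep = "\t"), con)
      }
    },
    matrix = {
      writeLines(paste(c("feature", colnames(x)), collapse = "\t"), con)
      if (nrow(x)) writeLines(paste(rownames(x),
                                    apply(x, 1, function(r) paste(fmt_num(r), collapse = "\t")),
                                    sep = "\t"), con)
    },
    peaks = {
      cols <- names(x)
      writeLines(paste(cols, collapse = "\t"), con)
      if (nrow(x)) {
        body <- vapply(seq_len(nrow(x)), function(i)
          paste(vapply(cols, function(cn) {
            v <- x[[cn]][i]
            if (is.numeric(v)) fmt_num(v) else as.character(v)
          }, ""), collapse = "\t"), "")
        writeLines(body, con)
      }
    }
  )
  invisible(path)
}
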