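#' Read gene intervals from GFF3
#'
#' Imports gene features (only) and returns a plain interval table with
#' AGAP-style gene identifiers.
#'
#' @param path GFF3 file.
#' @return `data.frame`: `gene_id`, `chrom`, `start`, `end` (1-based,
#'   inclusive, as in GFF), `description`.
#' @export
read_gene_intervals <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[tolower(as.character(g$type)) == "gene"]
  id <- if (!is.null(g$ID)) g$ID else as.character(seq_along(g))
  desc <- if (!is.null(g$description)) g$description
  else if (!is.null(g$Name)) g$Name else rep(NA_character_, length(g))
  data.frame(gene_id = id, chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g), end = GenomicRanges::end(g),
             description = desc, stringsAsFactors = FALSE)
}

#' Genes overlapping flagged genomic windows
#'
#' Intersects gene intervals (1-based inclusive) with the half-open bp
#' spans of flagged windows; a gene abutting a window's `end` coordinate
#' does not overlap. Also reports the top-`k` windows per chromosome by the
#' statistic, for summary tables.
#'
#' @param windows `data.frame` with `chrom`, `start`, `end` (half-open) and
#'   a statistic column (`fst` or `h12_mean`).
#' @param genes Gene table from [read_gene_intervals()].
#' @param statistic Name of the statistic column (default: `"fst"` if
#'   present, else `"h12_mean"`).
#' @param top_k Windows per chromosome in the `top_windows` summary
#'   (default 5).
#' @return A list of class `gene_report`: `overlaps` (gene x window rows)
#'   and `top_windows`.
#' @export
genes_in_windows <- function(windows, genes, statistic = NULL, top_k = 5) {
  statistic <- statistic %||%
    (if ("fst" %in% names(windows)) "fst" else "h12_mean")
  unmatched <- setdiff(unique(windows$chrom), unique(genes$chrom))
  if (length(unmatched) && nrow(windows))
    stop("window chromosome(s) absent from gene table: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  wr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start, windows$end - 1L))
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(gr, wr)
  overlaps <- if (length(ov)) {
    gi <- S4Vectors::queryHits(ov); wi <- S4Vectors::subjectHits(ov)
    data.frame(gene_id = genes$gene_id[gi],
               description = genes$description[gi],
               chrom = windows$chrom[wi], window_start = windows$start[wi],
               window_end = windows$end[wi],
               statistic = windows[[statistic]][wi],
               stringsAsFactors = FALSE)
  } else NULL
  top <- lapply(split(windows, windows$chrom), function(w) {
    w <- w[order(-w[[statistic]]), ]
    utils::head(w, top_k)
  })
  top <- do.call(rbind, top)
  rownames(top) <- NULL
  structure(list(overlaps = overlaps, top_windows = top,
                 statistic = statistic), class = "gene_report")
}

#' @export
print.gene_report <- function(x, ...) {
  n <- if (is.null(x$overlaps)) 0L else length(unique(x$overlaps$gene_id))
  cat(sprintf("gene report: %d gene(s) overlap flagged windows (%s)\n",
              n, x$statistic))
  if (!is.null(x$overlaps)) print.data.frame(x$overlaps, row.names = FALSE)
  invisible(x)
}
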