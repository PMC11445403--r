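#' Simulate reads around CNV breakpoints
#'
#' Emits single-end alignments overlapping the two breakpoints of a planted
#' CNV allele. A Bernoulli(`clip_fraction`) subset of the reads at each
#' breakpoint carries a CIGAR soft clip whose clipped boundary coordinate
#' equals the breakpoint — clip on the left of the alignment at the start
#' breakpoint, on the right at the end breakpoint — and the remainder are
#' fully matched reads covering the breakpoint.
#'
#' @param cnv A [planted_feature()] of kind `"cnv"` (uses `chrom`, `start`,
#'   `end`).
#' @param depth Reads overlapping each breakpoint (> 0).
#' @param clip_fraction Probability a read is soft-clipped at the breakpoint.
#' @param mapq Mapping quality: scalar, or a function `n -> integer vector`.
#' @param read_len Read length in bp (> 0).
#' @param seed Integer seed.
#' @param sample Sample id used in read names.
#' @return A `data.frame` of SAM alignment fields, one row per read, for
#'   [write_sam()].
#' @export
generate_breakpoint_reads <- function(cnv, depth, clip_fraction, mapq = 60,
                                      read_len = 100, seed = 1,
                                      sample = "sample") {
  stopifnot(inherits(cnv, "planted_feature"), cnv$kind == "cnv")
  if (read_len <= 0) stop("read_len must be positive", call. = FALSE)
  stopifnot(depth > 0, clip_fraction >= 0, clip_fraction <= 1)
  set.seed(seed)
  draw_mapq <- if (is.function(mapq)) mapq else function(n) rep(mapq, n)
  one_bp <- function(bp, side) {
    clipped <- stats::runif(depth) < clip_fraction
    pos <- integer(depth); cigar <- character(depth)
    clip_len <- sample(seq(10L, read_len - 10L), depth, replace = TRUE)
    for (i in seq_len(depth)) {
      if (clipped[i]) {
        m <- read_len - clip_len[i]
        if (side == "left") {        # boundary = POS = breakpoint
          pos[i] <- bp
          cigar[i] <- sprintf("%dS%dM", clip_len[i], m)
        } else {                     # boundary = POS + ref width = breakpoint
          pos[i] <- bp - m
          cigar[i] <- sprintf("%dM%dS", m, clip_len[i])
        }
      } else {
        pos[i] <- sample(seq(max(1L, bp - read_len + 1L), bp), 1L)
        cigar[i] <- sprintf("%dM", read_len)
      }
    }
    data.frame(pos = pos, cigar = cigar, clipped = clipped,
               stringsAsFactors = FALSE)
  }
  reads <- rbind(cbind(one_bp(cnv$start, "left"), breakpoint = "start"),
                 cbind(one_bp(cnv$end, "right"), breakpoint = "end"))
  n <- nrow(reads)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(bases, read_len, replace = TRUE), collapse = ""),
    character(1))
  out <- data.frame(
    qname = sprintf("%s_%s_%04d", sample, cnv$name, seq_len(n)),
    flag = 0L, rname = cnv$chrom, pos = pmax(1L, reads$pos),
    mapq = as.integer(draw_mapq(n)), cigar = reads$cigar,
    rnext = "*", pnext = 0L, tlen = 0L, seq = seqs,
    qual = strrep("I", read_len), stringsAsFactors = FALSE)
  out[order(out$pos), , drop = FALSE]
}

#' Write alignments as a SAM v1 file
#'
#' Coordinate-sorted, with `@HD` and `@SQ` header lines. The output passes
#' samtools/Rsamtools validation (it is what [read_alignments()] converts
#' to BAM).
#'
#' @param reads A `data.frame` with the 11 mandatory SAM columns as produced
#'   by [generate_breakpoint_reads()] (rows from several samples/CNVs may be
#'   concatenated).
#' @param path Output path.
#' @param chrom_lengths Named vector of reference lengths for `@SQ` lines;
#'   defaults to generous bounds past the last alignment.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, chrom_lengths = NULL) {
  need <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "rnext",
            "pnext", "tlen", "seq", "qual")
  stopifnot(all(need %in% names(reads)))
  reads <- reads[order(match(reads$rname, unique(reads$rname)), reads$pos), ,
                 drop = FALSE]
  contigs <- unique(reads$rname)
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(contigs, function(ch)
      max(reads$pos[reads$rname == ch]) + 10000, numeric(1))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs,
                   as.integer(chrom_lengths[contigs])))
  body <- do.call(paste, c(unname(reads[need]), sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' SAM text is converted to BAM with Rsamtools (which validates the format)
#' and scanned for the fields the soft-clip screen needs.
#'
#' @param path A `.sam` or `.bam` file.
#' @return A `data.frame` with columns `qname`, `rname`, `pos`, `mapq`,
#'   `cigar`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(
    path, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "mapq", "cigar")))[[1]]
  data.frame(qname = b$qname, rname = as.character(b$rname), pos = b$pos,
             mapq = b$mapq, cigar = b$cigar, stringsAsFactors = FALSE)
}
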