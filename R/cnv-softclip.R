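cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

right_clip <- function(cigar) grepl("[0-9]+S$", cigar)
left_clip <- function(cigar) grepl("^[0-9]+S", cigar)

#' Proportion of reads soft-clipped at a CNV breakpoint
#'
#' The denominator is every mapped read with mapping quality at least
#' `mapq_min` whose alignment covers or abuts the breakpoint; the numerator
#' is the subset whose CIGAR soft-clip boundary lies within `tolerance_bp`
#' of the breakpoint on the expected side. The clip boundary is the first
#' aligned reference base (left clips) or one past the last aligned base
#' (right clips). Only soft clips (`S`) count; hard clips (`H`) are read
#' trimming, not breakpoint evidence.
#'
#' @param reads Alignment `data.frame` from [read_alignments()] (`rname`,
#'   `pos`, `mapq`, `cigar`).
#' @param chrom Chromosome of the breakpoint.
#' @param breakpoint 1-based breakpoint coordinate.
#' @param side Expected clip side: `"left"` (CNV start) or `"right"` (CNV
#'   end).
#' @param mapq_min Mapping-quality cutoff (inclusive, default 10).
#' @param tolerance_bp Allowed distance between clip boundary and
#'   breakpoint (default 0: exact).
#' @return A list of class `softclip_profile`: `n_reads`, `n_clipped`,
#'   `proportion` (`NA` with `no_coverage = TRUE` when no read qualifies).
#' @export
softclip_proportion <- function(reads, chrom, breakpoint,
                                side = c("left", "right"), mapq_min = 10,
                                tolerance_bp = 0) {
  side <- match.arg(side)
  sel <- reads$rname == chrom & !is.na(reads$mapq) & reads$mapq >= mapq_min
  r <- reads[sel, , drop = FALSE]
  if (nrow(r)) {
    width <- cigar_ref_width(r$cigar)
    aln_end <- r$pos + width - 1L
    covers <- r$pos - 1L <= breakpoint & breakpoint <= aln_end + 1L
    r <- r[covers, , drop = FALSE]
  }
  if (nrow(r) == 0)
    return(structure(list(chrom = chrom, breakpoint = breakpoint,
                          side = side, n_reads = 0L, n_clipped = 0L,
                          proportion = NA_real_, no_coverage = TRUE),
                     class = "softclip_profile"))
  width <- cigar_ref_width(r$cigar)
  boundary <- if (side == "left") r$pos else r$pos + width
  clipped <- if (side == "left") left_clip(r$cigar) else right_clip(r$cigar)
  hit <- clipped & abs(boundary - breakpoint) <= tolerance_bp
  structure(list(chrom = chrom, breakpoint = breakpoint, side = side,
                 n_reads = nrow(r), n_clipped = sum(hit),
                 proportion = sum(hit) / nrow(r), no_coverage = FALSE),
            class = "softclip_profile")
}

#' @export
print.softclip_profile <- function(x, ...) {
  if (x$no_coverage) {
    cat(sprintf("soft-clip profile %s:%d (%s): no coverage\n",
                x$chrom, x$breakpoint, x$side))
  } else {
    cat(sprintf(
      "soft-clip profile %s:%d (%s): %d/%d reads clipped (%.1f%%)\n",
      x$chrom, x$breakpoint, x$side, x$n_clipped, x$n_reads,
      100 * x$proportion))
  }
  invisible(x)
}

#' Call a CNV allele from its two breakpoint profiles
#'
#' Present when the soft-clip proportion reaches `threshold` at the start
#' breakpoint, the end breakpoint, or both (inclusive comparison); the
#' evidence side is recorded. When neither breakpoint has coverage the
#' call is `no_coverage`.
#'
#' @param profile_start,profile_end [softclip_proportion()] results for the
#'   CNV's start (left-clip) and end (right-clip) breakpoints.
#' @param threshold Proportion cutoff (default 0.195, i.e. 19.5%).
#' @param name CNV allele name for the report.
#' @return A list of class `cnv_call`: `name`, `call`
#'   (`present`/`absent`/`no_coverage`), `evidence_side`
#'   (`start`/`end`/`both`/`none`), the two proportions.
#' @export
call_cnv <- function(profile_start, profile_end, threshold = 0.195,
                     name = NA_character_) {
  ps <- profile_start$proportion; pe <- profile_end$proportion
  if (profile_start$no_coverage && profile_end$no_coverage)
    return(structure(list(name = name, call = "no_coverage",
                          evidence_side = "none", prop_start = ps,
                          prop_end = pe, threshold = threshold),
                     class = "cnv_call"))
  hit_s <- !is.na(ps) && ps >= threshold
  hit_e <- !is.na(pe) && pe >= threshold
  side <- if (hit_s && hit_e) "both" else if (hit_s) "start"
  else if (hit_e) "end" else "none"
  structure(list(name = name,
                 call = if (hit_s || hit_e) "present" else "absent",
                 evidence_side = side, prop_start = ps, prop_end = pe,
                 threshold = threshold),
            class = "cnv_call")
}

#' @export
print.cnv_call <- function(x, ...) {
  cat(sprintf("CNV %s: %s (evidence: %s; start %.3f, end %.3f, cutoff %.3f)\n",
              x$name %||% "?", x$call, x$evidence_side,
              x$prop_start %||% NA, x$prop_end %||% NA, x$threshold))
  invisible(x)
}

#' Calibrate the soft-clip proportion threshold from a labelled set
#'
#' Given soft-clip proportions for a verification set of samples with known
#' CNV status, returns the midpoint between the highest negative and lowest
#' positive proportion when the classes separate; otherwise the threshold
#' maximising Youden's J (sensitivity + specificity - 1) over an exhaustive
#' sweep of candidate cutpoints.
#'
#' @param proportions Numeric vector of soft-clip proportions.
#' @param status Logical (or 0/1) vector: `TRUE` for known carriers.
#' @return A list of class `threshold_calibration`: `threshold`,
#'   `sensitivity`, `specificity`, `separated`.
#' @export
calibrate_threshold <- function(proportions, status) {
  status <- as.logical(status)
  stopifnot(length(proportions) == length(status), !anyNA(proportions))
  if (all(status) || !any(status))
    stop("calibration needs both carrier and non-carrier examples",
         call. = FALSE)
  pos <- proportions[status]; neg <- proportions[!status]
  perf <- function(thr) c(sens = mean(pos >= thr), spec = mean(neg < thr))
  if (max(neg) < min(pos)) {
    thr <- (max(neg) + min(pos)) / 2
    p <- perf(thr)
    return(structure(list(threshold = thr, sensitivity = p[["sens"]],
                          specificity = p[["spec"]], separated = TRUE),
                     class = "threshold_calibration"))
  }
  cand <- sort(unique(proportions))
  scores <- vapply(cand, function(thr) sum(perf(thr)) - 1, numeric(1))
  thr <- cand[which.max(scores)]
  p <- perf(thr)
  structure(list(threshold = thr, sensitivity = p[["sens"]],
                 specificity = p[["spec"]], separated = FALSE),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "calibrated clip threshold %.4g (%s; sensitivity %.2f, specificity %.2f)\n",
    x$threshold, if (x$separated) "classes separated, midpoint rule"
    else "overlapping classes, Youden-optimal", x$sensitivity,
    x$specificity))
  invisible(x)
}

#' Read a CNV breakpoint table from TSV
#'
#' Columns: `name` (CNV allele, e.g. Cyp6aap_Dup7), `chrom`, `start`,
#' `end` (the two breakpoint coordinates, 1-based, start < end).
#'
#' @param path TSV file.
#' @return A `data.frame`.
#' @export
read_breakpoint_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  miss <- setdiff(c("name", "chrom", "start", "end"), names(d))
  if (length(miss)) stop("breakpoint TSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(d$start >= d$end))
    stop("breakpoints must satisfy start < end", call. = FALSE)
  d
}

#' Screen one sample's alignments for a table of CNV alleles
#'
#' @param reads Alignments from [read_alignments()].
#' @param breakpoints Breakpoint table ([read_breakpoint_tsv()]).
#' @param threshold Proportion cutoff (default 0.195).
#' @param mapq_min,tolerance_bp Passed to [softclip_proportion()].
#' @return `data.frame`, one row per CNV allele: call, evidence side and
#'   the two breakpoint proportions.
#' @export
screen_cnv <- function(reads, breakpoints, threshold = 0.195,
                       mapq_min = 10, tolerance_bp = 0) {
  unmatched <- setdiff(unique(breakpoints$chrom), unique(reads$rname))
  if (length(unmatched))
    stop("breakpoint chromosome(s) absent from alignments: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(breakpoints)), function(k) {
    b <- breakpoints[k, ]
    ps <- softclip_proportion(reads, b$chrom, b$start, "left",
                              mapq_min, tolerance_bp)
    pe <- softclip_proportion(reads, b$chrom, b$end, "right",
                              mapq_min, tolerance_bp)
    cc <- call_cnv(ps, pe, threshold, name = b$name)
    data.frame(name = b$name, chrom = b$chrom, start = b$start,
               end = b$end, call = cc$call,
               evidence_side = cc$evidence_side,
               prop_start = cc$prop_start, prop_end = cc$prop_end,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
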