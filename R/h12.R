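garud_from_freqs <- function(p) {
  p <- sort(p, decreasing = TRUE)
  p2 <- p * p
  h1 <- sum(p2)
  p1 <- p[1]; pa <- if (length(p) >= 2) p[2] else 0
  pb <- if (length(p) >= 3) p[3] else 0
  h12 <- (p1 + pa)^2 + if (length(p) > 2) sum(p2[-(1:2)]) else 0
  h123 <- (p1 + pa + pb)^2 + if (length(p) > 3) sum(p2[-(1:3)]) else 0
  list(H1 = h1, H12 = h12, H123 = h123, H2_H1 = (h1 - p1^2) / h1)
}

hap_keys <- function(haps) {
  # collapse haplotype rows to strings for frequency counting
  do.call(paste0, as.data.frame(haps))
}

#' Garud's haplotype-homozygosity statistics
#'
#' With sorted haplotype-class frequencies `p1 >= p2 >= ...`:
#' `H1 = sum(pi^2)`; `H12 = (p1 + p2)^2 + sum_{i>=3} pi^2` (pools the top
#' two classes, sensitive to soft sweeps); `H123` pools the top three;
#' `H2/H1 = (H1 - p1^2)/H1` distinguishes hard from soft sweeps.
#'
#' @param haps Haplotypes x sites 0/1 matrix (one window). Haplotypes
#'   containing missing alleles are dropped before counting.
#' @return A list with `H1`, `H12`, `H123`, `H2_H1`, `n_haplotypes`,
#'   `n_classes`.
#' @export
garud_h <- function(haps) {
  stopifnot(is.matrix(haps))
  keep <- !apply(is.na(haps), 1, any)
  haps <- haps[keep, , drop = FALSE]
  if (nrow(haps) < 2L)
    stop("need at least two complete haplotypes", call. = FALSE)
  counts <- table(hap_keys(haps))
  p <- as.numeric(counts) / nrow(haps)
  out <- garud_from_freqs(p)
  out$n_haplotypes <- nrow(haps)
  out$n_classes <- length(p)
  out
}

snp_windows <- function(chrom, window_snps) {
  # consecutive-SNP windows per chromosome; terminal partial windows are
  # dropped, not padded
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    nw <- length(idx) %/% window_snps
    if (nw == 0) next
    for (w in seq_len(nw))
      out[[length(out) + 1L]] <-
        list(chrom = ch, sites = idx[((w - 1L) * window_snps + 1L):
                                       (w * window_snps)])
  }
  out
}

#' Garud H12 genome scan with haplotype subsampling
#'
#' Scans non-overlapping windows of `window_snps` consecutive SNPs,
#' separately per phenotype group. Because the groups differ in size, each
#' window's H12 is the mean of `n_iter` evaluations on random subsamples of
#' `subsample_size` haplotypes drawn without replacement, which makes the
#' two groups' statistics comparable. Maximal runs of windows whose mean
#' H12 exceeds `sweep_threshold` are reported as candidate sweep regions.
#'
#' @param gm A [genotype_matrix()] (phased, as the statistic requires).
#' @param panel A [phenotyped_panel()].
#' @param groups Phenotype groups to scan (default resistant and
#'   susceptible, separately).
#' @param window_snps SNPs per window (default 1000).
#' @param n_iter Subsample iterations per window (default 200).
#' @param subsample_size Haplotypes per subsample; default is the smallest
#'   scanned group's haplotype count (equalising group sizes).
#' @param sweep_threshold Mean H12 above which a window is called part of a
#'   sweep (default 0.2).
#' @param seed Integer seed.
#' @return A `data.frame` of class `h12_scan`: `group`, `chrom`, `start`,
#'   `end`, `mid` (bp span of the window's SNPs), `n_snps`, `h12_mean`,
#'   `h1_mean`, `sweep`.
#' @export
h12_scan <- function(gm, panel, groups = c("resistant", "susceptible"),
                     window_snps = 1000, n_iter = 200,
                     subsample_size = NULL, sweep_threshold = 0.2,
                     seed = 1) {
  group_samples <- lapply(stats::setNames(nm = groups), panel_samples,
                          panel = panel)
  hap_counts <- vapply(group_samples, function(s) 2L * length(s), integer(1))
  if (is.null(subsample_size)) subsample_size <- min(hap_counts)
  if (any(subsample_size > hap_counts))
    stop(sprintf("subsample_size %d exceeds haplotype count of group(s): %s",
                 subsample_size,
                 paste(names(hap_counts)[subsample_size > hap_counts],
                       collapse = ", ")), call. = FALSE)
  windows <- snp_windows(gm$chrom, window_snps)
  if (length(windows) == 0)
    stop("no complete window of ", window_snps, " SNPs", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (g in groups) {
    haps <- haplotypes(gm, group_samples[[g]])
    for (w in windows) {
      keys <- hap_keys(haps[, w$sites, drop = FALSE])
      keys <- keys[!grepl("NA", keys, fixed = TRUE)]
      if (length(keys) < subsample_size)
        stop(sprintf(
          "window %s:%d has only %d complete haplotypes (< subsample %d)",
          w$chrom, gm$pos[w$sites[1]], length(keys), subsample_size),
          call. = FALSE)
      h12s <- h1s <- numeric(n_iter)
      for (k in seq_len(n_iter)) {
        sub <- sample(keys, subsample_size)
        gh <- garud_from_freqs(as.numeric(table(sub)) / subsample_size)
        h12s[k] <- gh$H12; h1s[k] <- gh$H1
      }
      pos <- gm$pos[w$sites]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, chrom = w$chrom, start = min(pos), end = max(pos) + 1L,
        mid = (min(pos) + max(pos)) / 2, n_snps = length(w$sites),
        h12_mean = mean(h12s), h1_mean = mean(h1s),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$sweep <- out$h12_mean > sweep_threshold
  class(out) <- c("h12_scan", "data.frame")
  attr(out, "sweep_threshold") <- sweep_threshold
  out
}

#' @export
print.h12_scan <- function(x, ...) {
  cat(sprintf(
    "H12 scan: %d window x group entries; %d above threshold %.2f\n",
    nrow(x), sum(x$sweep), attr(x, "sweep_threshold") %||% 0.2))
  cols <- intersect(c("group", "chrom", "start", "end", "h12_mean"),
                    names(x))
  if (any(x$sweep))
    print.data.frame(x[x$sweep, cols], row.names = FALSE)
  invisible(x)
}

#' Contiguous sweep regions from an H12 scan
#'
#' @param scan An `h12_scan` result.
#' @return `data.frame` of maximal runs of above-threshold windows:
#'   `group`, `chrom`, `start`, `end`, `n_windows`, `max_h12`.
#' @export
sweep_regions <- function(scan) {
  rows <- list()
  for (g in unique(scan$group)) for (ch in unique(scan$chrom)) {
    s <- scan[scan$group == g & scan$chrom == ch, ]
    s <- s[order(s$start), ]
    r <- rle(s$sweep)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      blk <- s[starts[i]:ends[i], ]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, chrom = ch, start = min(blk$start), end = max(blk$end),
        n_windows = nrow(blk), max_h12 = max(blk$h12_mean),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               n_windows = integer(0), max_h12 = numeric(0))
}
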