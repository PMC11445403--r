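#' Plot a windowed genome-scan track
#'
#' Per-chromosome track of window statistic against window midpoint, the
#' standard presentation for FST and H12 scans. For H12 scans the two
#' phenotype groups are overlaid in different colours.
#'
#' @param x An `fst_scan`/`fst_windows` or `h12_scan` data.frame.
#' @param chrom Chromosome to plot (default: first present).
#' @param threshold Optional horizontal reference line (e.g. the 0.2 sweep
#'   threshold).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_windowed_stat <- function(x, chrom = NULL, threshold = NULL, ...) {
  stat <- if ("fst" %in% names(x)) "fst" else "h12_mean"
  chrom <- chrom %||% x$chrom[1]
  d <- x[x$chrom == chrom, ]
  mid <- if ("mid" %in% names(d)) d$mid else (d$start + d$end - 1) / 2
  if (stat == "h12_mean" && "group" %in% names(d)) {
    groups <- unique(d$group)
    cols <- stats::setNames(c("#3366cc", "#cc3377")[seq_along(groups)],
                            groups)
    graphics::plot(mid[d$group == groups[1]],
                   d$h12_mean[d$group == groups[1]], type = "l",
                   col = cols[1], xlab = paste("position on", chrom),
                   ylab = "mean H12", ylim = c(0, 1), ...)
    for (g in groups[-1])
      graphics::lines(mid[d$group == g], d$h12_mean[d$group == g],
                      col = cols[g])
    graphics::legend("topright", legend = groups, col = cols, lty = 1,
                     bty = "n")
  } else {
    graphics::plot(mid, d[[stat]], type = "h",
                   xlab = paste("position on", chrom), ylab = toupper(stat),
                   ...)
  }
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2, col = "grey40")
  invisible(x)
}
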