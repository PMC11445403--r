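#' Alternate-allele frequency by phenotype group
#'
#' Counts alternate alleles per phenotype group at one site, excluding
#' missing genotypes from the denominator (the "total alleles called").
#'
#' @param gm A [genotype_matrix()].
#' @param panel A [phenotyped_panel()].
#' @param chrom,pos Site to tabulate.
#' @param groups Phenotype groups (default all three).
#' @return A `data.frame` with one row per group: `alt_count`, `n_called`,
#'   `freq_pct` (percent, full precision; `NA` and flagged when no alleles
#'   were called).
#' @export
allele_frequency_by_group <- function(gm, panel, chrom, pos,
                                      groups = c("resistant", "susceptible",
                                                 "control")) {
  i <- site_index(gm, chrom, pos)
  if (is.na(i)) stop(sprintf("site %s:%s not present", chrom,
                             format(pos, big.mark = ",")), call. = FALSE)
  d <- dosage(gm)[i, ]
  rows <- lapply(groups, function(g) {
    smp <- panel_samples(panel, g)
    dg <- d[smp]
    n_called <- 2L * sum(!is.na(dg))
    alt <- sum(dg, na.rm = TRUE)
    data.frame(chrom = chrom, pos = pos, group = g, alt_count = alt,
               n_called = n_called,
               freq_pct = if (n_called > 0) 100 * alt / n_called else
                 NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Heterozygous / homozygous-alternate diplotype counts by group
#'
#' @inheritParams allele_frequency_by_group
#' @return A `data.frame` per group: `n_het`, `n_hom_alt`, `n_called`
#'   (diploid samples with a call).
#' @export
genotype_counts_by_group <- function(gm, panel, chrom, pos,
                                     groups = c("resistant", "susceptible",
                                                "control")) {
  i <- site_index(gm, chrom, pos)
  if (is.na(i)) stop(sprintf("site %s:%s not present", chrom,
                             format(pos, big.mark = ",")), call. = FALSE)
  d <- dosage(gm)[i, ]
  rows <- lapply(groups, function(g) {
    dg <- d[panel_samples(panel, g)]
    data.frame(chrom = chrom, pos = pos, group = g,
               n_het = sum(dg == 1, na.rm = TRUE),
               n_hom_alt = sum(dg == 2, na.rm = TRUE),
               n_called = sum(!is.na(dg)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen a candidate-SNP table against the panel
#'
#' Tabulates, for each candidate SNP present in the matrix, the per-group
#' alternate-allele frequencies, diplotype counts, the pooled-population
#' frequency, the over-5% highlight flag and the resistant-vs-susceptible
#' allele-count odds ratio.
#'
#' @param gm A [genotype_matrix()].
#' @param panel A [phenotyped_panel()].
#' @param candidates `data.frame` with columns `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `label` (amino-acid change, e.g. `L995F`). See
#'   [read_candidate_tsv()].
#' @param threshold_pct Highlight threshold on the pooled frequency
#'   (strictly greater than; default 5).
#' @return A list of class `resistance_screen`: `frequencies` (long table),
#'   `genotypes`, `snps` (per-SNP pooled frequency, highlight flag, odds
#'   ratio with 95% CI), `not_found` (candidates absent from the matrix).
#' @export
screen_candidates <- function(gm, panel, candidates, threshold_pct = 5) {
  stopifnot(all(c("gene", "chrom", "pos", "label") %in% names(candidates)))
  present <- !is.na(mapply(function(ch, p) site_index(gm, ch, p),
                           candidates$chrom, candidates$pos))
  freq <- list(); geno <- list(); snp_rows <- list()
  for (k in which(present)) {
    ch <- candidates$chrom[k]; p <- candidates$pos[k]
    f <- allele_frequency_by_group(gm, panel, ch, p)
    g <- genotype_counts_by_group(gm, panel, ch, p)
    f$gene <- candidates$gene[k]; f$label <- candidates$label[k]
    g$gene <- candidates$gene[k]; g$label <- candidates$label[k]
    freq[[length(freq) + 1L]] <- f
    geno[[length(geno) + 1L]] <- g
    pooled_alt <- sum(f$alt_count); pooled_n <- sum(f$n_called)
    pooled_pct <- if (pooled_n > 0) 100 * pooled_alt / pooled_n else NA_real_
    fr <- f[f$group == "resistant", ]; fs <- f[f$group == "susceptible", ]
    or <- odds_ratio(fr$alt_count, fr$n_called - fr$alt_count,
                     fs$alt_count, fs$n_called - fs$alt_count)
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      gene = candidates$gene[k], chrom = ch, pos = p,
      label = candidates$label[k],
      pooled_freq_pct = pooled_pct,
      highlighted = !is.na(pooled_pct) && pooled_pct > threshold_pct,
      odds_ratio = or$odds_ratio, ci_lower = or$ci_lower,
      ci_upper = or$ci_upper, significant = or$significant,
      continuity_corrected = or$continuity_corrected,
      stringsAsFactors = FALSE)
  }
  structure(list(
    frequencies = if (length(freq)) do.call(rbind, freq) else NULL,
    genotypes = if (length(geno)) do.call(rbind, geno) else NULL,
    snps = if (length(snp_rows)) do.call(rbind, snp_rows) else NULL,
    not_found = candidates[!present, , drop = FALSE]),
    class = "resistance_screen")
}

#' @export
print.resistance_screen <- function(x, ...) {
  cat(sprintf("resistance screen: %d candidate SNP(s) found, %d absent\n",
              if (is.null(x$snps)) 0L else nrow(x$snps), nrow(x$not_found)))
  if (!is.null(x$frequencies)) {
    f <- x$frequencies
    f$freq_pct <- round(f$freq_pct, 1)
    print.data.frame(f[, c("gene", "label", "chrom", "pos", "group",
                           "alt_count", "n_called", "freq_pct")],
                     row.names = FALSE)
  }
  invisible(x)
}

#' Flag SNPs with pooled frequency over a threshold
#'
#' @param freq_table Long frequency table (as in the `frequencies` element
#'   of [screen_candidates()]) covering the pooled sample population.
#' @param threshold_pct Strict threshold, percent (default 5: "over 5%").
#' @return `data.frame` of flagged SNPs with their pooled frequency.
#' @export
highlight_common <- function(freq_table, threshold_pct = 5) {
  key <- paste(freq_table$chrom, freq_table$pos)
  agg <- lapply(split(freq_table, key), function(d)
    data.frame(chrom = d$chrom[1], pos = d$pos[1],
               label = if ("label" %in% names(d)) d$label[1] else NA,
               pooled_freq_pct = 100 * sum(d$alt_count) / sum(d$n_called),
               stringsAsFactors = FALSE))
  agg <- do.call(rbind, agg)
  agg[!is.na(agg$pooled_freq_pct) & agg$pooled_freq_pct > threshold_pct, ,
      drop = FALSE]
}

#' Allele-count odds ratio with Woolf 95% confidence interval
#'
#' 2x2 table of alternate/reference allele counts in resistant vs
#' susceptible mosquitoes. When any cell is zero the Haldane-Anscombe
#' correction adds 0.5 to every cell (flagged). The Woolf interval is
#' `exp(log(OR) +/- 1.96 * sqrt(sum(1/cell)))`; the association is called
#' significant when the interval excludes 1.
#'
#' @param a,b Alternate and reference allele counts in the first group.
#' @param c,d Alternate and reference allele counts in the second group.
#' @return A list of class `odds_ratio_result`.
#' @export
odds_ratio <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  if ((a + b == 0 && c + d == 0) || (a + c == 0 && b + d == 0))
    return(structure(list(table = cells, odds_ratio = NA_real_,
                          ci_lower = NA_real_, ci_upper = NA_real_,
                          significant = NA, continuity_corrected = FALSE,
                          undefined = TRUE), class = "odds_ratio_result"))
  corrected <- any(cells == 0)
  w <- if (corrected) cells + 0.5 else cells
  or <- (w[["a"]] * w[["d"]]) / (w[["b"]] * w[["c"]])
  se <- sqrt(sum(1 / w))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  structure(list(table = cells, odds_ratio = unname(or),
                 ci_lower = ci[1], ci_upper = ci[2],
                 significant = ci[1] > 1 || ci[2] < 1,
                 continuity_corrected = corrected, undefined = FALSE),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("odds ratio: undefined (degenerate margins)\n")
  } else {
    cat(sprintf("odds ratio %.3f (95%% CI %.3f-%.3f)%s%s\n",
                x$odds_ratio, x$ci_lower, x$ci_upper,
                if (x$continuity_corrected) ", Haldane-Anscombe corrected"
                else "",
                if (isTRUE(x$significant)) ", significant" else ""))
  }
  invisible(x)
}

#' Read a candidate-SNP table from TSV
#'
#' Columns: `gene`, `chrom`, `pos`, `ref`, `alt`, `label`.
#'
#' @param path TSV file.
#' @return A `data.frame`.
#' @export
read_candidate_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  miss <- setdiff(c("gene", "chrom", "pos", "label"), names(d))
  if (length(miss)) stop("candidate TSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d
}
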