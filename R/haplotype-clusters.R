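#' Single-linkage haplotype clustering in a window
#'
#' Hierarchically clusters haplotypes on normalised Hamming distance
#' (fraction of differing sites), cuts the single-linkage dendrogram at
#' `max_distance`, and reports clusters of at least `min_cluster` members —
#' high-frequency haplotype groups that may be under directional selection.
#'
#' @param haps Haplotypes x sites 0/1 matrix ([haplotypes()]); row names
#'   identify the haplotypes.
#' @param max_distance Cut height: haplotypes joined at or below this
#'   normalised Hamming distance share a cluster (default 0.001, i.e.
#'   "highly similar" = differing at no more than 0.1% of sites).
#' @param min_cluster Minimum reported cluster size (inclusive, default 20).
#' @param phenotype Optional character vector, one phenotype per haplotype
#'   row, used for per-cluster membership counts.
#' @return A list of class `haplotype_clusters`: `clusters` (data.frame
#'   with `cluster`, `size` and per-phenotype counts), `members` (list of
#'   haplotype ids), `assignment` (cluster id per haplotype).
#' @export
cluster_haplotypes <- function(haps, max_distance = 0.001, min_cluster = 20,
                               phenotype = NULL) {
  if (!is.matrix(haps) || nrow(haps) == 0 || ncol(haps) == 0)
    stop("empty haplotype window", call. = FALSE)
  if (is.null(rownames(haps))) rownames(haps) <- paste0("hap", seq_len(nrow(haps)))
  # Hamming distance on 0/1 rows = Manhattan distance; normalise by sites
  d <- stats::dist(haps, method = "manhattan") / ncol(haps)
  hc <- stats::hclust(d, method = "single")
  assignment <- stats::cutree(hc, h = max_distance)
  sizes <- table(assignment)
  big <- as.integer(names(sizes)[sizes >= min_cluster])
  rows <- list(); members <- list()
  for (cl in big) {
    ids <- rownames(haps)[assignment == cl]
    row <- data.frame(cluster = cl, size = length(ids),
                      stringsAsFactors = FALSE)
    if (!is.null(phenotype)) {
      for (g in unique(phenotype))
        row[[paste0("n_", g)]] <- sum(phenotype[assignment == cl] == g)
    }
    rows[[length(rows) + 1L]] <- row
    members[[as.character(cl)]] <- ids
  }
  structure(list(
    clusters = if (length(rows)) do.call(rbind, rows) else NULL,
    members = members, assignment = assignment,
    max_distance = max_distance, min_cluster = min_cluster),
    class = "haplotype_clusters")
}

#' @export
print.haplotype_clusters <- function(x, ...) {
  n <- if (is.null(x$clusters)) 0L else nrow(x$clusters)
  cat(sprintf(
    "haplotype clusters: %d of size >= %d at single-linkage cut %.4g\n",
    n, x$min_cluster, x$max_distance))
  if (n) print.data.frame(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Fisher test of cluster membership against phenotype
#'
#' Two-sided Fisher exact test on the 2x2 table of cluster membership by
#' phenotype (resistant vs susceptible haplotypes; controls are excluded
#' because their phenotype is unknown).
#'
#' @param in_cluster Logical vector, one entry per haplotype.
#' @param phenotype Character vector (`"resistant"`/`"susceptible"`; other
#'   labels are dropped).
#' @return A list: the 2x2 `table`, `p_value`, `odds_ratio` (conditional
#'   MLE from the exact test), `undefined` flag for degenerate margins.
#' @export
cluster_phenotype_association <- function(in_cluster, phenotype) {
  stopifnot(length(in_cluster) == length(phenotype))
  keep <- phenotype %in% c("resistant", "susceptible")
  in_cluster <- in_cluster[keep]; phenotype <- phenotype[keep]
  tab <- table(factor(in_cluster, levels = c(TRUE, FALSE)),
               factor(phenotype, levels = c("resistant", "susceptible")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, p_value = NA_real_, odds_ratio = NA_real_,
                undefined = TRUE))
  ft <- stats::fisher.test(tab)
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate), undefined = FALSE)
}

#' Cluster haplotypes in flagged windows and test phenotype association
#'
#' For each window of interest (typically FST peaks), clusters the pooled
#' resistant + susceptible haplotypes and Fisher-tests every reported
#' cluster against phenotype, with Benjamini-Hochberg correction across
#' all clusters tested.
#'
#' @param gm A [genotype_matrix()].
#' @param panel A [phenotyped_panel()].
#' @param windows `data.frame` with `chrom`, `start`, `end` (half-open bp
#'   windows).
#' @inheritParams cluster_haplotypes
#' @return A `data.frame`: one row per reported cluster with window
#'   coordinates, size, per-phenotype counts, `p_value` and `p_adj`; `NULL`
#'   when no window yields a cluster.
#' @export
cluster_windows <- function(gm, panel, windows, max_distance = 0.001,
                            min_cluster = 20) {
  groups <- c("resistant", "susceptible")
  samples <- unlist(lapply(groups, panel_samples, panel = panel))
  phen <- rep(panel$phenotype[match(samples, panel$sample)], each = 2L)
  rows <- list()
  for (k in seq_len(nrow(windows))) {
    sites <- which(gm$chrom == windows$chrom[k] &
                     gm$pos >= windows$start[k] & gm$pos < windows$end[k])
    if (length(sites) == 0) next
    haps <- haplotypes(gm, samples, sites)
    cc <- cluster_haplotypes(haps, max_distance, min_cluster, phen)
    if (is.null(cc$clusters)) next
    for (j in seq_len(nrow(cc$clusters))) {
      cl <- cc$clusters$cluster[j]
      assoc <- cluster_phenotype_association(cc$assignment == cl, phen)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(chrom = windows$chrom[k], start = windows$start[k],
                   end = windows$end[k], stringsAsFactors = FALSE),
        cc$clusters[j, ],
        data.frame(p_value = assoc$p_value, stringsAsFactors = FALSE))
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
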