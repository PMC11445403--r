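#' Phased biallelic genotype matrix
#'
#' The central genotype container: a sites x samples x 2 integer array of
#' phased allele indices (0 = reference, 1 = alternate, `NA` = missing call)
#' together with per-site chromosome, position and alleles. Sites must be
#' sorted by chromosome then strictly increasing 1-based position.
#'
#' @param chrom Character vector of chromosome names, one per site.
#' @param pos Integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt Character vectors of reference/alternate alleles.
#' @param geno Integer array of dim `c(n_sites, n_samples, 2)` with values in
#'   `{0, 1, NA}`.
#' @param samples Character vector of sample identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, geno, samples) {
  n_sites <- length(pos)
  stopifnot(length(chrom) == n_sites, length(ref) == n_sites,
            length(alt) == n_sites)
  if (!is.array(geno) || length(dim(geno)) != 3L ||
      dim(geno)[1] != n_sites || dim(geno)[3] != 2L)
    stop("`geno` must be a sites x samples x 2 array", call. = FALSE)
  if (dim(geno)[2] != length(samples))
    stop("sample dimension of `geno` does not match `samples`", call. = FALSE)
  bad <- !(geno %in% c(0L, 1L, NA))
  if (any(bad)) stop("allele indices must be 0, 1 or NA (biallelic scope)",
                     call. = FALSE)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("positions must be strictly increasing on %s", ch),
           call. = FALSE)
  }
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         geno = geno, samples = as.character(samples)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic sites x %d samples (phased)\n",
              n_sites(x), n_samples(x)))
  for (ch in unique(x$chrom)) {
    p <- x$pos[x$chrom == ch]
    cat(sprintf("  %s: %d sites, span %d-%d\n", ch, length(p), min(p), max(p)))
  }
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing allele calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x A `genotype_matrix`.
#' @export
n_sites <- function(x) length(x$pos)

#' @rdname genotype_matrix
#' @export
n_samples <- function(x) length(x$samples)

#' Alternate-allele dosage matrix
#'
#' Collapses the phased array to per-sample dosages in `{0, 1, 2}`; a
#' genotype with either allele missing yields `NA` (the downstream LD and
#' frequency code uses pairwise-complete / non-missing denominators).
#'
#' @param x A `genotype_matrix`.
#' @return Numeric matrix, sites x samples, dimnames set.
#' @export
dosage <- function(x) {
  d <- x$geno[, , 1, drop = FALSE] + x$geno[, , 2, drop = FALSE]
  d <- array(d, dim = dim(x$geno)[1:2])
  dimnames(d) <- list(NULL, x$samples)
  d
}

#' Haplotype matrix for a set of samples
#'
#' Expands the phased array to a haplotypes x sites 0/1 matrix. Haplotypes
#' are ordered sample-major (sample 1 allele a, sample 1 allele b, sample 2
#' allele a, ...), with row names `<sample>_a` / `<sample>_b`.
#'
#' @param x A `genotype_matrix`.
#' @param samples Samples to include (default all).
#' @param sites Optional integer site indices (default all).
#' @return Integer matrix of dim `c(2 * length(samples), length(sites))`.
#' @export
haplotypes <- function(x, samples = x$samples, sites = seq_len(n_sites(x))) {
  idx <- match(samples, x$samples)
  if (anyNA(idx)) stop("unknown samples: ",
                       paste(samples[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  g <- x$geno[sites, idx, , drop = FALSE]
  nh <- 2L * length(idx)
  out <- matrix(NA_integer_, nrow = nh, ncol = length(sites))
  out[seq(1L, nh, by = 2L), ] <- t(array(g[, , 1], dim(g)[1:2]))
  out[seq(2L, nh, by = 2L), ] <- t(array(g[, , 2], dim(g)[1:2]))
  rownames(out) <- paste0(rep(samples, each = 2L), c("_a", "_b"))
  out
}

#' Subset a genotype matrix by site index
#' @param x A `genotype_matrix`.
#' @param sites Integer site indices to keep (in sorted order).
#' @return A `genotype_matrix`.
#' @export
subset_sites <- function(x, sites) {
  genotype_matrix(x$chrom[sites], x$pos[sites], x$ref[sites], x$alt[sites],
                  x$geno[sites, , , drop = FALSE], x$samples)
}

site_index <- function(x, chrom, pos) {
  i <- which(x$chrom == chrom & x$pos == pos)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

#' Phenotyped sample panel
#'
#' @param sample Character vector of sample identifiers (unique).
#' @param phenotype Character vector: `"resistant"`, `"susceptible"` or
#'   `"control"` (controls survived an oil-only exposure; their resistance
#'   phenotype is unknown and they are excluded from association tests).
#' @return A `data.frame` of class `phenotyped_panel`.
#' @export
phenotyped_panel <- function(sample, phenotype) {
  stopifnot(length(sample) == length(phenotype))
  if (anyDuplicated(sample)) stop("duplicate sample ids", call. = FALSE)
  ok <- phenotype %in% c("resistant", "susceptible", "control")
  if (!all(ok)) stop("unknown phenotype label(s): ",
                     paste(unique(phenotype[!ok]), collapse = ", "),
                     call. = FALSE)
  structure(data.frame(sample = as.character(sample),
                       phenotype = as.character(phenotype),
                       stringsAsFactors = FALSE),
            class = c("phenotyped_panel", "data.frame"))
}

panel_samples <- function(panel, group) panel$sample[panel$phenotype == group]
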