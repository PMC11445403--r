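# Build a genotype_matrix from explicit haplotype matrices.
# hap_a / hap_b: sites x samples 0/1 matrices (allele a / b of each sample).
gm_from_haps <- function(hap_a, hap_b, chrom = "1", pos = NULL,
                         samples = NULL) {
  ns <- nrow(hap_a)
  nsmp <- ncol(hap_a)
  pos <- pos %||% seq_len(ns)
  samples <- samples %||% sprintf("s%02d", seq_len(nsmp))
  geno <- array(NA_integer_, dim = c(ns, nsmp, 2))
  geno[, , 1] <- hap_a
  geno[, , 2] <- hap_b
  genotype_matrix(rep(chrom, ns), pos, rep("A", ns), rep("T", ns),
                  geno, samples)
}

# Build a genotype_matrix from a dosage matrix (sites x samples in 0/1/2,
# NA = missing); heterozygotes are phased ref|alt.
gm_from_dosage <- function(d, chrom = "1", pos = NULL, samples = NULL) {
  a <- ifelse(is.na(d), NA_integer_, as.integer(d == 2))
  b <- ifelse(is.na(d), NA_integer_, as.integer(d >= 1))
  gm_from_haps(a, b, chrom, pos, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# haplotype matrix with given class counts and site patterns
haps_with_freqs <- function(counts, patterns) {
  do.call(rbind, mapply(function(k, p)
    matrix(rep(p, k), nrow = k, byrow = TRUE),
    counts, patterns, SIMPLIFY = FALSE))
}

# study-shaped WHO tube-test counts (two tests with their own controls)
study_bioassay_records <- function() {
  rbind(
    data.frame(test = "discriminating", role = "treatment", replicate = 1:5,
               n_exposed = c(20, 20, 20, 20, 21),
               n_dead = c(10, 10, 10, 10, 10)),
    data.frame(test = "discriminating", role = "control", replicate = 1,
               n_exposed = 66, n_dead = 5),
    data.frame(test = "intensity_5x", role = "treatment", replicate = 1:3,
               n_exposed = c(15, 15, 15), n_dead = c(14, 14, 14)),
    data.frame(test = "intensity_5x", role = "control", replicate = 1,
               n_exposed = 37, n_dead = 4))
}
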