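#' Variant-filter thresholds
#'
#' The GATK-recommendation hard filters used to retain high-quality SNPs,
#' plus genotype-level and missingness rules and the sample-coverage rule.
#' All site-annotation comparisons are strict inequalities; an absent
#' annotation passes its rule by default (the GATK convention), switchable
#' with `strict_missing_info`.
#'
#' @param qd_min,qual_min,sor_max,fs_max,mq_min,mqranksum_min,readpos_min
#'   Site-annotation thresholds (`QD > 5`, `QUAL > 30`, `SOR < 3`,
#'   `FS < 60`, `MQ > 40`, `MQRankSum > -12.5`, `ReadPosRankSum > -8`).
#' @param dp_min,gq_min Genotype thresholds (`DP > 5`, `GQ > 20`); failing
#'   genotypes are set missing.
#' @param max_missing Drop sites with a missing-genotype fraction above this
#'   (default 0.20).
#' @param sample_cov_fraction,sample_cov_depth Retain samples with at least
#'   `sample_cov_fraction` of the genome above `sample_cov_depth`-fold
#'   coverage.
#' @param strict_missing_info If `TRUE`, an absent site annotation fails its
#'   rule.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(qd_min = 5.0, qual_min = 30.0, sor_max = 3.0,
                          fs_max = 60.0, mq_min = 40.0,
                          mqranksum_min = -12.5, readpos_min = -8.0,
                          dp_min = 5, gq_min = 20, max_missing = 0.20,
                          sample_cov_fraction = 0.40, sample_cov_depth = 10,
                          strict_missing_info = FALSE) {
  cfg <- list(qd_min = qd_min, qual_min = qual_min, sor_max = sor_max,
              fs_max = fs_max, mq_min = mq_min,
              mqranksum_min = mqranksum_min, readpos_min = readpos_min,
              dp_min = dp_min, gq_min = gq_min, max_missing = max_missing,
              sample_cov_fraction = sample_cov_fraction,
              sample_cov_depth = sample_cov_depth,
              strict_missing_info = strict_missing_info)
  stopifnot(all(vapply(cfg[1:12], function(x)
    is.numeric(x) || is.logical(x), logical(1))),
    max_missing >= 0, max_missing <= 1,
    sample_cov_fraction >= 0, sample_cov_fraction <= 1)
  structure(cfg, class = "filter_config")
}

#' Site-level hard filter
#'
#' Applies the seven GATK-style site rules with strict inequalities and
#' reports, per site, whether it passes and which rules it fails.
#'
#' @param site_qc `data.frame` with columns `QUAL`, `QD`, `SOR`, `FS`, `MQ`,
#'   `MQRankSum`, `ReadPosRankSum` (from [read_vcf()]).
#' @param config A [filter_config()].
#' @return A `data.frame` with logical `pass` and character `failed_rules`
#'   (comma-separated rule names, `""` when passing).
#' @export
site_filter <- function(site_qc, config = filter_config()) {
  need <- c("QUAL", "QD", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
  miss <- setdiff(need, names(site_qc))
  if (length(miss)) stop("site_qc lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  rule <- function(values, ok) {
    # NA annotation: pass unless strict mode
    ifelse(is.na(values), !config$strict_missing_info, ok)
  }
  checks <- cbind(
    QD = rule(site_qc$QD, site_qc$QD > config$qd_min),
    QUAL = rule(site_qc$QUAL, site_qc$QUAL > config$qual_min),
    SOR = rule(site_qc$SOR, site_qc$SOR < config$sor_max),
    FS = rule(site_qc$FS, site_qc$FS < config$fs_max),
    MQ = rule(site_qc$MQ, site_qc$MQ > config$mq_min),
    MQRankSum = rule(site_qc$MQRankSum,
                     site_qc$MQRankSum > config$mqranksum_min),
    ReadPosRankSum = rule(site_qc$ReadPosRankSum,
                          site_qc$ReadPosRankSum > config$readpos_min))
  failed <- apply(checks, 1, function(row)
    paste(colnames(checks)[!row], collapse = ","))
  data.frame(pass = rowSums(!checks) == 0, failed_rules = failed,
             stringsAsFactors = FALSE)
}

#' Mask low-quality genotypes
#'
#' Sets a genotype to missing unless `DP > dp_min` and `GQ > gq_min`
#' (strict; a genotype at exactly the threshold is masked). Genotypes with
#' absent DP/GQ are retained.
#'
#' @param vcf A `vcf_data` object from [read_vcf()] (or a list with
#'   `matrix`, `dp`, `gq`).
#' @param config A [filter_config()].
#' @return The `vcf_data` with failing genotypes set missing in `matrix`,
#'   plus attribute `"n_masked"`.
#' @export
genotype_mask <- function(vcf, config = filter_config()) {
  gm <- vcf$matrix
  fail <- (!is.na(vcf$dp) & vcf$dp <= config$dp_min) |
    (!is.na(vcf$gq) & vcf$gq <= config$gq_min)
  was_called <- !is.na(gm$geno[, , 1])
  gm$geno[, , 1][fail] <- NA_integer_
  gm$geno[, , 2][fail] <- NA_integer_
  vcf$matrix <- gm
  attr(vcf, "n_masked") <- sum(fail & was_called)
  vcf
}

#' Drop sites with excess missing genotypes
#'
#' Run after [genotype_mask()]; drops sites whose missing-genotype fraction
#' exceeds `max_missing`.
#'
#' @param gm A [genotype_matrix()].
#' @param config A [filter_config()].
#' @return A list: `matrix` (retained sites), `kept` (logical per input
#'   site), `missing_fraction`.
#' @export
missingness_filter <- function(gm, config = filter_config()) {
  missing <- is.na(array(gm$geno[, , 1], dim(gm$geno)[1:2]))
  frac <- rowMeans(missing)
  kept <- frac <= config$max_missing
  list(matrix = subset_sites(gm, which(kept)), kept = kept,
       missing_fraction = frac)
}

#' Retain samples by genome coverage
#'
#' Keeps samples for which at least `sample_cov_fraction` of the genome has
#' more than `sample_cov_depth`-fold coverage (inclusive on the fraction).
#' The fractions are an input (computed from alignments upstream of this
#' package).
#'
#' @param covered_fraction Named numeric vector in `[0, 1]`, one entry per
#'   sample.
#' @param config A [filter_config()].
#' @return Character vector of retained sample names.
#' @export
sample_coverage_filter <- function(covered_fraction,
                                   config = filter_config()) {
  if (any(is.na(covered_fraction)) || any(covered_fraction < 0) ||
      any(covered_fraction > 1))
    stop("covered fractions must lie in [0, 1]", call. = FALSE)
  if (is.null(names(covered_fraction)))
    stop("`covered_fraction` must be named by sample", call. = FALSE)
  names(covered_fraction)[covered_fraction >= config$sample_cov_fraction]
}

#' Full variant-QC pass over a VCF
#'
#' Composes the stages in their required order: site filter, genotype mask,
#' missingness filter (the missingness rule is only meaningful after
#' masking). Site filter and genotype mask commute; their order here is
#' conventional.
#'
#' @param vcf A `vcf_data` from [read_vcf()].
#' @param config A [filter_config()].
#' @return A list of class `qc_result`: `matrix` (the filtered
#'   [genotype_matrix()]), `site_report` (chrom, pos, pass, failed_rules,
#'   missing_fraction, retained), and `counts`.
#' @export
apply_variant_qc <- function(vcf, config = filter_config()) {
  gm0 <- vcf$matrix
  sf <- site_filter(vcf$site_qc, config)
  masked <- genotype_mask(vcf, config)
  keep_site <- which(sf$pass)
  gm1 <- subset_sites(masked$matrix, keep_site)
  mf <- missingness_filter(gm1, config)
  retained <- logical(n_sites(gm0))
  retained[keep_site] <- mf$kept
  missing_fraction <- rep(NA_real_, n_sites(gm0))
  missing_fraction[keep_site] <- mf$missing_fraction
  report <- data.frame(chrom = gm0$chrom, pos = gm0$pos, pass = sf$pass,
                       failed_rules = sf$failed_rules,
                       missing_fraction = missing_fraction,
                       retained = retained, stringsAsFactors = FALSE)
  report$failed_rules[sf$pass & !retained] <- "missingness"
  structure(list(matrix = mf$matrix, site_report = report,
                 counts = c(input = n_sites(gm0),
                            site_pass = length(keep_site),
                            retained = n_sites(mf$matrix),
                            genotypes_masked = attr(masked, "n_masked"))),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("variant QC result\n")
  cat(sprintf("  sites in: %d; passing site filter: %d; retained: %d\n",
              x$counts[["input"]], x$counts[["site_pass"]],
              x$counts[["retained"]]))
  cat(sprintf("  genotypes masked (DP/GQ): %d\n",
              x$counts[["genotypes_masked"]]))
  invisible(x)
}
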