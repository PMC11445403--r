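#' Site and genotype quality annotation model for synthetic VCFs
#'
#' Supplies the INFO annotations the GATK-style site filter consumes (QD,
#' SOR, FS, MQ, MQRankSum, ReadPosRankSum, QUAL) and the per-genotype DP/GQ
#' values. Each field is a scalar recycled over sites, or a vector with one
#' value per site; `overrides` pins individual sites to chosen values so
#' that tests can plant exactly one filter violation per record.
#'
#' @param qd,qual,sor,fs,mq,mq_rank_sum,read_pos_rank_sum Site annotations.
#'   Defaults sit comfortably inside the filter thresholds.
#' @param dp,gq Genotype-level depth and quality: scalar, or a sites x
#'   samples matrix.
#' @param overrides Optional `data.frame` with columns `chrom`, `pos`,
#'   `field`, `value` applied after recycling.
#' @return A list of class `qc_field_model`.
#' @export
qc_field_model <- function(qd = 30, qual = 500, sor = 1, fs = 10, mq = 60,
                           mq_rank_sum = 0, read_pos_rank_sum = 0,
                           dp = 20, gq = 99, overrides = NULL) {
  structure(list(QD = qd, QUAL = qual, SOR = sor, FS = fs, MQ = mq,
                 MQRankSum = mq_rank_sum, ReadPosRankSum = read_pos_rank_sum,
                 dp = dp, gq = gq, overrides = overrides),
            class = "qc_field_model")
}

materialise_qc <- function(qc, gm) {
  ns <- n_sites(gm)
  site <- data.frame(QUAL = rep_len(qc$QUAL, ns), QD = rep_len(qc$QD, ns),
                     SOR = rep_len(qc$SOR, ns), FS = rep_len(qc$FS, ns),
                     MQ = rep_len(qc$MQ, ns),
                     MQRankSum = rep_len(qc$MQRankSum, ns),
                     ReadPosRankSum = rep_len(qc$ReadPosRankSum, ns))
  if (!is.null(qc$overrides)) {
    ov <- qc$overrides
    for (k in seq_len(nrow(ov))) {
      i <- site_index(gm, ov$chrom[k], ov$pos[k])
      if (is.na(i)) stop(sprintf("override site %s:%d not in matrix",
                                 ov$chrom[k], ov$pos[k]), call. = FALSE)
      site[i, ov$field[k]] <- ov$value[k]
    }
  }
  to_mat <- function(v) if (is.matrix(v)) v else
    matrix(v, nrow = ns, ncol = n_samples(gm))
  list(site = site, dp = to_mat(qc$dp), gq = to_mat(qc$gq))
}

#' Write a phased biallelic VCF v4.2
#'
#' One record per site, phased `GT` (`0|1` style, `.|.` for missing), INFO
#' fields QD/SOR/FS/MQ/MQRankSum/ReadPosRankSum and FORMAT `GT:DP:GQ`.
#' Round-trips losslessly through [read_vcf()].
#'
#' @param gm A [genotype_matrix()] (sites must be sorted; unsorted input is
#'   an error).
#' @param path Output file path.
#' @param qc A [qc_field_model()].
#' @param contig_lengths Optional named vector of chromosome lengths for the
#'   header; defaults to the maximum observed position per chromosome.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, qc = qc_field_model(),
                      contig_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ord <- order(match(gm$chrom, unique(gm$chrom)), gm$pos)
  if (!identical(ord, seq_len(n_sites(gm))))
    stop("sites are not sorted by chromosome and position", call. = FALSE)
  m <- materialise_qc(qc, gm)
  contigs <- unique(gm$chrom)
  if (is.null(contig_lengths))
    contig_lengths <- vapply(contigs, function(ch)
      max(gm$pos[gm$chrom == ch]), numeric(1))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs,
            as.integer(contig_lengths[contigs])),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Symmetric odds ratio of strand bias\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias phred\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  a1 <- array(gm$geno[, , 1], dim(gm$geno)[1:2])
  a2 <- array(gm$geno[, , 2], dim(gm$geno)[1:2])
  gt <- matrix(paste0(ifelse(is.na(a1), ".", a1), "|",
                      ifelse(is.na(a2), ".", a2)),
               nrow = n_sites(gm))
  cells <- matrix(paste0(gt, ":", m$dp, ":", m$gq), nrow = n_sites(gm))
  info <- sprintf("QD=%g;SOR=%g;FS=%g;MQ=%g;MQRankSum=%g;ReadPosRankSum=%g",
                  m$site$QD, m$site$SOR, m$site$FS, m$site$MQ,
                  m$site$MQRankSum, m$site$ReadPosRankSum)
  body <- apply(cbind(gm$chrom, gm$pos, ".", gm$ref, gm$alt,
                      format(m$site$QUAL, trim = TRUE), "PASS", info,
                      "GT:DP:GQ", cells),
                1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phased biallelic VCF
#'
#' Parses with vcfR and returns the package's genotype container plus the
#' site and genotype quality annotations the QC filters consume. Multiallelic
#' records are rejected with a count (split them upstream with bcftools).
#'
#' @param path VCF file (v4.2 text, optionally gzipped).
#' @return A list of class `vcf_data`: `matrix` ([genotype_matrix()]),
#'   `site_qc` (data.frame QUAL/QD/SOR/FS/MQ/MQRankSum/ReadPosRankSum),
#'   `dp`, `gq` (sites x samples numeric matrices, `NA` where absent).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    stop(sprintf("%d multiallelic record(s); biallelic scope only",
                 sum(multi)), call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  ns <- nrow(fix)
  samples <- colnames(gt)
  geno <- array(NA_integer_, dim = c(ns, length(samples), 2L))
  geno[, , 1] <- a1
  geno[, , 2] <- a2
  gm <- genotype_matrix(fix[, "CHROM"], as.integer(fix[, "POS"]),
                        fix[, "REF"], fix[, "ALT"], geno, samples)
  info_num <- function(field)
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = field)))
  site_qc <- data.frame(
    QUAL = suppressWarnings(as.numeric(fix[, "QUAL"])),
    QD = info_num("QD"), SOR = info_num("SOR"), FS = info_num("FS"),
    MQ = info_num("MQ"), MQRankSum = info_num("MQRankSum"),
    ReadPosRankSum = info_num("ReadPosRankSum"))
  num_mat <- function(el) {
    m <- tryCatch(vcfR::extract.gt(v, element = el, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) matrix(NA_real_, ns, length(samples)) else m
  }
  structure(list(matrix = gm, site_qc = site_qc,
                 dp = num_mat("DP"), gq = num_mat("GQ")),
            class = "vcf_data")
}

#' @export
print.vcf_data <- function(x, ...) {
  cat("vcf_data\n")
  print(x$matrix)
  invisible(x)
}
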