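clean_qc <- function(n) data.frame(QUAL = rep(500, n), QD = 30, SOR = 1,
                                   FS = 10, MQ = 60, MQRankSum = 0,
                                   ReadPosRankSum = 0)

test_that("site filter applies strict thresholds and names failed rules", {
  qc <- clean_qc(4)
  qc$QD[2] <- 4.9
  qc$QD[3] <- 5.0          # boundary: strict ">"
  res <- site_filter(qc)
  expect_equal(res$pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$failed_rules[2], "QD")
  expect_equal(res$failed_rules[3], "QD")
  expect_equal(res$failed_rules[1], "")
})

test_that("each site rule trips independently at its threshold", {
  viol <- list(QD = 5.0, QUAL = 30.0, SOR = 3.0, FS = 60.0, MQ = 40.0,
               MQRankSum = -12.5, ReadPosRankSum = -8.0)
  qc <- clean_qc(length(viol))
  for (k in seq_along(viol)) qc[k, names(viol)[k]] <- viol[[k]]
  res <- site_filter(qc)
  expect_false(any(res$pass))
  expect_equal(res$failed_rules, names(viol))
})

test_that("absent annotations pass by default and fail in strict mode", {
  qc <- clean_qc(2)
  qc$MQRankSum[1] <- NA
  expect_true(site_filter(qc)$pass[1])
  strict <- site_filter(qc, filter_config(strict_missing_info = TRUE))
  expect_false(strict$pass[1])
  expect_equal(strict$failed_rules[1], "MQRankSum")
})

test_that("genotype mask enforces DP > 5 and GQ > 20, matching brute force", {
  set.seed(42)
  n_smp <- 10
  gm <- gm_from_dosage(matrix(1, nrow = 1, ncol = n_smp))
  dp <- matrix(c(5, 6, 4, 20, 20, 20, 20, 20, 20, 20), nrow = 1)
  gq <- matrix(c(99, 21, 99, 20, 19, 99, 99, 99, 99, 99), nrow = 1)
  vcf <- structure(list(matrix = gm, dp = dp, gq = gq), class = "vcf_data")
  masked <- genotype_mask(vcf)
  expected_masked <- sum(dp <= 5 | gq <= 20)
  expect_equal(attr(masked, "n_masked"), expected_masked)
  expect_equal(sum(is.na(masked$matrix$geno[1, , 1])), expected_masked)
  # DP=6, GQ=21 is retained (second sample)
  expect_false(is.na(masked$matrix$geno[1, 2, 1]))
})

test_that("missingness filter drops sites over 20% missing", {
  d <- matrix(1, nrow = 3, ncol = 42)
  d[1, 1:9] <- NA   # 9/42 = 21.4% -> dropped
  d[2, 1:8] <- NA   # 8/42 = 19.0% -> kept
  gm <- gm_from_dosage(d)
  mf <- missingness_filter(gm)
  expect_equal(mf$kept, c(FALSE, TRUE, TRUE))
  expect_equal(n_sites(mf$matrix), 2)
  expect_equal(mf$missing_fraction, c(9, 8, 0) / 42)
})

test_that("sample coverage rule is inclusive at 40%", {
  fr <- c(a = 0.1, b = 0.45, c = 0.4, d = 0.39)
  expect_equal(sample_coverage_filter(fr), c("b", "c"))
  expect_equal(sample_coverage_filter(c(x = 1, y = 1)), c("x", "y"))
  expect_error(sample_coverage_filter(c(a = 1.2)), "\\[0, 1\\]")
})

test_that("a VCF with one planted violation per rule retains only the clean records", {
  # 12 records: 7 single-rule site violations, 1 excess-missingness site
  # (planted via low DP in 5 of 10 samples), 4 clean
  d <- matrix(1, nrow = 12, ncol = 10)
  gm <- gm_from_dosage(d, pos = seq(100, 1200, by = 100))
  viol <- data.frame(
    chrom = "1", pos = seq(100, 700, by = 100),
    field = c("QD", "QUAL", "SOR", "FS", "MQ", "MQRankSum",
              "ReadPosRankSum"),
    value = c(4.0, 10, 5, 80, 20, -20, -10), stringsAsFactors = FALSE)
  dp <- matrix(20, nrow = 12, ncol = 10)
  dp[8, 1:5] <- 3   # 50% of genotypes masked at site 8 -> missingness
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path, qc_field_model(dp = dp, overrides = viol))
  qc <- apply_variant_qc(read_vcf(path))
  expect_equal(n_sites(qc$matrix), 4)
  expect_equal(qc$matrix$pos, seq(900, 1200, by = 100))
  rep <- qc$site_report
  expect_equal(rep$failed_rules[1:7], viol$field)
  expect_equal(rep$failed_rules[8], "missingness")
  expect_true(all(rep$retained[9:12]))
  expect_equal(sum(rep$retained), 4)
})

test_that("site filter and genotype mask commute", {
  set.seed(7)
  d <- matrix(sample(0:2, 60, replace = TRUE), nrow = 6)
  gm <- gm_from_dosage(d)
  dp <- matrix(sample(c(3, 20), 60, replace = TRUE), nrow = 6)
  site_qc <- clean_qc(6); site_qc$MQ[2] <- 10
  vcf <- structure(list(matrix = gm, site_qc = site_qc, dp = dp,
                        gq = matrix(99, 6, 10)), class = "vcf_data")
  # mask then site-subset
  m1 <- genotype_mask(vcf)
  g1 <- subset_sites(m1$matrix, which(site_filter(site_qc)$pass))
  # site-subset then mask
  keep <- which(site_filter(site_qc)$pass)
  vcf2 <- structure(list(matrix = subset_sites(gm, keep),
                         dp = dp[keep, , drop = FALSE],
                         gq = matrix(99, length(keep), 10)),
                    class = "vcf_data")
  g2 <- genotype_mask(vcf2)$matrix
  expect_identical(g1$geno, g2$geno)
})
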