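make_panel <- function(n_res, n_sus, n_con) {
  phenotyped_panel(
    sprintf("s%02d", seq_len(n_res + n_sus + n_con)),
    rep(c("resistant", "susceptible", "control"), c(n_res, n_sus, n_con)))
}

test_that("group allele frequencies match a brute-force count", {
  set.seed(11)
  d <- matrix(sample(c(0:2, NA), 42 * 20, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)), nrow = 20)
  gm <- gm_from_dosage(d)
  panel <- make_panel(23, 10, 9)
  for (site in c(1, 7, 20)) {
    f <- allele_frequency_by_group(gm, panel, "1", site)
    for (g in c("resistant", "susceptible", "control")) {
      idx <- which(panel$phenotype == g)
      dg <- d[site, idx]
      expect_equal(f$alt_count[f$group == g], sum(dg, na.rm = TRUE))
      expect_equal(f$n_called[f$group == g], 2 * sum(!is.na(dg)))
    }
  }
})

test_that("7 alternate alleles among 44 called gives 15.9%", {
  d <- matrix(0, nrow = 1, ncol = 23)
  d[1, 1:7] <- 1        # 7 het carriers
  d[1, 23] <- NA        # 1 missing genotype -> 44 alleles called
  gm <- gm_from_dosage(d)
  panel <- phenotyped_panel(sprintf("s%02d", 1:23), rep("resistant", 23))
  f <- allele_frequency_by_group(gm, panel, "1", 1, groups = "resistant")
  expect_equal(f$alt_count, 7)
  expect_equal(f$n_called, 44)
  expect_equal(round(f$freq_pct, 1), 15.9)
})

test_that("diplotype counts equal a brute-force tally and are consistent with allele counts", {
  set.seed(12)
  d <- matrix(sample(c(0:2, NA), 42 * 10, replace = TRUE), nrow = 10)
  gm <- gm_from_dosage(d)
  panel <- make_panel(23, 10, 9)
  for (site in c(2, 9)) {
    g <- genotype_counts_by_group(gm, panel, "1", site)
    f <- allele_frequency_by_group(gm, panel, "1", site)
    for (grp in c("resistant", "susceptible", "control")) {
      idx <- which(panel$phenotype == grp)
      expect_equal(g$n_het[g$group == grp], sum(d[site, idx] == 1,
                                                na.rm = TRUE))
      expect_equal(g$n_hom_alt[g$group == grp], sum(d[site, idx] == 2,
                                                    na.rm = TRUE))
      # allele count = het + 2 * hom-alt
      expect_equal(f$alt_count[f$group == grp],
                   g$n_het[g$group == grp] + 2 * g$n_hom_alt[g$group == grp])
    }
  }
})

test_that("13 het + 4 hom-alt among 23 gives a 45.7% allele frequency", {
  d <- matrix(0, nrow = 1, ncol = 23)
  d[1, 1:13] <- 1; d[1, 14:17] <- 2
  gm <- gm_from_dosage(d)
  panel <- phenotyped_panel(sprintf("s%02d", 1:23), rep("resistant", 23))
  f <- allele_frequency_by_group(gm, panel, "1", 1, groups = "resistant")
  expect_equal(f$alt_count, 13 + 2 * 4)
  expect_equal(round(f$freq_pct, 1), round(100 * 21 / 46, 1))
})

test_that("highlighting is strict at the 5% pooled threshold", {
  ft <- data.frame(chrom = "1", pos = c(1, 1, 2, 2, 3, 3),
                   group = rep(c("resistant", "susceptible"), 3),
                   alt_count = c(6, 1, 4, 1, 0, 0),
                   n_called = c(80, 22, 80, 20, 80, 20))
  # pos 1: 7/102 = 6.9% -> flagged; pos 2: 5/100 = 5.0% exactly -> not
  out <- highlight_common(ft)
  expect_equal(out$pos, 1)
  expect_equal(round(out$pooled_freq_pct, 1), 6.9)
})

test_that("odds ratio, Haldane correction and Woolf interval", {
  sym <- odds_ratio(10, 10, 10, 10)
  expect_equal(sym$odds_ratio, 1)
  expect_true(sym$ci_lower < 1 && sym$ci_upper > 1)
  expect_false(sym$significant)
  expect_false(sym$continuity_corrected)

  z <- odds_ratio(5, 41, 0, 20)
  expect_true(z$continuity_corrected)
  or_expect <- (5.5 * 20.5) / (41.5 * 0.5)
  se_expect <- sqrt(1 / 5.5 + 1 / 41.5 + 1 / 0.5 + 1 / 20.5)
  expect_equal(z$odds_ratio, or_expect)
  expect_equal(z$ci_lower, exp(log(or_expect) - 1.96 * se_expect))
  expect_equal(z$ci_upper, exp(log(or_expect) + 1.96 * se_expect))
  expect_equal(z$significant, z$ci_lower > 1 || z$ci_upper < 1)

  expect_true(odds_ratio(0, 10, 5, 5)$continuity_corrected)
  expect_true(odds_ratio(0, 0, 0, 0)$undefined)   # both margins empty
})

test_that("odds ratio is invariant under swapping both rows and columns", {
  set.seed(5)
  for (k in 1:20) {
    cc <- sample(0:30, 4, replace = TRUE)
    a <- odds_ratio(cc[1], cc[2], cc[3], cc[4])
    b <- odds_ratio(cc[4], cc[3], cc[2], cc[1])
    if (!isTRUE(a$undefined))
      expect_equal(a$odds_ratio, b$odds_ratio)
  }
})

test_that("screen_candidates recovers planted truth and reports absentees", {
  cfg <- sim_config(n_resistant = 8, n_susceptible = 6, n_control = 2,
                    chromosomes = c(chr = 10000), n_sites = 50, seed = 21)
  feats <- list(planted_feature("candidate_snp", "chr", pos = 5000,
                                freq = c(resistant = 0.5, susceptible = 0,
                                         control = 0.25), name = "mut"))
  sim <- generate_panel(cfg, feats)
  cand <- data.frame(gene = c("g1", "g2"), chrom = "chr",
                     pos = c(5000, 99999), ref = "A", alt = "T",
                     label = c("mut", "ghost"))
  scr <- screen_candidates(sim$matrix, sim$panel, cand)
  expect_equal(nrow(scr$not_found), 1)
  expect_equal(scr$not_found$label, "ghost")
  tr <- sim$truth$features
  f <- scr$frequencies
  for (g in c("resistant", "susceptible", "control"))
    expect_equal(f$alt_count[f$group == g],
                 tr$alt_count[tr$group == g])
  expect_true(all(c("odds_ratio", "highlighted") %in% names(scr$snps)))
})
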