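test_that("panel generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_resistant = 5, n_susceptible = 4, n_control = 3,
                    chromosomes = c(a = 20000, b = 10000),
                    n_sites = c(a = 100, b = 50), missing_rate = 0.05,
                    seed = 1)
  s1 <- generate_panel(cfg)
  s2 <- generate_panel(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$panel, s2$panel)
})

test_that("planted group frequency 0 yields zero alternate alleles", {
  cfg <- sim_config(n_resistant = 10, n_susceptible = 5, n_control = 2,
                    chromosomes = c(chr = 5000), n_sites = 20, seed = 2)
  sim <- generate_panel(cfg, list(planted_feature(
    "candidate_snp", "chr", pos = 2500,
    freq = c(resistant = 0, susceptible = 0.8, control = 0.5))))
  tr <- sim$truth$features
  expect_equal(tr$alt_count[tr$group == "resistant"], 0)
  i <- which(sim$matrix$pos == 2500)
  res <- sim$panel$sample[sim$panel$phenotype == "resistant"]
  expect_true(all(dosage(sim$matrix)[i, res] == 0))
})

test_that("realised frequencies follow the binomial sampling law", {
  # 2000 replicate sites at planted frequency 0.25 in 23 diploids (n = 46
  # alleles per site): the mean realised frequency lies within 3 standard
  # errors of 0.25
  cfg <- sim_config(n_resistant = 23, n_susceptible = 0, n_control = 0,
                    chromosomes = c(chr = 10000), n_sites = 2000, seed = 3)
  sim <- generate_panel(cfg, list(planted_feature(
    "diff_window", "chr", start = 1, end = 10001,
    freq = c(resistant = 0.25, susceptible = 0.25, control = 0.25),
    name = "bulk")))
  tr <- sim$truth$features
  n_draws <- tr$n_alleles[tr$group == "resistant"]
  p_hat <- tr$alt_count[tr$group == "resistant"] / n_draws
  se <- sqrt(0.25 * 0.75 / n_draws)
  expect_lt(abs(p_hat - 0.25), 3 * se)
})

test_that("features outside chromosome bounds are rejected with a message", {
  cfg <- sim_config(chromosomes = c(chr = 1000), n_sites = 10, seed = 4)
  expect_error(generate_panel(cfg, list(planted_feature(
    "candidate_snp", "chr", pos = 2000, freq = 0.5))), "outside")
  expect_error(generate_panel(cfg, list(planted_feature(
    "sweep", "chr", start = 900, end = 1500, core_freq = 0.5))), "outside")
  expect_error(generate_panel(cfg, list(planted_feature(
    "sweep", "zz", start = 1, end = 10, core_freq = 0.5))), "unknown")
})

test_that("overlapping sweep/diff features are rejected", {
  cfg <- sim_config(chromosomes = c(chr = 10000), n_sites = 10, seed = 5)
  f1 <- planted_feature("sweep", "chr", start = 1, end = 5000,
                        core_freq = 0.5, name = "s1")
  f2 <- planted_feature("diff_window", "chr", start = 4000, end = 6000,
                        freq = 0.5, name = "d1")
  expect_error(generate_panel(cfg, list(f1, f2)), "overlap")
})

test_that("positions are strictly increasing and missingness is planted", {
  cfg <- sim_config(chromosomes = c(a = 5000, b = 5000), n_sites = 200,
                    missing_rate = 0.1, seed = 6)
  sim <- generate_panel(cfg)
  for (ch in c("a", "b"))
    expect_true(all(diff(sim$matrix$pos[sim$matrix$chrom == ch]) > 0))
  miss <- mean(is.na(sim$matrix$geno[, , 1]))
  expect_gt(miss, 0.05); expect_lt(miss, 0.15)
  # both alleles of a genotype are missing together
  expect_identical(is.na(sim$matrix$geno[, , 1]),
                   is.na(sim$matrix$geno[, , 2]))
})

test_that("VCF writer emits parseable records that round-trip", {
  d <- matrix(c(0, 1, 2, NA, 1, 0), nrow = 3)
  gm <- gm_from_dosage(d, pos = c(100, 200, 300))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  lines <- readLines(path)
  expect_equal(sum(!startsWith(lines, "#")), 3)
  expect_true(any(startsWith(lines, "##fileformat=VCFv4.2")))
  v <- read_vcf(path)
  expect_identical(v$matrix$geno, gm$geno)
  expect_identical(v$matrix$pos, gm$pos)
  expect_equal(v$site_qc$QD, rep(30, 3))
  expect_equal(v$dp, matrix(20, 3, 2), ignore_attr = TRUE)
})

test_that("a planted QD violation fails the site filter downstream", {
  d <- matrix(1, nrow = 3, ncol = 4)
  gm <- gm_from_dosage(d, pos = c(10, 20, 30))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path, qc_field_model(overrides = data.frame(
    chrom = "1", pos = 20, field = "QD", value = 4.0)))
  sf <- site_filter(read_vcf(path)$site_qc)
  expect_equal(sf$pass, c(TRUE, FALSE, TRUE))
  expect_equal(sf$failed_rules[2], "QD")
})

test_that("breakpoint reads honour the clip fraction and SAM grammar", {
  cnv <- planted_feature("cnv", "chr", start = 5000, end = 8000,
                         clip_fraction = 0.3, carriers = "s1",
                         name = "dup")
  none <- generate_breakpoint_reads(cnv, depth = 30, clip_fraction = 0,
                                    seed = 7)
  expect_false(any(grepl("S", none$cigar)))
  all_clip <- generate_breakpoint_reads(cnv, depth = 30, clip_fraction = 1,
                                        seed = 7)
  expect_true(all(grepl("S", all_clip$cigar)))
  # CIGAR lengths sum to the read length (format grammar)
  lens <- vapply(strsplit(all_clip$cigar, "(?<=[MS])", perl = TRUE),
                 function(ops) sum(as.integer(sub("[MS]", "", ops))),
                 numeric(1))
  expect_true(all(lens == 100))
  expect_identical(generate_breakpoint_reads(cnv, 30, 0.5, seed = 9),
                   generate_breakpoint_reads(cnv, 30, 0.5, seed = 9))
  expect_error(generate_breakpoint_reads(cnv, 30, 0.5, read_len = 0),
               "read_len")
})

test_that("SAM output passes Rsamtools validation and round-trips fields", {
  cnv <- planted_feature("cnv", "chr2", start = 2000, end = 4000,
                         clip_fraction = 0.4, carriers = "x", name = "d7")
  reads <- generate_breakpoint_reads(cnv, depth = 40, clip_fraction = 0.4,
                                     seed = 8)
  path <- tempfile(fileext = ".sam")
  write_sam(reads, path, chrom_lengths = c(chr2 = 10000))
  aln <- read_alignments(path)
  expect_equal(nrow(aln), nrow(reads))
  expect_setequal(aln$qname, reads$qname)
  expect_equal(sort(aln$pos), sort(reads$pos))
})

test_that("simulated bioassay counts follow their binomial law", {
  rec <- generate_bioassay_counts(100, 0, n_treated = 50, n_control = 20,
                                  seed = 10)
  trt <- rec[rec$role == "treatment", ]
  expect_equal(sum(trt$n_dead), 50)
  expect_equal(sum(trt$n_exposed), 50)

  rec0 <- generate_bioassay_counts(0, 0, n_treated = 50, n_control = 20,
                                   seed = 11)
  s <- summarise_bioassay(rec0)
  expect_equal(s$observed_mortality, 0)
  expect_equal(s$classification, "confirmed_resistance")

  big <- generate_bioassay_counts(49.5, 0, n_treated = 10000,
                                  n_control = 100, seed = 12)
  m <- observed_mortality(big[big$role == "treatment", ])
  se <- 100 * sqrt(0.495 * 0.505 / 10000)
  expect_lt(abs(m - 49.5), 3 * se)
})
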