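mk_reads <- function(pos, cigar, mapq = 60, rname = "chr") {
  data.frame(qname = sprintf("r%03d", seq_along(pos)), rname = rname,
             pos = pos, mapq = mapq, cigar = cigar,
             stringsAsFactors = FALSE)
}

test_that("soft-clip proportion is a direct count over qualifying reads", {
  # 10 reads covering the breakpoint at 1000; 3 left-clipped exactly there
  reads <- mk_reads(
    pos = c(rep(1000, 3), seq(920, 980, by = 10)),
    cigar = c(rep("30S70M", 3), rep("100M", 7)))
  p <- softclip_proportion(reads, "chr", 1000, "left")
  expect_equal(p$n_reads, 10)
  expect_equal(p$n_clipped, 3)
  expect_equal(p$proportion, 0.30)
})

test_that("reads below the mapping-quality cutoff are excluded", {
  reads <- mk_reads(rep(1000, 5), rep("30S70M", 5), mapq = 5)
  p <- softclip_proportion(reads, "chr", 1000, "left")
  expect_true(p$no_coverage)
  expect_true(is.na(p$proportion))
  # MQ = 10 is inclusive
  reads$mapq <- 10
  expect_equal(softclip_proportion(reads, "chr", 1000, "left")$proportion, 1)
})

test_that("clip-boundary tolerance is exact by default", {
  reads <- mk_reads(c(1001, 950), c("30S70M", "100M"))
  p0 <- softclip_proportion(reads, "chr", 1000, "left", tolerance_bp = 0)
  expect_equal(p0$n_clipped, 0)
  p1 <- softclip_proportion(reads, "chr", 1000, "left", tolerance_bp = 1)
  expect_equal(p1$n_clipped, 1)
})

test_that("right-side clips are measured at the alignment end", {
  # 60M40S starting at 941 aligns 941..1000, clip boundary = 1001
  reads <- mk_reads(c(941, 920), c("60M40S", "100M"))
  p <- softclip_proportion(reads, "chr", 1001, "right")
  expect_equal(p$n_reads, 2)
  expect_equal(p$n_clipped, 1)
  # a left clip at the same coordinate is not right-side evidence
  reads2 <- mk_reads(1001, "40S60M")
  expect_equal(softclip_proportion(reads2, "chr", 1001,
                                   "right")$n_clipped, 0)
})

test_that("CNV calls apply the inclusive 19.5% threshold per side", {
  prof <- function(p) list(proportion = p, no_coverage = is.na(p))
  expect_equal(call_cnv(prof(0.30), prof(0.02))$call, "present")
  expect_equal(call_cnv(prof(0.30), prof(0.02))$evidence_side, "start")
  expect_equal(call_cnv(prof(0.10), prof(0.10))$call, "absent")
  expect_equal(call_cnv(prof(0.195), prof(0))$call, "present")
  expect_equal(call_cnv(prof(0.30), prof(0.30))$evidence_side, "both")
  expect_equal(call_cnv(prof(0.02), prof(0.30))$evidence_side, "end")
  expect_equal(call_cnv(prof(NA), prof(NA))$call, "no_coverage")
})

test_that("threshold calibration: midpoint when separated, Youden otherwise", {
  sep <- calibrate_threshold(c(0.05, 0.10, 0.15, 0.24, 0.30, 0.40),
                             c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(sep$threshold, 0.195)
  expect_true(sep$separated)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)

  props <- c(0.05, 0.22, 0.10, 0.18, 0.25, 0.12, 0.30, 0.16)
  status <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  ov <- calibrate_threshold(props, status)
  expect_false(ov$separated)
  # exhaustive sweep oracle over all candidate thresholds
  cand <- sort(unique(props))
  j <- vapply(cand, function(t)
    mean(props[status] >= t) + mean(props[!status] < t) - 1, numeric(1))
  expect_equal(ov$sensitivity + ov$specificity - 1, max(j))
  expect_lt(ov$sensitivity + ov$specificity - 1, 1)

  expect_error(calibrate_threshold(c(0.1, 0.2), c(TRUE, TRUE)), "both")
})

test_that("simulated clip fractions are recovered within binomial error", {
  cnv <- planted_feature("cnv", "chr", start = 10000, end = 14000,
                         clip_fraction = 0.3, carriers = "s", name = "dup")
  reads <- generate_breakpoint_reads(cnv, depth = 200, clip_fraction = 0.3,
                                     seed = 13)
  p <- softclip_proportion(reads, "chr", 10000, "left")
  se <- sqrt(0.3 * 0.7 / 200)
  expect_equal(p$n_reads, 200)
  expect_lt(abs(p$proportion - 0.3), 3 * se)
})

test_that("calls are invariant to read order", {
  cnv <- planted_feature("cnv", "chr", start = 5000, end = 7000,
                         clip_fraction = 0.4, carriers = "s", name = "dup")
  reads <- generate_breakpoint_reads(cnv, depth = 50, clip_fraction = 0.4,
                                     seed = 14)
  p1 <- softclip_proportion(reads, "chr", 5000, "left")
  set.seed(15)
  p2 <- softclip_proportion(reads[sample(nrow(reads)), ], "chr", 5000,
                            "left")
  expect_equal(p1$proportion, p2$proportion)
})

test_that("screen_cnv rejects breakpoints on unknown chromosomes", {
  reads <- mk_reads(1000, "100M")
  bp <- data.frame(name = "dup", chrom = "other", start = 100, end = 200)
  expect_error(screen_cnv(reads, bp), "other")
})
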