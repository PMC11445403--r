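test_that("Garud statistics match closed forms", {
  h <- haps_with_freqs(c(4, 3, 2, 1),
                       list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  g <- garud_h(h)
  expect_equal(g$H12, 0.7^2 + 0.2^2 + 0.1^2)     # 0.54
  expect_equal(g$H1, sum(c(0.4, 0.3, 0.2, 0.1)^2))
  expect_equal(g$H123, 0.9^2 + 0.1^2)
  expect_equal(g$H2_H1, (g$H1 - 0.4^2) / g$H1)

  same <- matrix(1, nrow = 8, ncol = 5)
  gs <- garud_h(same)
  expect_equal(gs$H1, 1)
  expect_equal(gs$H12, 1)

  # n distinct singletons: H12 = (2/n)^2 + (n-2)/n^2
  n <- 6
  singles <- diag(n)
  g1 <- garud_h(singles)
  expect_equal(g1$H12, (2 / n)^2 + (n - 2) / n^2)
})

test_that("Garud statistics are ordered, bounded and order-invariant", {
  set.seed(301)
  for (k in 1:20) {
    h <- matrix(stats::rbinom(12 * 6, 1, 0.5), nrow = 12)
    g <- garud_h(h)
    expect_gte(g$H12, g$H1)
    expect_gte(g$H123, g$H12)
    expect_true(all(unlist(g[c("H1", "H12", "H123")]) <= 1))
    expect_true(all(unlist(g[c("H1", "H12", "H123")]) >= 0))
    gp <- garud_h(h[sample(nrow(h)), ])
    expect_equal(gp$H12, g$H12)
  }
  expect_error(garud_h(matrix(1, 1, 3)), "two")
})

test_that("haplotypes with missing alleles are dropped before counting", {
  h <- rbind(c(1, 1), c(1, 1), c(1, NA), c(0, 0))
  g <- garud_h(h)
  expect_equal(g$n_haplotypes, 3)
  expect_equal(g$H1, (2 / 3)^2 + (1 / 3)^2)
})

test_that("degenerate scan (one iteration, full group) equals direct garud_h", {
  set.seed(302)
  cfg <- sim_config(n_resistant = 8, n_susceptible = 8, n_control = 0,
                    chromosomes = c(chr = 5000), n_sites = 100, seed = 41)
  sim <- generate_panel(cfg)
  scan <- h12_scan(sim$matrix, sim$panel, groups = "resistant",
                   window_snps = 100, n_iter = 1, subsample_size = 16,
                   seed = 42)
  direct <- garud_h(haplotypes(sim$matrix,
                               sim$panel$sample[sim$panel$phenotype ==
                                                  "resistant"]))
  expect_equal(scan$h12_mean, direct$H12)
  expect_equal(scan$h1_mean, direct$H1)
  expect_error(h12_scan(sim$matrix, sim$panel, groups = "resistant",
                        window_snps = 100, subsample_size = 17),
               "exceeds")
})

test_that("a planted sweep elevates mean H12 only inside the swept windows", {
  cfg <- sim_config(n_resistant = 23, n_susceptible = 0, n_control = 0,
                    chromosomes = c(chr = 40000), n_sites = 2000, seed = 51)
  feats <- list(planted_feature("sweep", "chr", start = 1, end = 22001,
                                core_freq = 0.8, name = "sw"))
  sim <- generate_panel(cfg, feats)
  scan <- h12_scan(sim$matrix, sim$panel, groups = "resistant",
                   window_snps = 1000, n_iter = 200, seed = 52)
  expect_equal(nrow(scan), 2)
  expect_gt(scan$h12_mean[1], 0.2)   # swept window
  expect_lt(scan$h12_mean[2], 0.2)   # unlinked null window
  expect_equal(scan$sweep, c(TRUE, FALSE))
  reg <- sweep_regions(scan)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_windows, 1)
})

test_that("exact-duplicate haplotypes cluster at distance zero", {
  set.seed(303)
  core <- matrix(rep(stats::rbinom(50, 1, 0.5), 25), nrow = 25,
                 byrow = TRUE)
  noise <- matrix(stats::rbinom(10 * 50, 1, 0.5), nrow = 10)
  cl <- cluster_haplotypes(rbind(core, noise), max_distance = 0,
                           min_cluster = 20)
  expect_equal(nrow(cl$clusters), 1)
  expect_gte(cl$clusters$size, 25)
})

test_that("all-distinct random haplotypes yield no tight cluster", {
  set.seed(304)
  h <- matrix(stats::rbinom(40 * 200, 1, 0.5), nrow = 40)
  cl <- cluster_haplotypes(h, max_distance = 0.01, min_cluster = 5)
  expect_null(cl$clusters)
})

test_that("two planted haplotype cores are recovered with their sizes", {
  set.seed(305)
  a <- stats::rbinom(100, 1, 0.5); b <- 1 - a
  h <- rbind(matrix(rep(a, 22), nrow = 22, byrow = TRUE),
             matrix(rep(b, 21), nrow = 21, byrow = TRUE))
  cl <- cluster_haplotypes(h, max_distance = 0.001, min_cluster = 20)
  expect_equal(sort(cl$clusters$size), c(21, 22))
})

test_that("cluster-phenotype association matches the exact hypergeometric tail", {
  # 20 of 46 resistant haplotypes in the cluster, 0 of 20 susceptible
  in_cl <- c(rep(TRUE, 20), rep(FALSE, 26), rep(FALSE, 20))
  phen <- rep(c("resistant", "susceptible"), c(46, 20))
  res <- cluster_phenotype_association(in_cl, phen)
  # two-sided Fisher p by enumeration over the hypergeometric support
  m <- 20; tot <- 66; n_res <- 46
  probs <- stats::dhyper(0:m, n_res, tot - n_res, m)
  p_exact <- sum(probs[probs <= stats::dhyper(20, n_res, tot - n_res, m) *
                         (1 + 1e-7)])
  expect_equal(res$p_value, p_exact, tolerance = 1e-10)
  expect_lt(res$p_value, 0.05)

  balanced <- cluster_phenotype_association(
    rep(c(TRUE, FALSE, TRUE, FALSE), each = 5),
    rep(c("resistant", "susceptible"), each = 10))
  expect_equal(balanced$p_value, 1)

  degenerate <- cluster_phenotype_association(
    rep(TRUE, 10), rep(c("resistant", "susceptible"), 5))
  expect_true(degenerate$undefined)
})

test_that("controls are excluded from the association test", {
  in_cl <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  phen <- c("resistant", "resistant", "susceptible", "susceptible",
            "control", "control")
  res <- cluster_phenotype_association(in_cl, phen)
  expect_equal(sum(res$table), 4)
})

test_that("gene-window overlap is half-open and matches brute force", {
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:10), chrom = "chr",
    start = c(50, 150, 250, 300, 999, 1000, 1500, 2000, 2600, 10),
    end = c(120, 220, 260, 420, 1200, 1400, 1600, 2400, 2800, 20),
    description = NA_character_)
  windows <- data.frame(chrom = "chr", start = c(1, 1001, 2001),
                        end = c(1001, 2001, 3001), fst = c(0.5, 0.1, 0.3))
  rep <- genes_in_windows(windows, genes, statistic = "fst")
  brute <- unlist(lapply(seq_len(nrow(genes)), function(i)
    if (any(genes$start[i] <= windows$end - 1 &
            genes$end[i] >= windows$start)) genes$gene_id[i]))
  expect_setequal(unique(rep$overlaps$gene_id), brute)
  # gene g05 spans the window-1/window-2 boundary: reported in both
  expect_equal(sum(rep$overlaps$gene_id == "g05"), 2)
  # abutting half-open end: a gene starting at end coordinate is excluded
  abut <- data.frame(gene_id = "ab", chrom = "chr", start = 1001,
                     end = 1100, description = NA)
  rep2 <- genes_in_windows(windows[1, ], abut, statistic = "fst")
  expect_null(rep2$overlaps)
  expect_error(genes_in_windows(
    data.frame(chrom = "zz", start = 1, end = 10, fst = 0), genes),
    "zz")
})
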