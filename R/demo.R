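#' Generate a study-shaped demonstration bundle
#'
#' Writes a complete synthetic input set with known ground truth into
#' `outdir`: a 23 resistant / 10 susceptible / 9 control panel as a phased
#' VCF; six candidate resistance SNPs planted at the frequencies of a
#' field survey (vgsc T791M, L995F, N1570Y, A1746S, P1874L; gste2 L119V)
#' with exact allele counts; one planted selective sweep (core-haplotype
#' frequency 0.8) on chromosome X; one strongly differentiated 1-kb window
#' (0.9 vs 0.1) on chromosome 2R among null windows; one CNV allele with
#' soft-clipped reads at its breakpoints in a single resistant carrier;
#' WHO tube-test counts; synthetic gene models; truth tables; and a ready
#' [run_config()] YAML.
#'
#' @param outdir Output directory (created).
#' @param seed Integer seed; the bundle is byte-identical under the same
#'   seed.
#' @return A list with the generated paths, the `run_config` and the
#'   ground `truth`, invisibly printable.
#' @export
make_demo <- function(outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reads_dir <- file.path(outdir, "reads")
  dir.create(reads_dir, showWarnings = FALSE)

  chroms <- c(`2L` = 2431500, `2R` = 500000, `3R` = 28599000, X = 60000)
  cfg <- sim_config(
    n_resistant = 23, n_susceptible = 10, n_control = 9,
    chromosomes = chroms,
    n_sites = c(`2L` = 1000, `2R` = 2500, `3R` = 500, X = 3000),
    seed = stage_seed(seed, "panel"))

  cand <- data.frame(
    gene = c("vgsc", "vgsc", "vgsc", "vgsc", "vgsc", "gste2"),
    chrom = c("2L", "2L", "2L", "2L", "2L", "3R"),
    pos = c(2416980L, 2422652L, 2429745L, 2430424L, 2430881L, 28598062L),
    label = c("T791M", "L995F", "N1570Y", "A1746S", "P1874L", "L119V"),
    stringsAsFactors = FALSE)
  cand_freq <- list(
    T791M = c(resistant = 0, susceptible = 0.056, control = 0.056),
    L995F = c(resistant = 0.159, susceptible = 0.15, control = 0.167),
    N1570Y = c(resistant = 0.109, susceptible = 0, control = 0.063),
    A1746S = c(resistant = 0, susceptible = 0.05, control = 0.063),
    P1874L = c(resistant = 0.043, susceptible = 0.10, control = 0.063),
    L119V = c(resistant = 0.068, susceptible = 0, control = 0))

  features <- lapply(seq_len(nrow(cand)), function(k)
    planted_feature("candidate_snp", cand$chrom[k], pos = cand$pos[k],
                    freq = cand_freq[[cand$label[k]]], exact = TRUE,
                    name = cand$label[k]))
  features <- c(features, list(
    planted_feature("diff_window", "2R", start = 250001L, end = 251001L,
                    freq = c(resistant = 0.9, susceptible = 0.1,
                             control = 0.5),
                    name = "diff_2R_250k"),
    planted_feature("sweep", "X", start = 15001L, end = 45001L,
                    core_freq = 0.8, name = "sweep_X"),
    planted_feature("cnv", "2R", start = 350000L, end = 353000L,
                    carriers = "res01", clip_fraction = 0.4,
                    name = "Cyp6aap_Dup7_syn")))

  sim <- generate_panel(cfg, features)
  gm <- sim$matrix

  vcf_path <- file.path(outdir, "panel.vcf")
  write_vcf(gm, vcf_path, contig_lengths = chroms)

  phen_path <- file.path(outdir, "phenotypes.tsv")
  utils::write.table(sim$panel, phen_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cand$ref <- gm$ref[mapply(function(ch, p) site_index(gm, ch, p),
                            cand$chrom, cand$pos)]
  cand$alt <- gm$alt[mapply(function(ch, p) site_index(gm, ch, p),
                            cand$chrom, cand$pos)]
  cand_path <- file.path(outdir, "candidates.tsv")
  utils::write.table(cand[, c("gene", "chrom", "pos", "ref", "alt",
                              "label")],
                     cand_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  bp_path <- file.path(outdir, "breakpoints.tsv")
  utils::write.table(
    data.frame(name = "Cyp6aap_Dup7_syn", chrom = "2R", start = 350000L,
               end = 353000L),
    bp_path, sep = "\t", quote = FALSE, row.names = FALSE)

  cnv_feat <- features[[length(features)]]
  sam_samples <- c(res01 = 0.4, res02 = 0.02, sus01 = 0.02, con01 = 0.02)
  for (smp in names(sam_samples)) {
    reads <- generate_breakpoint_reads(
      cnv_feat, depth = 60, clip_fraction = sam_samples[[smp]],
      read_len = 100, seed = stage_seed(seed, paste0("reads_", smp)),
      sample = smp)
    write_sam(reads, file.path(reads_dir, paste0(smp, ".sam")),
              chrom_lengths = chroms)
  }

  # WHO tube-test counts: discriminating dose over 5 replicate tubes,
  # intensity dose over 3, each with its own oil-exposed control
  bio <- rbind(
    data.frame(test = "discriminating", role = "treatment",
               replicate = 1:5, n_exposed = c(20, 20, 20, 20, 21),
               n_dead = c(10, 10, 10, 10, 10)),
    data.frame(test = "discriminating", role = "control", replicate = 1,
               n_exposed = 66, n_dead = 5),
    data.frame(test = "intensity_5x", role = "treatment", replicate = 1:3,
               n_exposed = c(15, 15, 15), n_dead = c(14, 14, 14)),
    data.frame(test = "intensity_5x", role = "control", replicate = 1,
               n_exposed = 37, n_dead = 4))
  bio_path <- file.path(outdir, "bioassay.tsv")
  utils::write.table(bio, bio_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  genes <- data.frame(
    gene_id = c("AGAP_SYN_VGSC", "AGAP_SYN_GSTE2", "AGAP_SYN_CYP9K1",
                "AGAP_SYN_XOFF", "AGAP_SYN_2R_IN", "AGAP_SYN_2R_OFF"),
    chrom = c("2L", "3R", "X", "X", "2R", "2R"),
    start = c(2416000L, 28597000L, 25000L, 50000L, 250200L, 100000L),
    end = c(2431400L, 28599000L, 27000L, 52000L, 250800L, 101000L),
    description = c("voltage-gated sodium channel (synthetic model)",
                    "glutathione S-transferase epsilon 2 (synthetic model)",
                    "cytochrome P450, sweep-region (synthetic model)",
                    "off-sweep control gene (synthetic model)",
                    "differentiated-window gene (synthetic model)",
                    "null-window control gene (synthetic model)"),
    stringsAsFactors = FALSE)
  gff_path <- file.path(outdir, "genes.gff3")
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               type = "gene", ID = genes$gene_id,
                               description = genes$description)
  rtracklayer::export(gr, gff_path, format = "gff3")

  if (!is.null(sim$truth$features))
    utils::write.table(sim$truth$features,
                       file.path(outdir, "truth_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  sweep_df <- do.call(rbind, lapply(names(sim$truth$sweeps), function(nm) {
    s <- sim$truth$sweeps[[nm]]
    data.frame(feature = nm, chrom = s$chrom, start = s$start, end = s$end,
               n_core_haplotypes = length(s$core_haplotypes),
               realised_core_freq = s$realised_core_freq)
  }))
  if (!is.null(sweep_df))
    utils::write.table(sweep_df, file.path(outdir, "truth_sweeps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  config <- run_config(
    vcf = vcf_path, phenotype_tsv = phen_path, candidate_tsv = cand_path,
    breakpoint_tsv = bp_path, bioassay_tsv = bio_path, gff = gff_path,
    reads_dir = reads_dir, outdir = file.path(outdir, "results"),
    seed = seed,
    params = list(bioassay_tiers = c(discriminating = "discriminating",
                                     intensity_5x = "intensity_5x")))
  yaml::write_yaml(
    list(vcf = basename(vcf_path), phenotype_tsv = basename(phen_path),
         candidate_tsv = basename(cand_path),
         breakpoint_tsv = basename(bp_path),
         bioassay_tsv = basename(bio_path), gff = basename(gff_path),
         reads_dir = "reads", outdir = file.path(outdir, "results"),
         seed = seed,
         params = list(bioassay_tiers = list(
           discriminating = "discriminating",
           intensity_5x = "intensity_5x"))),
    file.path(outdir, "config.yaml"))

  invisible(list(config = config,
                 config_yaml = file.path(outdir, "config.yaml"),
                 truth = sim$truth, panel = sim$panel, matrix = gm,
                 paths = list(vcf = vcf_path, phenotypes = phen_path,
                              candidates = cand_path, breakpoints = bp_path,
                              bioassay = bio_path, gff = gff_path,
                              reads_dir = reads_dir)))
}
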