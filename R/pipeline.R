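write_stage_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble and validate a pipeline run configuration
#'
#' @param vcf Phased biallelic VCF path.
#' @param phenotype_tsv TSV with columns `sample`, `phenotype`.
#' @param candidate_tsv Candidate-SNP table ([read_candidate_tsv()]).
#' @param breakpoint_tsv CNV breakpoint table ([read_breakpoint_tsv()]).
#' @param bioassay_tsv Tube-test counts ([read_bioassay_tsv()]).
#' @param gff Gene-model GFF3.
#' @param reads_dir Directory of per-sample `.sam`/`.bam` files for the CNV
#'   screen.
#' @param outdir Output directory (created).
#' @param seed Base seed; each stochastic stage derives its own stream via
#'   [stage_seed()].
#' @param stages Character vector of stages to run, in dependency order.
#' @param params Named list overriding stage parameters: `window_bp`,
#'   `n_perm`, `centile`, `noise_multiplier`, `window_snps`, `n_iter`,
#'   `subsample_size`, `sweep_threshold`, `max_distance`, `min_cluster`,
#'   `cnv_threshold`, `mapq_min`, `tolerance_bp`, `bioassay_tiers`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(vcf, phenotype_tsv, candidate_tsv = NULL,
                       breakpoint_tsv = NULL, bioassay_tsv = NULL,
                       gff = NULL, reads_dir = NULL, outdir = "vectorsweep_out",
                       seed = 1,
                       stages = c("qc", "screen", "ld", "fst", "h12",
                                  "clusters", "cnv", "bioassay"),
                       params = list()) {
  defaults <- list(window_bp = 1000, n_perm = 200, centile = 99,
                   noise_multiplier = 3, window_snps = 1000, n_iter = 200,
                   subsample_size = NULL, sweep_threshold = 0.2,
                   max_distance = 0.001, min_cluster = 20,
                   cnv_threshold = 0.195, mapq_min = 10, tolerance_bp = 0,
                   bioassay_tiers = "discriminating")
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  defaults[names(params)] <- params
  paths <- list(vcf = vcf, phenotype_tsv = phenotype_tsv,
                candidate_tsv = candidate_tsv,
                breakpoint_tsv = breakpoint_tsv,
                bioassay_tsv = bioassay_tsv, gff = gff,
                reads_dir = reads_dir)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input `%s` does not exist: %s", nm, p), call. = FALSE)
  }
  structure(c(paths, list(outdir = outdir, seed = as.integer(seed),
                          stages = stages, params = defaults)),
            class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file with the [run_config()] fields; relative input
#'   paths are resolved against the YAML file's directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || file.exists(p)) p else
    file.path(base, p)
  run_config(vcf = rel(y$vcf), phenotype_tsv = rel(y$phenotype_tsv),
             candidate_tsv = rel(y$candidate_tsv),
             breakpoint_tsv = rel(y$breakpoint_tsv),
             bioassay_tsv = rel(y$bioassay_tsv), gff = rel(y$gff),
             reads_dir = rel(y$reads_dir),
             outdir = y$outdir %||% "vectorsweep_out",
             seed = y$seed %||% 1,
             stages = y$stages %||% c("qc", "screen", "ld", "fst", "h12",
                                      "clusters", "cnv", "bioassay"),
             params = y$params %||% list())
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the enabled stages in dependency order (qc, screen, ld, fst,
#' h12, clusters, cnv, bioassay), writing one TSV per stage into the output
#' directory (genomic outputs carry a coordinate-convention header comment)
#' and returning the per-stage summary tables. A stage failure halts the
#' run with a stage-named error. Stochastic stages derive independent
#' seeds from the base seed, so the run is reproducible and stages can be
#' toggled without shifting each other's random streams.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: per-stage results plus a
#'   provenance block (package version, seed, parameters, input checksums).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  params <- config$params
  coord_note <- "coordinates: 1-based bp, windows half-open [start, end)"

  phen <- utils::read.delim(config$phenotype_tsv, stringsAsFactors = FALSE)
  panel <- phenotyped_panel(phen$sample, phen$phenotype)

  vcf <- run_stage("qc", read_vcf(config$vcf))
  missing_phen <- setdiff(vcf$matrix$samples, panel$sample)
  if (length(missing_phen))
    stop("no phenotype for VCF sample(s): ",
         paste(missing_phen, collapse = ", "), call. = FALSE)

  gm <- vcf$matrix
  if ("qc" %in% config$stages) {
    qc <- run_stage("qc", apply_variant_qc(vcf))
    write_stage_tsv(qc$site_report,
                    file.path(config$outdir, "qc_site_report.tsv"),
                    coord_note)
    gm <- qc$matrix
    report$qc <- qc
  }

  candidates <- NULL
  if (!is.null(config$candidate_tsv))
    candidates <- read_candidate_tsv(config$candidate_tsv)

  if ("screen" %in% config$stages && !is.null(candidates)) {
    scr <- run_stage("screen", screen_candidates(gm, panel, candidates))
    if (!is.null(scr$frequencies))
      write_stage_tsv(scr$frequencies,
                      file.path(config$outdir, "screen_frequencies.tsv"),
                      coord_note)
    if (!is.null(scr$snps))
      write_stage_tsv(scr$snps, file.path(config$outdir, "screen_snps.tsv"),
                      coord_note)
    report$screen <- scr
  }

  if ("ld" %in% config$stages && !is.null(candidates)) {
    ld <- run_stage("ld", {
      found <- !is.na(mapply(function(ch, p) site_index(gm, ch, p),
                             candidates$chrom, candidates$pos))
      if (sum(found) >= 2)
        pairwise_r2(gm, candidates[found, , drop = FALSE]) else NULL
    })
    if (!is.null(ld))
      write_stage_tsv(ld_long(ld), file.path(config$outdir, "ld_pairs.tsv"),
                      coord_note)
    report$ld <- ld
  }

  if ("fst" %in% config$stages) {
    fst <- run_stage("fst", fst_permutation_significance(
      gm, panel, window_bp = params$window_bp, n_perm = params$n_perm,
      centile = params$centile, noise_multiplier = params$noise_multiplier,
      seed = stage_seed(config$seed, "fst")))
    write_stage_tsv(fst, file.path(config$outdir, "fst_windows.tsv"),
                    coord_note)
    report$fst <- fst
  }

  if ("h12" %in% config$stages) {
    h12 <- run_stage("h12", h12_scan(
      gm, panel, window_snps = params$window_snps, n_iter = params$n_iter,
      subsample_size = params$subsample_size,
      sweep_threshold = params$sweep_threshold,
      seed = stage_seed(config$seed, "h12")))
    write_stage_tsv(h12, file.path(config$outdir, "h12_windows.tsv"),
                    coord_note)
    report$h12 <- h12
    report$sweeps <- sweep_regions(h12)
    if (!is.null(config$gff)) {
      genes <- run_stage("h12", read_gene_intervals(config$gff))
      swp <- h12[h12$sweep, , drop = FALSE]
      if (nrow(swp)) {
        gr <- run_stage("h12", genes_in_windows(swp, genes, "h12_mean"))
        if (!is.null(gr$overlaps))
          write_stage_tsv(gr$overlaps,
                          file.path(config$outdir, "h12_genes.tsv"),
                          coord_note)
        report$h12_genes <- gr
      }
    }
  }

  if ("clusters" %in% config$stages) {
    wins <- NULL
    if (!is.null(report$fst)) wins <- report$fst[report$fst$flagged, ]
    if (!is.null(report$sweeps) && nrow(report$sweeps))
      wins <- rbind(wins[, c("chrom", "start", "end")],
                    report$sweeps[, c("chrom", "start", "end")])
    else if (!is.null(wins)) wins <- wins[, c("chrom", "start", "end")]
    cl <- run_stage("clusters", if (!is.null(wins) && nrow(wins))
      cluster_windows(gm, panel, wins, params$max_distance,
                      params$min_cluster) else NULL)
    if (!is.null(cl))
      write_stage_tsv(cl, file.path(config$outdir, "haplotype_clusters.tsv"),
                      coord_note)
    report$clusters <- cl
  }

  if ("cnv" %in% config$stages && !is.null(config$breakpoint_tsv) &&
      !is.null(config$reads_dir)) {
    cnv <- run_stage("cnv", {
      bp <- read_breakpoint_tsv(config$breakpoint_tsv)
      files <- list.files(config$reads_dir, pattern = "\\.(sam|bam)$",
                          full.names = TRUE)
      calls <- lapply(files, function(f) {
        reads <- read_alignments(f)
        sc <- screen_cnv(reads, bp, params$cnv_threshold, params$mapq_min,
                         params$tolerance_bp)
        cbind(sample = sub("\\.(sam|bam)$", "", basename(f)), sc)
      })
      do.call(rbind, calls)
    })
    write_stage_tsv(cnv, file.path(config$outdir, "cnv_calls.tsv"),
                    coord_note)
    report$cnv <- cnv
  }

  if ("bioassay" %in% config$stages && !is.null(config$bioassay_tsv)) {
    ba <- run_stage("bioassay", summarise_bioassay(
      read_bioassay_tsv(config$bioassay_tsv), params$bioassay_tiers))
    write_stage_tsv(ba, file.path(config$outdir, "bioassay_summary.tsv"))
    report$bioassay <- ba
  }

  inputs <- Filter(Negate(is.null),
                   config[c("vcf", "phenotype_tsv", "candidate_tsv",
                            "breakpoint_tsv", "bioassay_tsv", "gff")])
  report$provenance <- list(
    package = "vectorsweep",
    version = as.character(utils::packageVersion("vectorsweep")),
    seed = config$seed, stages = config$stages, params = params,
    input_md5 = vapply(inputs, function(p) unname(tools::md5sum(p)),
                       character(1)))
  jsonlite::write_json(report$provenance,
                       file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  stages <- setdiff(names(x), "provenance")
  cat(sprintf("vectorsweep run report (seed %d): %d stage outputs\n",
              x$provenance$seed, length(stages)))
  cat("  stages:", paste(stages, collapse = ", "), "\n")
  if (!is.null(x$bioassay)) print(x$bioassay)
  if (!is.null(x$fst))
    cat(sprintf("  FST: %d/%d windows flagged\n", sum(x$fst$flagged),
                nrow(x$fst)))
  if (!is.null(x$h12))
    cat(sprintf("  H12: %d/%d window entries above threshold\n",
                sum(x$h12$sweep), nrow(x$h12)))
  if (!is.null(x$cnv))
    cat(sprintf("  CNV: %d present call(s)\n", sum(x$cnv$call == "present")))
  invisible(x)
}
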