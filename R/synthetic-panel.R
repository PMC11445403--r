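#' Configuration for the synthetic phenotyped panel
#'
#' Defines the study design the generator emulates: two phenotype groups of
#' diploid phased genotypes plus unphenotyped controls, one or more
#' chromosomes, and a background site-frequency law. Defaults mirror a
#' field study panel of 23 resistant, 10 susceptible and 9 control
#' mosquitoes.
#'
#' @param n_resistant,n_susceptible,n_control Group sizes (diploid samples).
#' @param chromosomes Named integer vector: chromosome lengths in bp.
#' @param n_sites Sites per chromosome; either a single count recycled over
#'   chromosomes or a named vector.
#' @param freq_range Background alternate-allele frequencies are drawn
#'   uniformly from this interval (low frequencies dominate real folded
#'   spectra; the default keeps all background sites polymorphic).
#' @param missing_rate Probability that a diploid genotype call is missing.
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_resistant = 23, n_susceptible = 10, n_control = 9,
                       chromosomes = c(`2L` = 1e5), n_sites = 1000,
                       freq_range = c(0.05, 0.5), missing_rate = 0,
                       seed = 1) {
  stopifnot(n_resistant >= 0, n_susceptible >= 0, n_control >= 0,
            all(chromosomes >= 1), length(freq_range) == 2,
            freq_range[1] >= 0, freq_range[2] <= 1,
            freq_range[1] <= freq_range[2],
            missing_rate >= 0, missing_rate <= 1)
  if (is.null(names(chromosomes)))
    stop("`chromosomes` must be a named vector of lengths", call. = FALSE)
  if (length(n_sites) == 1L)
    n_sites <- stats::setNames(rep(n_sites, length(chromosomes)),
                               names(chromosomes))
  if (any(n_sites > chromosomes[names(n_sites)]))
    stop("more sites requested than positions available", call. = FALSE)
  structure(list(n_resistant = as.integer(n_resistant),
                 n_susceptible = as.integer(n_susceptible),
                 n_control = as.integer(n_control),
                 chromosomes = chromosomes, n_sites = n_sites,
                 freq_range = freq_range, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Declare a feature to plant in the synthetic panel
#'
#' @param kind One of `"candidate_snp"`, `"sweep"`, `"diff_window"`, `"cnv"`.
#' @param chrom Chromosome name.
#' @param pos 1-based position (candidate_snp only).
#' @param start,end 1-based half-open interval `[start, end)` (sweep,
#'   diff_window, and the two CNV breakpoints).
#' @param freq Planted alternate-allele frequency: a single value, or a named
#'   vector over phenotype groups (candidate_snp, diff_window).
#' @param exact If `TRUE`, plant exactly `round(freq * n_alleles)` alternate
#'   alleles per group instead of Bernoulli sampling (deterministic truth).
#' @param core_freq Core-haplotype frequency in `[0, 1]` (sweep).
#' @param groups Phenotype groups carrying the feature (default all three).
#' @param carriers Character vector of carrier sample ids (cnv).
#' @param clip_fraction Proportion of reads soft-clipped at the breakpoints
#'   in carriers (cnv).
#' @param name Feature label used in the truth table.
#' @return A list of class `planted_feature`.
#' @export
planted_feature <- function(kind, chrom, pos = NULL, start = NULL, end = NULL,
                            freq = NULL, exact = FALSE, core_freq = NULL,
                            groups = c("resistant", "susceptible", "control"),
                            carriers = NULL, clip_fraction = NULL,
                            name = NULL) {
  kind <- match.arg(kind, c("candidate_snp", "sweep", "diff_window", "cnv"))
  if (kind == "candidate_snp") {
    stopifnot(!is.null(pos), pos >= 1, !is.null(freq),
              all(freq >= 0), all(freq <= 1))
  } else {
    stopifnot(!is.null(start), !is.null(end))
    if (start >= end) stop("interval must satisfy start < end", call. = FALSE)
  }
  if (kind == "sweep")
    stopifnot(!is.null(core_freq), core_freq >= 0, core_freq <= 1)
  if (kind == "diff_window")
    stopifnot(!is.null(freq), all(freq >= 0), all(freq <= 1))
  if (kind == "cnv")
    stopifnot(!is.null(clip_fraction), clip_fraction >= 0, clip_fraction <= 1)
  structure(list(kind = kind, chrom = chrom, pos = pos, start = start,
                 end = end, freq = freq, exact = isTRUE(exact),
                 core_freq = core_freq, groups = groups, carriers = carriers,
                 clip_fraction = clip_fraction,
                 name = name %||% sprintf("%s_%s", kind, chrom)),
            class = "planted_feature")
}

expand_group_freq <- function(freq) {
  groups <- c("resistant", "susceptible", "control")
  if (is.null(names(freq))) return(stats::setNames(rep(freq[1], 3), groups))
  out <- stats::setNames(rep(NA_real_, 3), groups)
  out[names(freq)] <- freq
  if (anyNA(out)) stop("`freq` must name all groups or be unnamed",
                       call. = FALSE)
  out
}

check_feature_bounds <- function(f, chromosomes) {
  if (!f$chrom %in% names(chromosomes))
    stop(sprintf("feature '%s': unknown chromosome '%s'", f$name, f$chrom),
         call. = FALSE)
  len <- chromosomes[[f$chrom]]
  if (f$kind == "candidate_snp") {
    if (f$pos > len)
      stop(sprintf("feature '%s': position %d outside %s (length %d)",
                   f$name, f$pos, f$chrom, len), call. = FALSE)
  } else if (f$end > len + 1L) {
    stop(sprintf("feature '%s': interval [%d,%d) outside %s (length %d)",
                 f$name, f$start, f$end, f$chrom, len), call. = FALSE)
  }
  invisible(TRUE)
}

plant_exact_counts <- function(hap, rows, group_idx, freqs) {
  # hap: sites x haplotypes 0/1 matrix; assigns exactly round(f * n_hap)
  # alternate alleles per group at each row, positions randomised
  for (g in names(group_idx)) {
    cols <- group_idx[[g]]
    if (length(cols) == 0L) next
    k <- as.integer(round(freqs[[g]] * length(cols)))
    for (r in rows) {
      hap[r, cols] <- 0L
      if (k > 0L) hap[r, sample(cols, k)] <- 1L
    }
  }
  hap
}

#' Generate a phenotyped synthetic genotype panel with planted features
#'
#' Background sites are unlinked: each haplotype allele is an independent
#' Bernoulli draw from the site's background frequency. Planted features
#' overwrite the background: candidate SNPs and differentiated windows use
#' group-specific frequencies; a sweep stores one core haplotype over its
#' interval and copies it onto a Bernoulli(`core_freq`)-selected subset of
#' haplotypes. The returned truth records the realised per-group alternate
#' counts for every planted feature, sweep core membership and CNV carriers.
#'
#' @param config A [sim_config()].
#' @param features List of [planted_feature()] objects.
#' @return A list of class `synthetic_panel` with elements `panel`
#'   ([phenotyped_panel()]), `matrix` ([genotype_matrix()]) and `truth`.
#' @export
generate_panel <- function(config, features = list()) {
  stopifnot(inherits(config, "sim_config"))
  for (f in features) check_feature_bounds(f, config$chromosomes)
  sw <- features[vapply(features, function(f)
    f$kind %in% c("sweep", "diff_window"), logical(1))]
  if (length(sw) > 1L) {
    for (i in seq_len(length(sw) - 1L)) for (j in seq(i + 1L, length(sw))) {
      a <- sw[[i]]; b <- sw[[j]]
      if (a$chrom == b$chrom && a$start < b$end && b$start < a$end)
        stop(sprintf("features '%s' and '%s' overlap", a$name, b$name),
             call. = FALSE)
    }
  }

  set.seed(config$seed)
  samples <- c(sprintf("res%02d", seq_len(config$n_resistant)),
               sprintf("sus%02d", seq_len(config$n_susceptible)),
               sprintf("con%02d", seq_len(config$n_control)))
  phen <- rep(c("resistant", "susceptible", "control"),
              c(config$n_resistant, config$n_susceptible, config$n_control))
  panel <- phenotyped_panel(samples, phen)
  n_smp <- length(samples)
  n_hap <- 2L * n_smp
  hap_group <- rep(phen, each = 2L)
  group_idx <- lapply(stats::setNames(nm = c("resistant", "susceptible",
                                             "control")),
                      function(g) which(hap_group == g))

  chrom_v <- character(0); pos_v <- integer(0)
  hap_all <- NULL
  truth_rows <- list()
  sweep_truth <- list()

  for (ch in names(config$chromosomes)) {
    len <- config$chromosomes[[ch]]
    ns <- config$n_sites[[ch]]
    pos <- sort(sample.int(len, ns))
    # force candidate-SNP positions into the site list
    for (f in features) {
      if (f$kind == "candidate_snp" && f$chrom == ch && !(f$pos %in% pos))
        pos <- sort(unique(c(pos, as.integer(f$pos))))
    }
    ns <- length(pos)
    f_bg <- stats::runif(ns, config$freq_range[1], config$freq_range[2])
    hap <- matrix(stats::rbinom(ns * n_hap, 1L, rep(f_bg, n_hap)),
                  nrow = ns, ncol = n_hap)

    for (f in features) {
      if (f$chrom != ch) next
      if (f$kind == "candidate_snp") {
        r <- which(pos == f$pos)
        freqs <- expand_group_freq(f$freq)
        if (f$exact) {
          hap <- plant_exact_counts(hap, r, group_idx, freqs)
        } else {
          for (g in names(group_idx)) {
            cols <- group_idx[[g]]
            if (length(cols))
              hap[r, cols] <- stats::rbinom(length(cols), 1L, freqs[[g]])
          }
        }
        cnt <- vapply(group_idx, function(cols)
          sum(hap[r, cols]), integer(1))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          feature = f$name, kind = f$kind, chrom = ch, pos = f$pos,
          group = names(cnt), alt_count = unname(cnt),
          n_alleles = lengths(group_idx)[names(cnt)],
          stringsAsFactors = FALSE)
      } else if (f$kind == "diff_window") {
        rows <- which(pos >= f$start & pos < f$end)
        freqs <- expand_group_freq(f$freq)
        for (g in names(group_idx)) {
          cols <- group_idx[[g]]
          if (length(cols) && length(rows))
            hap[rows, cols] <- stats::rbinom(
              length(rows) * length(cols), 1L, freqs[[g]])
        }
        cnt <- vapply(group_idx, function(cols)
          sum(hap[rows, cols, drop = FALSE]), integer(1))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          feature = f$name, kind = f$kind, chrom = ch, pos = f$start,
          group = names(cnt), alt_count = unname(cnt),
          n_alleles = lengths(group_idx)[names(cnt)] * length(rows),
          stringsAsFactors = FALSE)
      } else if (f$kind == "sweep") {
        rows <- which(pos >= f$start & pos < f$end)
        if (length(rows)) {
          core <- stats::rbinom(length(rows), 1L, f_bg[rows])
          hcols <- which(hap_group %in% f$groups)
          carrier <- hcols[stats::runif(length(hcols)) < f$core_freq]
          hap[rows, carrier] <- core
          sweep_truth[[f$name]] <- list(
            chrom = ch, start = f$start, end = f$end,
            core = core, core_haplotypes = carrier,
            realised_core_freq = length(carrier) / length(hcols))
        }
      }
    }

    chrom_v <- c(chrom_v, rep(ch, ns))
    pos_v <- c(pos_v, pos)
    hap_all <- rbind(hap_all, hap)
  }

  n_tot <- length(pos_v)
  geno <- array(NA_integer_, dim = c(n_tot, n_smp, 2L))
  geno[, , 1] <- hap_all[, seq(1L, n_hap, by = 2L)]
  geno[, , 2] <- hap_all[, seq(2L, n_hap, by = 2L)]
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n_tot * n_smp) < config$missing_rate,
                   nrow = n_tot)
    geno[, , 1][mask] <- NA_integer_
    geno[, , 2][mask] <- NA_integer_
  }
  ref <- sample(c("A", "C", "G", "T"), n_tot, replace = TRUE)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
    USE.NAMES = FALSE)
  gm <- genotype_matrix(chrom_v, pos_v, ref, alt, geno, samples)

  cnvs <- features[vapply(features, function(f) f$kind == "cnv", logical(1))]
  truth <- list(
    features = if (length(truth_rows)) do.call(rbind, truth_rows) else NULL,
    sweeps = sweep_truth,
    cnv_carriers = stats::setNames(
      lapply(cnvs, function(f) f$carriers),
      vapply(cnvs, function(f) f$name, character(1))))
  structure(list(panel = panel, matrix = gm, truth = truth,
                 config = config, features = features),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("synthetic_panel\n")
  cat(sprintf("  samples: %d resistant, %d susceptible, %d control\n",
              x$config$n_resistant, x$config$n_susceptible,
              x$config$n_control))
  print(x$matrix)
  cat(sprintf("  planted features: %d\n", length(x$features)))
  invisible(x)
}

#' Simulate WHO tube-test replicate counts
#'
#' Deaths are binomial at the stated true mortalities, split over replicates
#' as evenly as the totals allow (the WHO design exposes ~20-25 mosquitoes
#' per tube).
#'
#' @param true_mortality True treatment mortality, percent.
#' @param control_mortality True control mortality, percent.
#' @param n_treated,n_control Total mosquitoes exposed.
#' @param n_replicates Number of treatment tubes (controls use one tube).
#' @param seed Integer seed.
#' @return A `data.frame` of tube-test records with columns `test`, `role`,
#'   `replicate`, `n_exposed`, `n_dead`, suitable for [summarise_bioassay()].
#' @export
generate_bioassay_counts <- function(true_mortality, control_mortality,
                                     n_treated, n_control,
                                     n_replicates = 5, seed = 1) {
  assert_scalar_percent(true_mortality, "true_mortality")
  assert_scalar_percent(control_mortality, "control_mortality")
  stopifnot(n_treated > 0, n_control > 0, n_replicates >= 1)
  set.seed(seed)
  per <- diff(round(seq(0, n_treated, length.out = n_replicates + 1)))
  dead <- stats::rbinom(n_replicates, per, true_mortality / 100)
  ctrl_dead <- stats::rbinom(1L, n_control, control_mortality / 100)
  rbind(
    data.frame(test = "assay", role = "treatment",
               replicate = seq_len(n_replicates),
               n_exposed = per, n_dead = dead, stringsAsFactors = FALSE),
    data.frame(test = "assay", role = "control", replicate = 1L,
               n_exposed = n_control, n_dead = ctrl_dead,
               stringsAsFactors = FALSE))
}
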