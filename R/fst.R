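# Per-site Hudson FST components (Hudson's estimator as popularised for
# two-population windowed scans). With sample allele frequencies p1, p2 and
# allele-call counts n1, n2:
#   numerator   = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)
#   denominator = p1(1-p2) + p2(1-p1)
# Windowed FST is the ratio of summed numerators to summed denominators
# (ratio-of-sums, not mean-of-ratios). Sites with < 2 alleles called in
# either group contribute nothing.
hudson_components <- function(ac1, n1, ac2, n2) {
  ok <- n1 >= 2 & n2 >= 2
  p1 <- ifelse(ok, ac1 / n1, NA_real_)
  p2 <- ifelse(ok, ac2 / n2, NA_real_)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = ifelse(ok, num, 0), den = ifelse(ok, den, 0), informative = ok)
}

group_allele_counts <- function(d, idx) {
  sub <- d[, idx, drop = FALSE]
  list(ac = rowSums(sub, na.rm = TRUE),
       n = 2L * rowSums(!is.na(sub)))
}

window_id <- function(pos, window_bp) (pos - 1L) %/% window_bp

# core used by both the user-facing scan and the permutation loop
windowed_fst_core <- function(d, chrom, pos, idx_a, idx_b, window_bp) {
  ga <- group_allele_counts(d, idx_a)
  gb <- group_allele_counts(d, idx_b)
  comp <- hudson_components(ga$ac, ga$n, gb$ac, gb$n)
  key <- paste0(chrom, ":", window_id(pos, window_bp))
  num <- tapply(comp$num, key, sum)
  den <- tapply(comp$den, key, sum)
  nv <- tapply(rep(1L, length(pos)), key, sum)
  ord <- order(names(num))
  list(key = names(num)[ord],
       fst = ifelse(den[ord] > 0, num[ord] / den[ord], NA_real_),
       n_variants = as.integer(nv[ord]))
}

#' Windowed Hudson FST between two phenotype groups
#'
#' FST measures allele-frequency differentiation between the two groups.
#' Computed per non-overlapping window of fixed bp width as the ratio of
#' summed per-site Hudson numerators to summed denominators; windows with
#' no variants are omitted, and negative window values (sampling noise
#' around zero differentiation) are retained.
#'
#' @param gm A [genotype_matrix()].
#' @param panel A [phenotyped_panel()].
#' @param groups Character vector of two phenotype groups (default
#'   resistant vs susceptible).
#' @param window_bp Window width in bp (default 1000).
#' @return A `data.frame` of class `fst_windows`: `chrom`, `start`, `end`
#'   (1-based, half-open), `n_variants`, `fst`.
#' @export
windowed_fst <- function(gm, panel, groups = c("resistant", "susceptible"),
                         window_bp = 1000) {
  stopifnot(length(groups) == 2)
  idx_a <- match(panel_samples(panel, groups[1]), gm$samples)
  idx_b <- match(panel_samples(panel, groups[2]), gm$samples)
  if (length(idx_a) < 2 || length(idx_b) < 2 || anyNA(idx_a) || anyNA(idx_b))
    stop("both groups need >= 2 samples present in the matrix",
         call. = FALSE)
  d <- dosage(gm)
  core <- windowed_fst_core(d, gm$chrom, gm$pos, idx_a, idx_b, window_bp)
  parts <- strsplit(core$key, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1)
  wid <- as.integer(vapply(parts, `[`, character(1), 2))
  out <- data.frame(chrom = chrom, start = wid * window_bp + 1L,
                    end = (wid + 1L) * window_bp + 1L,
                    n_variants = core$n_variants, fst = unname(core$fst),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, unique(gm$chrom)), out$start), ]
  rownames(out) <- NULL
  class(out) <- c("fst_windows", "data.frame")
  out
}

#' Permutation significance for windowed FST peaks
#'
#' FST peaks can arise from locally correlated SNPs rather than phenotype,
#' so significance is judged against a phenotype-permutation null: the
#' group labels are permuted genome-wide (once per iteration, preserving
#' group sizes) and windowed FST recomputed. A window is flagged when
#' (a) its observed FST exceeds the `centile`-th percentile of its own
#' permuted values, and (b) it exceeds `noise_multiplier` times a noise
#' floor — by default the genome-wide `centile`-th percentile of all
#' permuted window values (`noise_mode = "global"`), or per-window with
#' `noise_mode = "per_window"`.
#'
#' @inheritParams windowed_fst
#' @param n_perm Number of label permutations (default 200; fewer than 100
#'   makes the upper centile unstable and warns).
#' @param centile Percentile for criterion (a) (default 99).
#' @param noise_multiplier Multiplier for criterion (b) (default 3).
#' @param noise_mode `"global"` or `"per_window"` noise floor.
#' @param seed Integer seed for the permutation stream.
#' @return A `data.frame` of class `fst_scan`: the [windowed_fst()] columns
#'   plus `perm_centile` (the window's permutation threshold),
#'   `noise_floor`, `above_centile`, `above_noise`, `flagged`.
#' @export
fst_permutation_significance <- function(gm, panel,
                                         groups = c("resistant",
                                                    "susceptible"),
                                         window_bp = 1000, n_perm = 200,
                                         centile = 99, noise_multiplier = 3,
                                         noise_mode = c("global",
                                                        "per_window"),
                                         seed = 1) {
  noise_mode <- match.arg(noise_mode)
  if (n_perm < 100)
    warning("fewer than 100 permutations: the ", centile,
            "th centile is unstable", call. = FALSE)
  obs <- windowed_fst(gm, panel, groups, window_bp)
  idx_a <- match(panel_samples(panel, groups[1]), gm$samples)
  idx_b <- match(panel_samples(panel, groups[2]), gm$samples)
  pool <- c(idx_a, idx_b)
  na <- length(idx_a)
  d <- dosage(gm)
  key_obs <- paste0(obs$chrom, ":", (obs$start - 1L) %/% window_bp)

  set.seed(seed)
  perm <- matrix(NA_real_, nrow = nrow(obs), ncol = n_perm)
  for (k in seq_len(n_perm)) {
    shuffled <- sample(pool)
    core <- windowed_fst_core(d, gm$chrom, gm$pos,
                              shuffled[seq_len(na)], shuffled[-seq_len(na)],
                              window_bp)
    perm[, k] <- core$fst[match(key_obs, core$key)]
  }
  q <- centile / 100
  perm_centile <- apply(perm, 1, stats::quantile, probs = q, na.rm = TRUE,
                        names = FALSE)
  noise_floor <- if (noise_mode == "global")
    rep(stats::quantile(perm, probs = q, na.rm = TRUE, names = FALSE),
        nrow(obs))
  else perm_centile
  obs$perm_centile <- perm_centile
  obs$noise_floor <- noise_floor
  obs$above_centile <- !is.na(obs$fst) & obs$fst > perm_centile
  obs$above_noise <- !is.na(obs$fst) &
    obs$fst > noise_multiplier * noise_floor
  obs$flagged <- obs$above_centile & obs$above_noise
  class(obs) <- c("fst_scan", "data.frame")
  obs
}

#' @export
print.fst_scan <- function(x, ...) {
  cat(sprintf(
    "windowed FST scan: %d windows, %d flagged (centile + noise criteria)\n",
    nrow(x), sum(x$flagged)))
  cols <- intersect(c("chrom", "start", "end", "n_variants", "fst",
                      "perm_centile"), names(x))
  if (any(x$flagged))
    print.data.frame(x[x$flagged, cols], row.names = FALSE)
  invisible(x)
}
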