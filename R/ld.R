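#' Rogers-Huff composite linkage disequilibrium
#'
#' The correlation between the alternate-allele dosage vectors of two sites,
#' computed with population-moment (biased) denominators over the
#' pairwise-complete samples:
#' `r = cov(x, y) / sqrt(var(x) var(y))`. Squaring gives the familiar r^2.
#' Dosages require no phasing, which is what makes this estimator the
#' standard choice for genotype-level LD.
#'
#' @param x,y Numeric dosage vectors in `{0, 1, 2}` (`NA` = missing), equal
#'   length.
#' @return `r` in `[-1, 1]`, with attribute `n` (pairwise-complete sample
#'   count). `NA` (never 0) when either site is monomorphic among the
#'   complete pairs or fewer than two complete pairs exist.
#' @export
rogers_huff_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2L) return(structure(NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum(x * x) / n - mx * mx
  vy <- sum(y * y) / n - my * my
  if (vx <= 0 || vy <= 0) return(structure(NA_real_, n = n))
  cxy <- sum(x * y) / n - mx * my
  structure(cxy / sqrt(vx * vy), n = n)
}

#' Pairwise r-squared matrix over a set of SNPs
#'
#' All unordered pairs, missing dosages handled by pairwise-complete
#' deletion. Monomorphic sites yield `NA` rows/columns (flagged undefined,
#' never coerced to 0 — this matters for small panels). The diagonal is 1
#' wherever the site is polymorphic.
#'
#' @param gm A [genotype_matrix()].
#' @param sites Integer site indices, or a `data.frame` with `chrom`/`pos`
#'   columns (e.g. a candidate table); labels taken from its `label` column
#'   when present.
#' @param samples Samples to include (default: all, pooling phenotype
#'   groups).
#' @return A list of class `ld_matrix`: `r`, `r2`, `n` (square matrices)
#'   and `labels`.
#' @export
pairwise_r2 <- function(gm, sites, samples = gm$samples) {
  if (is.data.frame(sites)) {
    idx <- mapply(function(ch, p) site_index(gm, ch, p),
                  sites$chrom, sites$pos)
    labels <- if ("label" %in% names(sites)) sites$label else
      paste0(sites$chrom, ":", sites$pos)
    found <- !is.na(idx)
    idx <- idx[found]; labels <- labels[found]
  } else {
    idx <- sites
    labels <- paste0(gm$chrom[idx], ":", gm$pos[idx])
  }
  if (length(idx) < 2L) stop("need at least two sites", call. = FALSE)
  d <- dosage(gm)[idx, samples, drop = FALSE]
  k <- length(idx)
  r <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  nm <- matrix(0L, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    xi <- d[i, ]
    ri <- rogers_huff_r(xi, xi)
    r[i, i] <- if (is.na(ri)) NA_real_ else 1
    nm[i, i] <- attr(ri, "n")
    if (i < k) for (j in seq(i + 1L, k)) {
      rij <- rogers_huff_r(xi, d[j, ])
      r[i, j] <- r[j, i] <- as.numeric(rij)
      nm[i, j] <- nm[j, i] <- attr(rij, "n")
    }
  }
  structure(list(r = r, r2 = r * r, n = nm, labels = labels),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, digits = 3, ...) {
  cat("Rogers-Huff pairwise LD (r^2); NA = undefined (monomorphic site)\n")
  print(round(x$r2, digits))
  invisible(x)
}

#' Long-format LD table
#'
#' @param x An `ld_matrix`.
#' @return `data.frame` with one row per unordered site pair: `site_a`,
#'   `site_b`, `r`, `r2`, `n`.
#' @export
ld_long <- function(x) {
  stopifnot(inherits(x, "ld_matrix"))
  k <- length(x$labels)
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  data.frame(site_a = x$labels[pairs[, 1]], site_b = x$labels[pairs[, 2]],
             r = x$r[pairs], r2 = x$r2[pairs], n = x$n[pairs],
             stringsAsFactors = FALSE)
}
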