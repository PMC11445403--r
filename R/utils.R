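`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed for a named stage
#'
#' A single user-facing seed fans out to independent per-stage seeds so that
#' toggling one pipeline stage does not shift the random stream of another.
#' The derived seed always fits a 32-bit signed integer.
#'
#' @param seed Base integer seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  salt <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + salt * 104729) %% 2147483629)
}

# round half away from zero, as printed tables in the field round
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_scalar_percent <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 100)
    stop(sprintf("`%s` must be a single percentage in [0, 100]", name),
         call. = FALSE)
  invisible(x)
}
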