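#' Pooled observed mortality from WHO tube-test replicates
#'
#' @param records `data.frame` of tube-test records with columns `n_exposed`
#'   and `n_dead` (one row per replicate tube); deaths are counted 24 h
#'   post exposure, with knocked-down mosquitoes counted as dead.
#' @return Mortality as a percentage of all exposed mosquitoes, pooled over
#'   replicates.
#' @export
observed_mortality <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("n_exposed", "n_dead") %in% names(records)))
  if (any(records$n_dead > records$n_exposed) || any(records$n_dead < 0))
    stop("n_dead must lie in [0, n_exposed]", call. = FALSE)
  n <- sum(records$n_exposed)
  if (n == 0) stop("no mosquitoes exposed", call. = FALSE)
  100 * sum(records$n_dead) / n
}

#' Abbott's correction for control mortality
#'
#' `corrected = 100 * (T - C) / (100 - C)`, the WHO-recommended adjustment
#' of treatment mortality `T` for background control mortality `C`. Applied
#' when control mortality is at least 5% (see [validity_check()]). When
#' `T < C` the result is clamped at 0 and flagged via the `"clamped"`
#' attribute.
#'
#' @param treatment_mortality Observed treatment mortality, percent.
#' @param control_mortality Observed control mortality, percent (< 100).
#' @return Corrected mortality, percent.
#' @export
abbott_correct <- function(treatment_mortality, control_mortality) {
  assert_scalar_percent(treatment_mortality, "treatment_mortality")
  assert_scalar_percent(control_mortality, "control_mortality")
  if (control_mortality >= 100)
    stop("Abbott's correction is undefined at 100% control mortality",
         call. = FALSE)
  out <- 100 * (treatment_mortality - control_mortality) /
    (100 - control_mortality)
  if (out < 0) {
    out <- 0
    attr(out, "clamped") <- TRUE
  }
  out
}

#' WHO resistance classification from corrected mortality
#'
#' Discriminating-dose tier: mortality below 90% confirms resistance,
#' 90 to below 98% is suspected resistance (the WHO band; the 97-98% gap
#' falls here), and 98% or more is susceptible. Intensity tier (5x
#' concentration): 98% or more indicates low-intensity resistance, below
#' 98% moderate-to-high intensity.
#'
#' @param mortality Corrected (or, when no correction applies, observed)
#'   mortality, percent.
#' @param tier `"discriminating"` or `"intensity_5x"`.
#' @return Classification label (character scalar).
#' @export
classify_mortality <- function(mortality,
                               tier = c("discriminating", "intensity_5x")) {
  assert_scalar_percent(mortality, "mortality")
  tier <- match.arg(tier)
  if (tier == "discriminating") {
    if (mortality < 90) "confirmed_resistance"
    else if (mortality < 98) "suspected_resistance"
    else "susceptible"
  } else {
    if (mortality >= 98) "low_intensity" else "moderate_to_high_intensity"
  }
}

#' Validity and correction rule for control tubes
#'
#' A test is invalid when control mortality exceeds 20%; Abbott's
#' correction is required when control mortality lies in [5%, 20%] and
#' skipped below 5%.
#'
#' @param control_records Control-tube records (`n_exposed`, `n_dead`), or a
#'   single control mortality percentage.
#' @return A list with `control_mortality`, `valid` and
#'   `correction_required`.
#' @export
validity_check <- function(control_records) {
  cm <- if (is.data.frame(control_records))
    observed_mortality(control_records) else control_records
  assert_scalar_percent(cm, "control mortality")
  list(control_mortality = cm, valid = cm <= 20,
       correction_required = cm >= 5 && cm <= 20)
}

#' Summarise WHO tube tests: pooling, correction and classification
#'
#' Pools replicates per test, applies [abbott_correct()] when the control
#' mortality rule requires it, and classifies the result. Mortalities are
#' reported to two decimals and the correction is computed on those
#' two-decimal pooled mortalities, which is how printed WHO tube-test
#' tables are built (their corrected values back-calculate exactly from
#' the rounded treatment and control percentages).
#'
#' @param records `data.frame` with columns `test` (assay identifier),
#'   `role` (`"treatment"` or `"control"`), `replicate`, `n_exposed`,
#'   `n_dead`. See [read_bioassay_tsv()].
#' @param tiers Named character vector mapping each `test` value to a
#'   classification tier (`"discriminating"` or `"intensity_5x"`). Unnamed
#'   scalar is recycled.
#' @return A `data.frame` of class `mortality_summary`, one row per test:
#'   pooled counts, observed/control/corrected mortality, validity and
#'   classification. `corrected_mortality` is `NA` ("not corrected") when
#'   control mortality is below 5%.
#' @export
summarise_bioassay <- function(records, tiers = "discriminating") {
  stopifnot(all(c("test", "role", "n_exposed", "n_dead") %in% names(records)))
  tiers <- unlist(tiers)
  tests <- unique(records$test)
  if (is.null(names(tiers)))
    tiers <- stats::setNames(rep_len(tiers, length(tests)), tests)
  rows <- lapply(tests, function(tn) {
    trt <- records[records$test == tn & records$role == "treatment", ]
    ctl <- records[records$test == tn & records$role == "control", ]
    if (nrow(trt) == 0) stop(sprintf("test '%s' has no treatment tubes", tn),
                             call. = FALSE)
    t_mort <- round_half_up(observed_mortality(trt))
    ctrl <- if (nrow(ctl)) validity_check(ctl) else
      list(control_mortality = NA_real_, valid = TRUE,
           correction_required = FALSE)
    c_mort <- round_half_up(ctrl$control_mortality)
    corrected <- if (isTRUE(ctrl$correction_required))
      as.numeric(abbott_correct(t_mort, c_mort))
    else NA_real_
    effective <- if (is.na(corrected)) t_mort else corrected
    data.frame(
      test = tn, tier = unname(tiers[tn]),
      n_exposed = sum(trt$n_exposed), n_dead = sum(trt$n_dead),
      observed_mortality = t_mort,
      control_mortality = c_mort,
      corrected_mortality = round_half_up(corrected),
      valid = ctrl$valid,
      classification = if (isTRUE(ctrl$valid))
        classify_mortality(effective, unname(tiers[tn])) else NA_character_,
      stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("mortality_summary", "data.frame"))
}

#' @export
print.mortality_summary <- function(x, ...) {
  cat("WHO tube-test summary (24 h mortality, Abbott-corrected where",
      "control mortality >= 5%)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read tube-test replicate counts from TSV
#'
#' Expected columns: `test`, `role` (`treatment`/`control`), `replicate`,
#' `n_exposed`, `n_dead`.
#'
#' @param path TSV file.
#' @return A `data.frame` of tube-test records.
#' @export
read_bioassay_tsv <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("test", "role", "n_exposed", "n_dead")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("bioassay TSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  rec
}
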