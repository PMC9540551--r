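# End-to-end orchestration: admissions -> eligible cohort -> case-mix ->
# outcomes -> instrument -> analysis-ready table.

#' Build the analysis-ready cohort from an admission dataset
#'
#' Runs the full data pipeline for one condition: eligibility and ES/NES
#' classification, case-mix derivation (Charlson, frailty), outcome
#' construction (DAOH-90 and secondaries), the tendency-to-operate
#' instrument, hospital quality proxies and the time-period covariate.
#' Rows without a valid TTO (insufficient lookback coverage or hospital
#' volume below `min_volume`) are excluded from the analysis cohort with a
#' logged count.
#'
#' @param data An [admission_data()] object.
#' @param spec A [condition_spec()]; defaults to the shipped spec matching
#'   `condition`.
#' @param condition Condition name used to pick the default spec.
#' @param code_map Code map for case-mix derivation.
#' @param horizon Outcome horizon in days (default 90).
#' @param min_volume Minimum eligible lookback admissions for a valid TTO.
#' @param daoh_variant Use `daoh_90` (main) or `daoh_alt_90`
#'   (count-days-for-decedents) as the primary outcome column `daoh`;
#'   both are always present.
#' @param low_volume_exclusion Exclude hospitals whose emergency surgery
#'   volume is at least one interquartile range below the median hospital
#'   volume (a sensitivity analysis; default `FALSE`).
#' @return A list with `cohort` (analysis rows), `full_cohort` (eligible
#'   rows before TTO validity filtering), `exclusions`, `eligible` (the
#'   instrument pool), `proxies`, `tto_invalid_n`,
#'   `low_volume_hospitals`, `index_start`.
#' @export
prepare_analysis_data <- function(data, spec = NULL,
                                  condition = "appendicitis",
                                  code_map = default_code_map(),
                                  horizon = 90, min_volume = 10,
                                  daoh_variant = c("main", "count_days_for_decedents"),
                                  low_volume_exclusion = FALSE) {
  daoh_variant <- match.arg(daoh_variant)
  if (is.null(spec)) spec <- default_condition_specs()[[condition]]
  if (is.null(spec)) abort(sprintf("no condition spec for '%s'", condition))

  built <- build_cohort(data, spec)
  cohort <- built$cohort
  cohort <- derive_casemix(data, cohort, map = code_map)
  cohort <- derive_outcomes(data, cohort, horizon = horizon)

  pool <- eligible_admissions(data, spec)
  study_start <- min(data$admissions$admission_date)
  tto <- compute_tto(pool, window_days = spec$lookback_exclusion_days,
                     min_volume = min_volume, study_start = study_start)
  cohort$tto <- tto$tto[match(cohort$admission_id, tto$admission_id)]
  cohort$tto_valid <- tto$valid[match(cohort$admission_id, tto$admission_id)]

  # mortality for quality proxies needs outcomes on the pool; reuse the
  # cohort's where available and derive from death dates elsewhere
  adm <- data$admissions
  pool_death <- adm$death_date[match(pool$admission_id, adm$admission_id)]
  pool$mortality_90 <- !is.na(pool_death) &
    pool_death < pool$admission_date + horizon
  proxies <- hospital_quality_proxies(pool, study_start = study_start)
  cohort <- join_quality_proxies(cohort, proxies, study_start = study_start)

  cohort$year <- factor(floor((cohort$index_date - built$index_start) / 365))
  cohort$age_band <- age_band(cohort$age)
  cohort$daoh <- if (daoh_variant == "main") cohort$daoh_90 else cohort$daoh_alt_90

  low_volume_hospitals <- character(0)
  if (low_volume_exclusion) {
    vol <- pool |>
      filter(.data$es) |>
      count(.data$hospital_id, name = "es_volume")
    thr <- stats::median(vol$es_volume) - stats::IQR(vol$es_volume)
    low_volume_hospitals <- vol$hospital_id[vol$es_volume < thr]
    if (length(low_volume_hospitals)) {
      inform(sprintf("low-volume exclusion removes %d hospital(s): %s",
                     length(low_volume_hospitals),
                     paste(low_volume_hospitals, collapse = ", ")))
    }
  }

  keep <- cohort$tto_valid %in% TRUE &
    !cohort$hospital_id %in% low_volume_hospitals
  n_invalid <- sum(!cohort$tto_valid %in% TRUE)
  if (n_invalid) {
    inform(sprintf("%d row(s) without a valid TTO excluded from IV fitting",
                   n_invalid))
  }
  list(cohort = cohort[keep, , drop = FALSE],
       full_cohort = cohort,
       exclusions = built$exclusions,
       eligible = pool,
       proxies = proxies,
       tto_invalid_n = n_invalid,
       low_volume_hospitals = low_volume_hospitals,
       index_start = built$index_start)
}

#' Simulate, prepare and analyse in one call
#'
#' Convenience wrapper used in examples and validation: generates a
#' synthetic dataset under `config`, prepares the analysis cohort and
#' returns IV (and optionally naive) estimates for an outcome, together
#' with the generator's truth.
#'
#' @param config A [sim_config()].
#' @param outcome Outcome column (default `"daoh"`).
#' @param spec A [model_spec()].
#' @param reps Bootstrap replications (0 = point estimates only).
#' @param naive Also compute the naive comparator?
#' @return A list with `estimates`, `naive`, `truth_summary`, `prep`,
#'   `sim`.
#' @export
simulate_and_analyse <- function(config, outcome = "daoh",
                                 spec = model_spec(), reps = 0,
                                 naive = FALSE) {
  sim <- generate_dataset(config)
  prep <- prepare_analysis_data(sim$data, condition = config$condition)
  est <- iv_effects(prep$cohort, outcome, spec, reps = reps)
  nv <- if (naive) naive_estimate(prep$cohort, outcome, spec)
  truth <- true_effects(sim$truth, ids = prep$cohort$admission_id)
  list(estimates = est, naive = nv, truth_summary = truth, prep = prep,
       sim = sim)
}
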