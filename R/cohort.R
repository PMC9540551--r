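# Cohort construction: eligibility rules and emergency-surgery (ES)
# classification for one acute condition.

EMERGENCY_METHODS <- c("emergency_ed", "emergency_gp")
SURGICAL_SPECIALTIES <- c("general_surgery", "general_surgery_subspecialty",
                          "other_surgery")

# Per-admission eligibility flags (vectorised over the whole dataset).
# Returns the admissions table with: has_qualifying_diag,
# qualifying_episode_order, qualifying_specialty_ok, relevant (diagnosis
# only, used for the prior-admission exclusion), and the first failing rule
# for ineligible admissions.
eligibility_flags <- function(data, spec, min_age = 18) {
  adm <- data$admissions
  ep <- data$episodes
  ep12 <- ep[ep$episode_order <= 2L, , drop = FALSE]
  main <- normalize_codes(first_code(ep12$diag_codes))
  qual <- match_any_prefix(main, spec$include_codes)
  if (!is.null(spec$second_field_rule)) {
    sec <- normalize_codes(second_code(ep12$diag_codes))
    main_is_alt <- match_any_prefix(main, spec$second_field_rule$main_prefixes)
    sec_rel <- !is.na(sec) & match_any_prefix(sec, spec$include_codes)
    qual <- qual | (main_is_alt & sec_rel)
  }
  ep12$qual <- qual & !is.na(main)
  ep12$surgical <- ep12$specialty %in% SURGICAL_SPECIALTIES
  e <- ep12[order(ep12$admission_id, ep12$episode_order), , drop = FALSE]
  qs <- e[e$qual & e$surgical, , drop = FALSE]
  qs1 <- qs[!duplicated(qs$admission_id), , drop = FALSE]
  q <- e[e$qual, , drop = FALSE]
  q1 <- q[!duplicated(q$admission_id), , drop = FALSE]
  out <- adm
  out$has_qualifying_diag <- adm$admission_id %in% q1$admission_id
  out$qualifying_specialty_ok <- adm$admission_id %in% qs1$admission_id
  out$qualifying_episode_order <-
    qs1$episode_order[match(adm$admission_id, qs1$admission_id)]
  no_surg <- is.na(out$qualifying_episode_order)
  out$qualifying_episode_order[no_surg] <-
    q1$episode_order[match(adm$admission_id[no_surg], q1$admission_id)]
  out$emergency <- out$admission_method %in% EMERGENCY_METHODS
  out$relevant <- out$has_qualifying_diag
  # Prior relevant emergency admission within the lookback window, judged
  # by the same diagnosis rule. Strictly earlier admissions only.
  rel <- out[out$relevant & out$emergency,
             c("admission_id", "patient_id", "admission_date")]
  rel <- rel[order(rel$patient_id, rel$admission_date, rel$admission_id), , drop = FALSE]
  if (nrow(rel)) {
    # Nearest strictly-earlier relevant emergency admission date (same-day
    # admissions do not exclude each other).
    u <- rel[!duplicated(rel[c("patient_id", "admission_date")]),
             c("patient_id", "admission_date")]
    i <- match(paste(rel$patient_id, rel$admission_date),
               paste(u$patient_id, u$admission_date))
    has_prev <- i > 1L & u$patient_id[pmax(i - 1L, 1L)] == rel$patient_id
    gap <- rel$admission_date - u$admission_date[pmax(i - 1L, 1L)]
    rel$prior_relevant <- has_prev & gap <= spec$lookback_exclusion_days
  } else {
    rel$prior_relevant <- logical(0)
  }
  out$prior_relevant <- FALSE
  out$prior_relevant[match(rel$admission_id, out$admission_id)] <- rel$prior_relevant
  out$age_ok <- !is.na(out$age) & out$age >= min_age
  out$eligible <- out$age_ok & out$emergency & out$has_qualifying_diag &
    out$qualifying_specialty_ok & !out$prior_relevant
  out
}

#' Classify emergency surgery from procedure records
#'
#' Flags each admission as emergency surgery if any procedure matching the
#' condition's qualifying code prefixes occurred no later than
#' `window_days` after admission (or at any time within the admission when
#' the window is [ANY_TIME]), and returns the days from admission to the
#' earliest qualifying procedure.
#'
#' @param admissions Data frame with `admission_id`, `admission_date`,
#'   `discharge_date`.
#' @param procedures Data frame with `admission_id`, `code`, `date`.
#' @param spec A [condition_spec()].
#' @param codes,window_days Override the spec's procedure prefixes and
#'   window (used by the sensitivity re-classifications).
#' @return A tibble keyed by `admission_id` with logical `es` and integer
#'   `days_to_surgery` (`NA` for non-ES admissions).
#' @export
classify_treatment <- function(admissions, procedures, spec,
                               codes = spec$es_procedure_codes,
                               window_days = spec$es_window_days) {
  pr <- procedures[procedures$admission_id %in% admissions$admission_id, ,
                   drop = FALSE]
  span <- admissions[match(pr$admission_id, admissions$admission_id),
                     c("admission_date", "discharge_date")]
  if (nrow(pr) && any(pr$date < span$admission_date)) {
    abort("procedure dated before admission")
  }
  days <- pr$date - span$admission_date
  qual <- match_any_prefix(pr$code, codes) &
    pr$date <= span$discharge_date &
    (is.infinite(window_days) | days <= window_days)
  prq <- tibble(admission_id = pr$admission_id[qual], days = days[qual])
  prq <- prq[order(prq$admission_id, prq$days), , drop = FALSE]
  first <- prq[!duplicated(prq$admission_id), , drop = FALSE]
  out <- tibble(admission_id = admissions$admission_id)
  out$days_to_surgery <- as.integer(
    first$days[match(out$admission_id, first$admission_id)])
  out$es <- !is.na(out$days_to_surgery)
  out[, c("admission_id", "es", "days_to_surgery")]
}

#' Build the eligible cohort for one condition
#'
#' Applies the eligibility rules to an admission dataset and classifies
#' each eligible index admission as emergency surgery (ES) versus
#' non-emergency strategy (NES). An admission is eligible when a consultant
#' episode within it carries a relevant main diagnosis (or, where the spec
#' defines a second-field rule, a relevant second diagnosis with a
#' qualifying main diagnosis) in the first or second episode, under a
#' surgical specialty, within an emergency admission, for a patient aged
#' `min_age` or older, with no prior relevant emergency admission in the
#' preceding lookback window. The exclusion tally attributes each excluded
#' candidate to the first failing rule, in the order: outside the index
#' window; age; admission method; diagnosis; specialty; prior relevant
#' admission.
#'
#' @param data An [admission_data()] object including lookback-period
#'   records.
#' @param spec A [condition_spec()].
#' @param index_start,index_end Day-offset bounds of the index window
#'   (half-open `[index_start, index_end)`). The default index window
#'   starts one lookback-exclusion window after the earliest admission, so
#'   the prior-admission rule and the instrument have full lookback
#'   coverage, and ends after the latest admission.
#' @param min_age Minimum age in years (default 18).
#' @return A list with `cohort` (one row per eligible index admission:
#'   ids, condition, `index_date`, `discharge_date`, demographics, `es`,
#'   `days_to_surgery`, `qualifying_episode_order`) and `exclusions` (a
#'   tibble of rule / count in application order, plus the candidate and
#'   cohort totals as attributes).
#' @export
build_cohort <- function(data, spec, index_start = NULL, index_end = NULL,
                         min_age = 18) {
  flags <- eligibility_flags(data, spec, min_age = min_age)
  if (is.null(index_start)) {
    index_start <- min(flags$admission_date) + spec$lookback_exclusion_days
  }
  if (is.null(index_end)) index_end <- max(flags$admission_date) + 1L

  # Overlapping admissions for one patient: keep both, warn.
  ov <- flags[order(flags$patient_id, flags$admission_date), , drop = FALSE]
  if (nrow(ov) > 1L) {
    same <- ov$patient_id[-1] == ov$patient_id[-nrow(ov)]
    overlap <- same & ov$admission_date[-1] < ov$discharge_date[-nrow(ov)]
    if (any(overlap)) {
      warn(sprintf("%d overlapping admission(s) for the same patient; keeping both",
                   sum(overlap)))
    }
  }

  in_window <- flags$admission_date >= index_start &
    flags$admission_date < index_end
  cand <- flags[in_window, , drop = FALSE]
  rule <- with(cand, ifelse(!age_ok, "age_under_minimum",
               ifelse(!emergency, "non_emergency_method",
               ifelse(!has_qualifying_diag, "no_qualifying_diagnosis",
               ifelse(!qualifying_specialty_ok, "non_surgical_specialty",
               ifelse(prior_relevant, "prior_relevant_admission", "eligible"))))))
  rules <- c("age_under_minimum", "non_emergency_method",
             "no_qualifying_diagnosis", "non_surgical_specialty",
             "prior_relevant_admission")
  rule_counts <- vapply(rules, function(r) sum(rule == r), integer(1))
  tally <- tibble(rule = c("outside_index_window", rules),
                  n = unname(c(sum(!in_window), rule_counts)))

  elig <- cand[rule == "eligible", , drop = FALSE]
  cls <- classify_treatment(elig, data$procedures, spec)
  cohort <- tibble(
    admission_id = elig$admission_id,
    patient_id = elig$patient_id,
    hospital_id = elig$hospital_id,
    condition = spec$name,
    index_date = elig$admission_date,
    discharge_date = elig$discharge_date,
    qualifying_episode_order = elig$qualifying_episode_order,
    age = elig$age,
    sex = elig$sex %||% NA_character_,
    ethnicity = elig$ethnicity %||% NA_character_,
    imd_quintile = elig$imd_quintile %||% NA_integer_,
    es = cls$es[match(elig$admission_id, cls$admission_id)],
    days_to_surgery = cls$days_to_surgery[match(elig$admission_id, cls$admission_id)]
  )
  attr(tally, "candidates") <- nrow(cand) + sum(!in_window)
  attr(tally, "cohort_n") <- nrow(cohort)
  list(cohort = cohort, exclusions = tally,
       index_start = index_start, index_end = index_end)
}

#' Eligible emergency admissions across the whole study period
#'
#' Applies the per-admission eligibility rules (age, emergency method,
#' qualifying diagnosis in episode 1-2, surgical specialty, no prior
#' relevant emergency admission) to every admission regardless of date, and
#' classifies each eligible admission as ES or NES. This is the pool over
#' which the tendency-to-operate instrument and the hospital quality
#' proxies are computed.
#'
#' @inheritParams build_cohort
#' @return A tibble with one row per eligible admission: `admission_id`,
#'   `patient_id`, `hospital_id`, `admission_date`, `discharge_date`,
#'   `es`, `days_to_surgery`.
#' @export
eligible_admissions <- function(data, spec, min_age = 18) {
  flags <- eligibility_flags(data, spec, min_age = min_age)
  elig <- flags[flags$eligible, , drop = FALSE]
  cls <- classify_treatment(elig, data$procedures, spec)
  tibble(
    admission_id = elig$admission_id,
    patient_id = elig$patient_id,
    hospital_id = elig$hospital_id,
    admission_date = elig$admission_date,
    discharge_date = elig$discharge_date,
    es = cls$es[match(elig$admission_id, cls$admission_id)],
    days_to_surgery = cls$days_to_surgery[match(elig$admission_id, cls$admission_id)]
  )
}

#' Re-derive emergency-surgery flags under a sensitivity definition
#'
#' `strict_codes` re-classifies using the spec's stricter procedure list
#' and window. `reduced_window` computes the upper quartile of observed
#' days-to-surgery among default-ES rows and re-classifies with that
#' threshold (the default code list is kept).
#'
#' @param cohort A cohort tibble built under the default definition.
#' @param data The [admission_data()] object used to build it.
#' @param spec The [condition_spec()].
#' @param mode `"strict_codes"` or `"reduced_window"`.
#' @return A list with the re-classified `cohort` and the `threshold`
#'   (window in days) used.
#' @export
apply_sensitivity_definition <- function(cohort, data, spec,
                                         mode = c("strict_codes", "reduced_window")) {
  mode <- match.arg(mode)
  if (mode == "strict_codes") {
    codes <- spec$strict_es_procedure_codes
    threshold <- spec$strict_window_days
  } else {
    if (!any(cohort$es)) abort("reduced_window: cohort has no ES rows")
    threshold <- unname(quantile(cohort$days_to_surgery[cohort$es], 0.75,
                                 type = 7))
    codes <- spec$es_procedure_codes
  }
  adm <- tibble(admission_id = cohort$admission_id,
                admission_date = cohort$index_date,
                discharge_date = cohort$discharge_date)
  cls <- classify_treatment(adm, data$procedures, spec,
                            codes = codes, window_days = threshold)
  cohort$es <- cls$es[match(cohort$admission_id, cls$admission_id)]
  cohort$days_to_surgery <- cls$days_to_surgery[match(cohort$admission_id, cls$admission_id)]
  list(cohort = cohort, threshold = threshold)
}
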