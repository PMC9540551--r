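# Synthetic admission-record generator with known causal structure.
#
# The data-generating process mirrors the statistical structure the
# analysis assumes: hospitals carry a latent operating preference on the
# probit scale (the instrument's source of variation), an unobserved
# severity factor U confounds both treatment choice and outcomes, case-mix
# deficits and comorbidities are emitted as diagnosis codes through the
# same configurable code maps the case-mix module reads, and the treatment
# effect acts on the index length of stay so that DAOH is derived from
# spells rather than drawn directly. Both potential spell sets are
# constructed per admission, so every person's true effect on DAOH is known
# exactly.

#' Configure the synthetic admissions generator
#'
#' Builds a validated `sim_config`. The defaults describe a study of 40
#' hospitals with around 500 eligible admissions per hospital over a
#' two-year index window preceded by a one-year lookback (so the
#' tendency-to-operate instrument and the prior-admission exclusion have
#' full coverage), a moderately strong hospital preference instrument, and
#' unobserved-severity confounding. See [scenario_presets()] for the named
#' scenarios used in validation.
#'
#' @param n_hospitals Number of hospitals (>= 2).
#' @param admissions_per_hospital Mean index-window admissions per hospital
#'   (a Poisson count; admissions are also generated through the lookback
#'   year at the same daily rate).
#' @param study_start,study_end Integer day offsets bounding the study
#'   period; the span must be at least 455 days (one lookback year plus a
#'   90-day follow-up).
#' @param condition Condition label; must match a name in
#'   [default_condition_specs()].
#' @param preference_spread SD of the hospital latent operating preference
#'   on the probit scale.
#' @param instrument_strength Coefficient of the hospital preference in the
#'   treatment model; 0 makes the instrument irrelevant.
#' @param confounding_strength Loading of the unobserved severity factor U
#'   on the treatment latent index (U also loads on death and length of
#'   stay via `death_model` and `los_model`, so a nonzero value induces
#'   unmeasured confounding).
#' @param ate_days True average treatment effect of emergency surgery on
#'   DAOH in days for patients without frailty-specific modification,
#'   applied as a shift of the index length of stay.
#' @param effect_by_frailty Named numeric additive effect modifiers (days)
#'   for the frailty categories `fit`, `mild`, `moderate`, `severe`.
#' @param deficit_prevalence Per-deficit baseline probabilities (length =
#'   number of deficits in `code_map`).
#' @param comorbidity_prevalence Per-Charlson-condition baseline
#'   probabilities (length = number of conditions in `code_map`).
#' @param age_mean,age_sd,female_prob Demographics.
#' @param los_model,death_model,readmit_model,treat_model,deficit_model,comorbidity_model
#'   Named parameter lists for outcome and treatment generation (see the
#'   methods vignette for each parameter's role and units).
#' @param ineligible Named fractions of admissions made ineligible on
#'   purpose (under-18 age, elective or other admission method, relevant
#'   diagnosis only in episode 3, non-surgical specialty) so the cohort
#'   rules are exercised.
#' @param diag_in_ep2_frac Fraction of eligible admissions whose relevant
#'   diagnosis sits in episode 2 rather than 1.
#' @param second_field_frac For intestinal obstruction only: fraction of
#'   eligible admissions qualifying through the second diagnosis field with
#'   a colorectal-cancer main diagnosis.
#' @param repeat_prior_frac Fraction of index admissions given a relevant
#'   emergency admission 30-364 days earlier (which excludes them).
#' @param late_procedure_frac Fraction of untreated admissions receiving a
#'   qualifying procedure after the time window (they stay non-emergency
#'   surgery).
#' @param nonqualifying_procedure_frac Fraction of untreated admissions
#'   receiving a non-qualifying procedure.
#' @param code_map Code map used to emit comorbidity/deficit codes.
#' @param seed Integer seed; identical config and seed give byte-identical
#'   output.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_hospitals = 40,
                       admissions_per_hospital = 500,
                       study_start = 0L,
                       study_end = 1095L,
                       condition = "appendicitis",
                       preference_spread = 0.6,
                       instrument_strength = 1.0,
                       confounding_strength = 0.5,
                       ate_days = 5,
                       effect_by_frailty = c(fit = 0, mild = 0, moderate = 0, severe = 0),
                       deficit_prevalence = rep(0.045, 32),
                       comorbidity_prevalence = c(0.04, 0.03, 0.02, 0.03, 0.03,
                                                  0.06, 0.015, 0.015, 0.015, 0.05,
                                                  0.015, 0.008, 0.02, 0.02, 0.006,
                                                  0.01, 0.003),
                       age_mean = 55, age_sd = 18, female_prob = 0.52,
                       los_model = list(meanlog = 2.3, sdlog = 0.5,
                                        age_loading = 0.10, frailty_loading = 0.05,
                                        u_loading = 0.20),
                       death_model = list(intercept = -2.2, age_loading = 0.45,
                                          frailty_loading = 0.10, u_loading = 0.30),
                       readmit_model = list(base_prob = 0.10, u_loading = 0.25,
                                            max_gap = 25, los_meanlog = 1.2,
                                            los_sdlog = 0.5),
                       treat_model = list(intercept = -0.2, age_loading = -0.10,
                                          frailty_loading = 0.08),
                       deficit_model = list(age_loading = 0.8, u_loading = 0.4),
                       comorbidity_model = list(age_loading = 0.7),
                       ineligible = list(age_under18 = 0.02, elective = 0.04,
                                         other_method = 0.01, late_episode = 0.02,
                                         nonsurgical = 0.02),
                       diag_in_ep2_frac = 0.08,
                       second_field_frac = 0.05,
                       repeat_prior_frac = 0.02,
                       late_procedure_frac = 0.05,
                       nonqualifying_procedure_frac = 0.05,
                       code_map = default_code_map(),
                       seed = 1L) {
  if (!is.numeric(n_hospitals) || n_hospitals < 2) {
    stop_config("n_hospitals", "must be at least 2")
  }
  if (!is.numeric(admissions_per_hospital) || admissions_per_hospital <= 0) {
    stop_config("admissions_per_hospital", "must be positive")
  }
  if (study_end - study_start < 455) {
    stop_config("study_end", "study span must be at least 455 days (one lookback year plus 90-day follow-up)")
  }
  specs <- default_condition_specs()
  if (!condition %in% names(specs)) {
    stop_config("condition", sprintf("must be one of: %s",
                                     paste(names(specs), collapse = ", ")))
  }
  if (!is.numeric(preference_spread) || preference_spread < 0) {
    stop_config("preference_spread", "must be non-negative")
  }
  if (!is.finite(ate_days)) stop_config("ate_days", "must be finite")
  lv <- c("fit", "mild", "moderate", "severe")
  if (!all(lv %in% names(effect_by_frailty)) ||
      !all(is.finite(effect_by_frailty))) {
    stop_config("effect_by_frailty",
                "must be finite and named fit/mild/moderate/severe")
  }
  check_prob(female_prob, "female_prob")
  check_prob(deficit_prevalence, "deficit_prevalence")
  check_prob(comorbidity_prevalence, "comorbidity_prevalence")
  check_prob(readmit_model$base_prob, "readmit_model$base_prob")
  for (f in names(ineligible)) check_prob(ineligible[[f]], paste0("ineligible$", f))
  check_prob(diag_in_ep2_frac, "diag_in_ep2_frac")
  check_prob(second_field_frac, "second_field_frac")
  check_prob(repeat_prior_frac, "repeat_prior_frac")
  check_prob(late_procedure_frac, "late_procedure_frac")
  check_prob(nonqualifying_procedure_frac, "nonqualifying_procedure_frac")
  map <- validate_code_map(code_map)
  if (length(deficit_prevalence) != nrow(map$frailty)) {
    stop_config("deficit_prevalence",
                sprintf("length %d does not match the %d configured deficits",
                        length(deficit_prevalence), nrow(map$frailty)))
  }
  if (length(comorbidity_prevalence) != nrow(map$charlson)) {
    stop_config("comorbidity_prevalence",
                sprintf("length %d does not match the %d configured conditions",
                        length(comorbidity_prevalence), nrow(map$charlson)))
  }
  if (!is.numeric(age_sd) || age_sd <= 0) stop_config("age_sd", "must be positive")
  structure(as.list(environment())[names(formals(sim_config))],
            class = "sim_config")
}

#' Named simulation scenarios
#'
#' Fully specified configurations used throughout validation:
#'
#' * `null_effect`: zero treatment effect, confounding present — the IV
#'   estimate should cover zero while selection still distorts the naive
#'   contrast.
#' * `unconfounded`: effect of 5 DAOH days, no unobserved confounding —
#'   both the naive and IV estimators should recover the truth.
#' * `strong_iv_confounded`: effect of 5 DAOH days, strong hospital
#'   preference instrument, unobserved-severity confounding — the headline
#'   discriminating scenario (naive biased, IV approximately unbiased).
#' * `heterogeneous_frailty`: overall effect of 5 days with a -10 day
#'   modifier for severe frailty (sign reversal) and -3 for moderate
#'   frailty, emulating effect modification by frailty.
#' * `weak_instrument`: hospital preference nearly irrelevant, used to
#'   confirm that the first-stage F statistic flags a weak instrument
#'   (F < 10).
#'
#' @param name One of `null_effect`, `unconfounded`, `strong_iv_confounded`,
#'   `heterogeneous_frailty`, `weak_instrument`.
#' @param ... Overrides passed on to [sim_config()] (e.g. `seed`).
#' @return A `sim_config`.
#' @export
scenario_presets <- function(name, ...) {
  presets <- list(
    null_effect = list(ate_days = 0),
    unconfounded = list(confounding_strength = 0),
    strong_iv_confounded = list(),
    heterogeneous_frailty = list(
      effect_by_frailty = c(fit = 0, mild = 0, moderate = -3, severe = -10)),
    weak_instrument = list(instrument_strength = 0.005)
  )
  if (!name %in% names(presets)) {
    abort(sprintf("unknown preset '%s'; valid presets: %s", name,
                  paste(names(presets), collapse = ", ")),
          class = "emergiv_lookup_error")
  }
  do.call(sim_config, utils::modifyList(presets[[name]], list(...)))
}

# Emitted diagnosis code for a prefix: prefix + "X" matches its own prefix
# and (by construction of the default map) no other condition or deficit.
emit_code <- function(prefix) paste0(prefix, "X")

#' Generate a synthetic admission dataset with known ground truth
#'
#' Draws hospitals, admissions, case-mix, treatment assignment and both
#' potential spell trajectories under `config`, emits the realised arm as
#' coded admission records, and returns the latent truth (per-admission
#' unobserved severity, true propensity and true effect on DAOH, plus the
#' dataset-level true average and subgroup effects over the eligible
#' index-window admissions).
#'
#' @param config A [sim_config()].
#' @return A list of class `emergiv_sim` with elements `data` (an
#'   [admission_data()] object), `truth` (per-admission tibble plus
#'   `true_ate` and `true_cate`), and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  spec <- default_condition_specs()[[cfg$condition]]
  map <- validate_code_map(cfg$code_map)
  start <- cfg$study_start; end <- cfg$study_end
  span <- end - start
  index_days <- span - 365
  H <- cfg$n_hospitals
  hosp_ids <- sprintf("H%03d", seq_len(H))
  alpha <- rnorm(H, 0, cfg$preference_spread)

  n_h <- rpois(H, cfg$admissions_per_hospital * span / index_days)
  N <- sum(n_h)
  hosp <- rep.int(seq_len(H), n_h)
  date <- start + sample.int(span, N, replace = TRUE) - 1L

  age <- pmin(95, pmax(18, round(rnorm(N, cfg$age_mean, cfg$age_sd))))
  sex <- ifelse(rbinom(N, 1, cfg$female_prob) == 1, "F", "M")
  ethnicity <- sample(c("white", "black", "asian", "mixed", "other"), N,
                      replace = TRUE, prob = c(0.80, 0.05, 0.08, 0.03, 0.04))
  imd <- sample.int(5, N, replace = TRUE)
  U <- rnorm(N)

  # deliberately ineligible fractions (mutually exclusive categories)
  inel <- cfg$ineligible
  cat_p <- c(inel$age_under18, inel$elective, inel$other_method,
             inel$late_episode, inel$nonsurgical)
  r <- runif(N)
  cum <- cumsum(cat_p)
  flag <- rep("eligible", N)
  labs <- c("age_under18", "elective", "other_method", "late_episode", "nonsurgical")
  lo <- c(0, cum[-length(cum)])
  for (k in seq_along(labs)) flag[r >= lo[k] & r < cum[k]] <- labs[k]
  age[flag == "age_under18"] <- sample(5:17, sum(flag == "age_under18"), replace = TRUE)
  method <- rep(NA_character_, N)
  em_mix <- sample(c("emergency_ed", "emergency_gp"), N, replace = TRUE,
                   prob = c(0.75, 0.25))
  method <- em_mix
  method[flag == "elective"] <- "elective"
  method[flag == "other_method"] <- "other"

  age_z <- (age - cfg$age_mean) / cfg$age_sd

  # deficits and comorbidities (logit-scale shifts by age and severity U)
  dl <- cfg$deficit_model
  nD <- length(cfg$deficit_prevalence)
  p_def <- stats::plogis(
    matrix(stats::qlogis(cfg$deficit_prevalence), N, nD, byrow = TRUE) +
      dl$age_loading * age_z + dl$u_loading * U)
  def_mat <- matrix(runif(N * nD), N, nD) < p_def
  def_count <- as.integer(rowSums(def_mat))
  frail_cat <- frailty_category(def_count)

  cl <- cfg$comorbidity_model
  nC <- length(cfg$comorbidity_prevalence)
  p_com <- stats::plogis(
    matrix(stats::qlogis(cfg$comorbidity_prevalence), N, nC, byrow = TRUE) +
      cl$age_loading * age_z)
  com_mat <- matrix(runif(N * nC), N, nC) < p_com

  # treatment assignment (probit): hospital preference is the instrument
  tm <- cfg$treat_model
  mean_def <- sum(cfg$deficit_prevalence)
  lat <- tm$intercept + cfg$instrument_strength * alpha[hosp] +
    tm$age_loading * age_z + tm$frailty_loading * (def_count - mean_def) +
    cfg$confounding_strength * U
  prop <- pnorm(lat)
  trt <- rbinom(N, 1, prop) == 1

  # death (treatment-independent), potential lengths of stay, re-admission
  dm <- cfg$death_model
  p_death <- pnorm(dm$intercept + dm$age_loading * age_z +
                     dm$frailty_loading * def_count + dm$u_loading * U)
  died <- rbinom(N, 1, p_death) == 1
  death_off <- sample.int(90, N, replace = TRUE) - 1L

  lm_ <- cfg$los_model
  los0 <- pmin(89L, 1L + as.integer(floor(rlnorm(
    N, lm_$meanlog + lm_$age_loading * age_z +
      lm_$frailty_loading * def_count + lm_$u_loading * U, lm_$sdlog))))
  eff <- cfg$ate_days + cfg$effect_by_frailty[as.character(frail_cat)]
  los1 <- pmin(89L, pmax(1L, los0 - as.integer(round(eff))))

  rm_ <- cfg$readmit_model
  readm <- rbinom(N, 1, stats::plogis(stats::qlogis(rm_$base_prob) +
                                        rm_$u_loading * U)) == 1
  gap <- sample.int(rm_$max_gap + 1L, N, replace = TRUE) - 1L
  rlos <- 1L + as.integer(floor(rlnorm(N, rm_$los_meanlog, rm_$los_sdlog)))

  death_date <- ifelse(died, date + death_off, NA_integer_)

  # derived DAOH per arm from the (up to two) potential spells
  arm_daoh <- function(los_arm) {
    disch <- date + los_arm
    disch <- ifelse(died & death_off < los_arm, date + death_off, disch)
    re_start <- disch + gap
    has_re <- readm & (!died | death_date > re_start)
    re_disch <- re_start + rlos
    re_disch <- ifelse(died, pmin(re_disch, death_date), re_disch)
    hor_end <- date + 90L
    in1 <- pmin(disch, hor_end) - date
    in2 <- ifelse(has_re, pmax(0L, pmin(re_disch, hor_end) - pmin(re_start, hor_end)), 0L)
    daoh <- ifelse(died, 0L, 90L - in1 - in2)
    list(daoh = as.integer(daoh), disch = as.integer(disch),
         has_re = has_re, re_start = as.integer(re_start),
         re_disch = as.integer(re_disch))
  }
  arm0 <- arm_daoh(los0)
  arm1 <- arm_daoh(los1)
  true_effect <- arm1$daoh - arm0$daoh
  disch <- ifelse(trt, arm1$disch, arm0$disch)
  has_re <- ifelse(trt, arm1$has_re, arm0$has_re)
  re_start <- ifelse(trt, arm1$re_start, arm0$re_start)
  re_disch <- ifelse(trt, arm1$re_disch, arm0$re_disch)

  admission_id <- seq_len(N)
  patient_id <- sprintf("P%07d", seq_len(N))

  # prior relevant emergency admissions for a fraction of index rows
  can_prior <- which(date >= start + 395L)
  n_prior <- round(cfg$repeat_prior_frac * N)
  prior_rows <- if (n_prior > 0 && length(can_prior))
    sample(can_prior, min(n_prior, length(can_prior))) else integer(0)

  # ---- emitted records ----------------------------------------------------
  cond_code <- function(n) {
    pfx <- spec$include_codes[1L + (sample.int(length(spec$include_codes), n,
                                               replace = TRUE) - 1L)]
    emit_code(pfx)
  }
  main_code <- cond_code(N)
  # secondary (comorbidity + deficit) code string per admission
  sec_codes <- {
    all_emit <- c(vapply(map$charlson$prefixes, function(p) emit_code(p[1]), character(1)),
                  vapply(map$frailty$prefixes, function(p) emit_code(p[1]), character(1)))
    mat <- cbind(com_mat, def_mat)
    pieces <- lapply(seq_len(ncol(mat)), function(j)
      ifelse(mat[, j], all_emit[j], NA_character_))
    s <- do.call(paste, c(pieces, list(sep = "|")))
    s <- gsub("NA\\|", "", s)
    s <- sub("\\|NA$", "", s)
    s[s == "NA"] <- ""
    s
  }

  use_ep2 <- flag == "eligible" & runif(N) < cfg$diag_in_ep2_frac
  use_sf <- cfg$condition == "intestinal_obstruction" &
    flag == "eligible" & !use_ep2 & runif(N) < cfg$second_field_frac
  late_ep <- flag == "late_episode"
  nonsurg <- flag == "nonsurgical"

  ep1_main <- ifelse(use_ep2 | late_ep, "R69X",
                     ifelse(use_sf, "C18X", main_code))
  ep1_diag <- ifelse(use_sf, paste0("C18X|", main_code), ep1_main)
  ep1_diag <- ifelse(nzchar(sec_codes), paste0(ep1_diag, "|", sec_codes), ep1_diag)
  ep1_spec <- ifelse(use_ep2, "general_medicine",
                     ifelse(nonsurg, "general_medicine", "general_surgery"))
  # for ep2 carriers the qualifying (surgical) episode is number 2
  ep2_rows <- which(use_ep2 | late_ep)
  ep2_diag <- ifelse(use_ep2[ep2_rows], main_code[ep2_rows], "R10X")
  ep2_spec <- ifelse(use_ep2[ep2_rows], ifelse(nonsurg[ep2_rows],
                                               "general_medicine",
                                               "general_surgery"),
                     "general_medicine")
  ep3_rows <- which(late_ep)

  episodes <- tibble(
    admission_id = c(admission_id, admission_id[ep2_rows], admission_id[ep3_rows]),
    episode_order = c(rep(1L, N), rep(2L, length(ep2_rows)), rep(3L, length(ep3_rows))),
    specialty = c(ep1_spec, ep2_spec, rep("general_surgery", length(ep3_rows))),
    diag_codes = c(ep1_diag, ep2_diag, main_code[ep3_rows])
  )

  # procedures
  stay <- disch - date
  win <- if (is.infinite(spec$es_window_days)) stay else
    pmin(spec$es_window_days, stay)
  proc_day <- as.integer(floor(runif(N) * (pmax(win, 0L) + 1L)))
  proc_day <- pmin(proc_day, stay)
  es_code <- emit_code(spec$es_procedure_codes[
    1L + (sample.int(length(spec$es_procedure_codes), N, replace = TRUE) - 1L)])
  treated_rows <- which(trt)
  # late qualifying procedures among untreated (stay beyond the window)
  can_late <- which(!trt & is.finite(spec$es_window_days) &
                      stay > spec$es_window_days)
  late_rows <- can_late[runif(length(can_late)) < cfg$late_procedure_frac]
  late_day <- spec$es_window_days + 1L +
    as.integer(floor(runif(length(late_rows)) *
                       (stay[late_rows] - spec$es_window_days)))
  late_day <- pmin(late_day, stay[late_rows])
  nq_rows <- which(!trt & runif(N) < cfg$nonqualifying_procedure_frac)
  procedures <- tibble(
    admission_id = c(admission_id[treated_rows], admission_id[late_rows],
                     admission_id[nq_rows]),
    code = c(es_code[treated_rows], es_code[late_rows],
             rep("X99X", length(nq_rows))),
    date = c(date[treated_rows] + proc_day[treated_rows],
             date[late_rows] + late_day,
             date[nq_rows])
  )

  admissions <- tibble(
    admission_id = admission_id,
    patient_id = patient_id,
    hospital_id = hosp_ids[hosp],
    admission_method = method,
    admission_date = as.integer(date),
    discharge_date = as.integer(disch),
    age = as.numeric(age),
    sex = sex,
    ethnicity = ethnicity,
    imd_quintile = as.integer(imd),
    death_date = as.integer(death_date)
  )

  next_id <- N
  # re-admission spells for the realised arm
  re_rows <- which(as.logical(has_re))
  if (length(re_rows)) {
    re_ids <- next_id + seq_along(re_rows)
    next_id <- next_id + length(re_rows)
    admissions <- bind_rows(admissions, tibble(
      admission_id = re_ids,
      patient_id = patient_id[re_rows],
      hospital_id = hosp_ids[hosp[re_rows]],
      admission_method = "emergency_ed",
      admission_date = as.integer(re_start[re_rows]),
      discharge_date = as.integer(re_disch[re_rows]),
      age = as.numeric(age[re_rows]),
      sex = sex[re_rows],
      ethnicity = ethnicity[re_rows],
      imd_quintile = as.integer(imd[re_rows]),
      death_date = as.integer(death_date[re_rows])
    ))
    episodes <- bind_rows(episodes, tibble(
      admission_id = re_ids, episode_order = 1L,
      specialty = "general_surgery", diag_codes = "R10X"))
  }

  # prior relevant emergency admissions (exclude their index rows)
  if (length(prior_rows)) {
    pr_ids <- next_id + seq_along(prior_rows)
    next_id <- next_id + length(prior_rows)
    pr_date <- date[prior_rows] -
      (30L + as.integer(floor(runif(length(prior_rows)) * 335)))
    pr_trt <- runif(length(prior_rows)) <
      pnorm(tm$intercept + cfg$instrument_strength * alpha[hosp[prior_rows]])
    pr_los <- 2L + as.integer(floor(runif(length(prior_rows)) * 5))
    admissions <- bind_rows(admissions, tibble(
      admission_id = pr_ids,
      patient_id = patient_id[prior_rows],
      hospital_id = hosp_ids[hosp[prior_rows]],
      admission_method = "emergency_ed",
      admission_date = as.integer(pr_date),
      discharge_date = as.integer(pr_date + pr_los),
      age = as.numeric(pmax(18, age[prior_rows] - 1L)),
      sex = sex[prior_rows],
      ethnicity = ethnicity[prior_rows],
      imd_quintile = as.integer(imd[prior_rows]),
      death_date = as.integer(death_date[prior_rows])
    ))
    episodes <- bind_rows(episodes, tibble(
      admission_id = pr_ids, episode_order = 1L,
      specialty = "general_surgery", diag_codes = cond_code(length(pr_ids))))
    if (any(pr_trt)) {
      pw <- which(pr_trt)
      pr_day <- as.integer(floor(runif(length(pw)) *
                                   (pmin(if (is.finite(spec$es_window_days))
                                     spec$es_window_days else pr_los[pw],
                                     pr_los[pw]) + 1L)))
      pr_day <- pmin(pr_day, pr_los[pw])
      procedures <- bind_rows(procedures, tibble(
        admission_id = pr_ids[pw],
        code = emit_code(spec$es_procedure_codes[
          1L + (sample.int(length(spec$es_procedure_codes), length(pw),
                           replace = TRUE) - 1L)]),
        date = as.integer(pr_date[pw] + pr_day)
      ))
    }
  }

  data <- admission_data(admissions, episodes, procedures, validate = FALSE)

  intended_eligible <- flag == "eligible"
  intended_eligible[prior_rows] <- FALSE
  in_index <- date >= start + 365L
  per_adm <- tibble(
    admission_id = admission_id,
    hospital_id = hosp_ids[hosp],
    U = U,
    true_propensity = prop,
    es = trt,
    true_effect_days = as.numeric(true_effect),
    frailty_category = frail_cat,
    age_band = age_band(age),
    eligible = intended_eligible,
    in_index_window = in_index
  )
  truth <- latent_truth(per_adm)
  structure(list(data = data, truth = truth, config = cfg),
            class = "emergiv_sim")
}

# Build a LatentTruth object from a per-admission truth table.
latent_truth <- function(per_adm) {
  eligible <- per_adm$eligible & per_adm$in_index_window
  tr <- true_effects_impl(per_adm[eligible, , drop = FALSE])
  structure(list(per_admission = per_adm,
                 true_ate = tr$true_ate,
                 true_cate = tr$true_cate),
            class = "latent_truth")
}

true_effects_impl <- function(pa) {
  cate_by <- function(var) {
    levs <- levels(pa[[var]])
    est <- vapply(levs, function(l) {
      m <- pa[[var]] == l
      if (!any(m)) NA_real_ else mean(pa$true_effect_days[m])
    }, numeric(1))
    n <- vapply(levs, function(l) sum(pa[[var]] == l), integer(1))
    tibble(level = levs, true_cate = unname(est), n = unname(n))
  }
  list(true_ate = if (nrow(pa)) mean(pa$true_effect_days) else NA_real_,
       true_cate = list(frailty_category = cate_by("frailty_category"),
                        age_band = cate_by("age_band")))
}

#' Summarise true treatment effects from a generated dataset
#'
#' Averages per-person true effects on DAOH, overall and by frailty
#' category and age band, over the eligible index-window admissions (or
#' over a supplied set of admission ids, e.g. an analysis cohort).
#' Subgroups with no members are reported as missing, not zero.
#'
#' @param truth The `truth` element of a [generate_dataset()] result.
#' @param ids Optional admission ids to restrict to.
#' @return A list with `true_ate` (days) and `true_cate` (tibbles by
#'   frailty category and age band).
#' @export
true_effects <- function(truth, ids = NULL) {
  pa <- truth$per_admission
  if (is.null(ids)) {
    pa <- pa[pa$eligible & pa$in_index_window, , drop = FALSE]
  } else {
    pa <- pa[pa$admission_id %in% ids, , drop = FALSE]
  }
  true_effects_impl(pa)
}

#' Write a simulated dataset to CSV files
#'
#' Writes the admission tables (see [write_admission_data()]), the
#' per-admission truth sidecar `truth.csv` keyed by admission id, and the
#' configuration as `config.yaml`.
#'
#' @param sim An `emergiv_sim` from [generate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  write_admission_data(sim$data, dir)
  write.csv(sim$truth$per_admission, file.path(dir, "truth.csv"),
            row.names = FALSE)
  cfg <- sim$config
  cfg$effect_by_frailty <- as.list(cfg$effect_by_frailty)
  cfg$code_map <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
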