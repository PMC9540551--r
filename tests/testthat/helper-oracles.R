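# Independent brute-force oracles used to cross-check the vectorised
# implementations, plus small fixture builders.

# Day-by-day occupancy scan: number of days in [index, index + horizon)
# covered by any spell (half-open [admit, discharge)).
oracle_los <- function(spells, index_start, horizon = 90) {
  days <- index_start:(index_start + horizon - 1)
  covered <- vapply(days, function(d) {
    any(spells$admit <= d & d < spells$discharge)
  }, logical(1))
  sum(covered)
}

oracle_daoh <- function(spells, death_date, index_start, horizon = 90,
                        variant = "main") {
  end <- index_start + horizon
  died <- !is.na(death_date) && death_date < end
  if (!died) return(horizon - oracle_los(spells, index_start, horizon))
  if (variant == "main") return(0L)
  days <- index_start:(min(death_date, end) - 1)
  if (length(days) == 0 || min(death_date, end) <= index_start) return(0L)
  alive_out <- vapply(days, function(d) {
    !any(spells$admit <= d & d < spells$discharge)
  }, logical(1))
  sum(alive_out)
}

# Random spell fixture around an index admission at day 0.
random_spell_fixture <- function() {
  n_extra <- sample(0:3, 1)
  idx_los <- sample(0:40, 1)
  spells <- data.frame(admit = 0, discharge = idx_los)
  if (n_extra > 0) {
    a <- sample(0:110, n_extra, replace = TRUE)
    len <- sample(0:30, n_extra, replace = TRUE)
    spells <- rbind(spells, data.frame(admit = a, discharge = a + len))
  }
  death <- if (runif(1) < 0.3) sample(0:120, 1) else NA
  list(spells = spells, death = death)
}

# Brute-force Charlson score: loop conditions, loop codes.
oracle_charlson <- function(codes, map) {
  codes <- toupper(gsub(".", "", codes, fixed = TRUE))
  score <- 0L
  for (i in seq_len(nrow(map$charlson))) {
    hit <- FALSE
    for (cd in codes) {
      for (p in map$charlson$prefixes[[i]]) {
        if (startsWith(cd, p)) hit <- TRUE
      }
    }
    if (hit) score <- score + map$charlson$weight[i]
  }
  score
}

oracle_deficits <- function(codes, map) {
  codes <- toupper(gsub(".", "", codes, fixed = TRUE))
  count <- 0L
  for (i in seq_len(nrow(map$frailty))) {
    hit <- FALSE
    for (cd in codes) {
      for (p in map$frailty$prefixes[[i]]) {
        if (startsWith(cd, p)) hit <- TRUE
      }
    }
    if (hit) count <- count + 1L
  }
  count
}

# Textbook restricted-vs-unrestricted sum-of-squares F for a single added
# regressor (the instrument) in a linear model.
oracle_partial_F <- function(y, z, X) {
  Xr <- cbind(1, X)
  Xu <- cbind(1, z, X)
  rss <- function(M) sum(stats::lm.fit(M, y)$residuals^2)
  rss_r <- rss(Xr); rss_u <- rss(Xu)
  df2 <- length(y) - ncol(Xu)
  (rss_r - rss_u) / (rss_u / df2)
}

# Brute-force eligibility scan over a small admission dataset: applies the
# rules one admission at a time, independently of build_cohort's vectorised
# path.
oracle_cohort <- function(data, spec, index_start, index_end, min_age = 18) {
  adm <- data$admissions
  keep <- list()
  for (i in seq_len(nrow(adm))) {
    a <- adm[i, ]
    if (a$admission_date < index_start || a$admission_date >= index_end) next
    if (is.na(a$age) || a$age < min_age) next
    if (!a$admission_method %in% c("emergency_ed", "emergency_gp")) next
    eps <- data$episodes[data$episodes$admission_id == a$admission_id &
                           data$episodes$episode_order <= 2, ]
    qual_ep <- NA
    for (j in seq_len(nrow(eps))) {
      cds <- strsplit(eps$diag_codes[j], "|", fixed = TRUE)[[1]]
      main <- toupper(gsub(".", "", cds[1], fixed = TRUE))
      ok <- any(vapply(spec$include_codes, function(p) startsWith(main, p),
                       logical(1)))
      if (!ok && !is.null(spec$second_field_rule) && length(cds) >= 2) {
        sec <- toupper(gsub(".", "", cds[2], fixed = TRUE))
        main_alt <- any(vapply(spec$second_field_rule$main_prefixes,
                               function(p) startsWith(main, p), logical(1)))
        sec_rel <- any(vapply(spec$include_codes,
                              function(p) startsWith(sec, p), logical(1)))
        ok <- main_alt && sec_rel
      }
      if (ok && eps$specialty[j] %in% c("general_surgery",
                                        "general_surgery_subspecialty",
                                        "other_surgery")) {
        qual_ep <- eps$episode_order[j]
        break
      }
    }
    if (is.na(qual_ep)) next
    # prior relevant emergency admission (same diagnosis rule) within window
    prior <- FALSE
    others <- adm[adm$patient_id == a$patient_id &
                    adm$admission_id != a$admission_id, ]
    for (k in seq_len(nrow(others))) {
      o <- others[k, ]
      if (!o$admission_method %in% c("emergency_ed", "emergency_gp")) next
      gap <- a$admission_date - o$admission_date
      if (gap <= 0 || gap > spec$lookback_exclusion_days) next
      oe <- data$episodes[data$episodes$admission_id == o$admission_id &
                            data$episodes$episode_order <= 2, ]
      for (j in seq_len(nrow(oe))) {
        cds <- strsplit(oe$diag_codes[j], "|", fixed = TRUE)[[1]]
        main <- toupper(gsub(".", "", cds[1], fixed = TRUE))
        ok <- any(vapply(spec$include_codes, function(p) startsWith(main, p),
                         logical(1)))
        if (!ok && !is.null(spec$second_field_rule) && length(cds) >= 2) {
          sec <- toupper(gsub(".", "", cds[2], fixed = TRUE))
          ok <- any(vapply(spec$second_field_rule$main_prefixes,
                           function(p) startsWith(main, p), logical(1))) &&
            any(vapply(spec$include_codes, function(p) startsWith(sec, p),
                       logical(1)))
        }
        if (ok) prior <- TRUE
      }
    }
    if (prior) next
    # ES classification
    prs <- data$procedures[data$procedures$admission_id == a$admission_id, ]
    es <- FALSE; dts <- NA
    for (j in seq_len(nrow(prs))) {
      cd <- toupper(gsub(".", "", prs$code[j], fixed = TRUE))
      if (!any(vapply(spec$es_procedure_codes, function(p) startsWith(cd, p),
                      logical(1)))) next
      d <- prs$date[j] - a$admission_date
      within <- if (is.infinite(spec$es_window_days)) {
        prs$date[j] <= a$discharge_date
      } else d <= spec$es_window_days
      if (within) {
        es <- TRUE
        dts <- min(dts, d, na.rm = TRUE)
      }
    }
    keep[[length(keep) + 1]] <- data.frame(
      admission_id = a$admission_id, es = es,
      days_to_surgery = if (es) dts else NA,
      qualifying_episode_order = qual_ep)
  }
  if (length(keep)) do.call(rbind, keep) else
    data.frame(admission_id = integer(0), es = logical(0),
               days_to_surgery = integer(0), qualifying_episode_order = integer(0))
}

# Minimal hand-built admission dataset factory for cohort tests.
make_admission <- function(id, patient = paste0("P", id), hospital = "H001",
                           method = "emergency_ed", admit = 400, los = 5,
                           age = 50, death = NA,
                           episodes = list(list(order = 1,
                                                specialty = "general_surgery",
                                                diag = "K35X")),
                           procedures = NULL) {
  adm <- data.frame(admission_id = id, patient_id = patient,
                    hospital_id = hospital, admission_method = method,
                    admission_date = admit, discharge_date = admit + los,
                    age = age, sex = "F", ethnicity = "white",
                    imd_quintile = 3L, death_date = death)
  ep <- do.call(rbind, lapply(episodes, function(e) {
    data.frame(admission_id = id, episode_order = e$order,
               specialty = e$specialty, diag_codes = e$diag)
  }))
  pr <- if (!is.null(procedures)) {
    do.call(rbind, lapply(procedures, function(p) {
      data.frame(admission_id = id, code = p$code, date = admit + p$day)
    }))
  }
  list(adm = adm, ep = ep, pr = pr)
}

bind_admissions <- function(...) {
  parts <- list(...)
  admission_data(
    do.call(rbind, lapply(parts, `[[`, "adm")),
    do.call(rbind, lapply(parts, `[[`, "ep")),
    {
      prs <- do.call(rbind, Filter(Negate(is.null), lapply(parts, `[[`, "pr")))
      if (is.null(prs)) NULL else prs
    }
  )
}
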