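# Outcome construction: days alive and out of hospital (DAOH), total length
# of stay, 90-day mortality and 30-day emergency re-admission.
#
# Conventions: dates are integer day offsets; a hospital spell occupies the
# half-open interval [admit, discharge), so a same-day discharge contributes
# zero in-hospital days and LOS = discharge - admission.

# Per-row interval-union lengths without grouped loops: shift each row's
# intervals into a disjoint coordinate block, then a single global sweep
# (sort + running maximum of earlier endpoints) unions every row at once.
union_length_by_row <- function(row, a, d, n_rows) {
  keep <- !is.na(a) & !is.na(d) & d > a
  row <- row[keep]; a <- as.numeric(a[keep]); d <- as.numeric(d[keep])
  out <- integer(n_rows)
  if (!length(row)) return(out)
  span <- max(d) - min(a) + 2
  a2 <- a + row * span
  d2 <- d + row * span
  o <- order(a2, d2)
  row <- row[o]; a2 <- a2[o]; d2 <- d2[o]
  run <- cummax(c(-Inf, d2[-length(d2)]))
  contrib <- pmax(0, d2 - pmax(a2, run))
  agg <- rowsum(contrib, row)
  out[as.integer(rownames(agg))] <- as.integer(agg[, 1])
  out
}

# Union length of half-open intervals intersected with [lo, hi).
interval_union_length <- function(admit, discharge, lo, hi) {
  a <- pmax(admit, lo)
  d <- pmin(discharge, hi)
  keep <- d > a
  a <- a[keep]; d <- d[keep]
  if (!length(a)) return(0L)
  o <- order(a, d)
  a <- a[o]; d <- d[o]
  total <- 0L
  cur_a <- a[1]; cur_d <- d[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] <= cur_d) {
      cur_d <- max(cur_d, d[i])
    } else {
      total <- total + (cur_d - cur_a)
      cur_a <- a[i]; cur_d <- d[i]
    }
  }
  as.integer(total + (cur_d - cur_a))
}

#' Total length of stay within a follow-up horizon
#'
#' Counts the distinct in-hospital days within `[index_start, index_start +
#' horizon)` across a patient's hospital spells, merging overlapping or
#' adjacent spells and truncating spells that cross the horizon.
#'
#' @param spells A data frame with columns `admit` and `discharge` (integer
#'   day offsets; half-open intervals), including the index admission.
#' @param index_start Day offset at which follow-up starts.
#' @param horizon Follow-up length in days (default 90).
#' @return Integer number of in-hospital days, between 0 and `horizon`.
#' @export
#' @examples
#' total_los(data.frame(admit = c(0, 20), discharge = c(5, 24)), 0)  # 9
total_los <- function(spells, index_start, horizon = 90) {
  stopifnot(horizon > 0)
  if (any(spells$discharge < spells$admit)) {
    abort("spell with discharge before admission")
  }
  interval_union_length(spells$admit, spells$discharge,
                        index_start, index_start + horizon)
}

#' Days alive and out of hospital
#'
#' Computes DAOH over a fixed horizon from a patient's hospital spells and
#' death date. Under the main definition, patients who die within the
#' horizon are assigned zero DAOH; survivors get `horizon` minus their
#' total LOS. Under the `count_days_for_decedents` sensitivity variant,
#' decedents instead get the count of days on which they were alive and out
#' of hospital between the index date and death; survivors are identical
#' under both variants.
#'
#' @inheritParams total_los
#' @param death_date Day offset of death, or `NA` if alive.
#' @param variant `"main"` (default) or `"count_days_for_decedents"`.
#' @return Integer DAOH in `[0, horizon]`.
#' @export
#' @examples
#' sp <- data.frame(admit = 0, discharge = 9)
#' daoh(sp, death_date = NA, index_start = 0)            # 81
#' daoh(sp, death_date = 10, index_start = 0)            # 0
#' daoh(sp, death_date = 10, index_start = 0,
#'      variant = "count_days_for_decedents")            # 1
daoh <- function(spells, death_date, index_start, horizon = 90,
                 variant = c("main", "count_days_for_decedents")) {
  variant <- match.arg(variant)
  if (!is.na(death_date) && death_date < index_start) {
    abort("death before index admission start")
  }
  end <- index_start + horizon
  died <- !is.na(death_date) && death_date < end
  if (!died) {
    return(as.integer(horizon - total_los(spells, index_start, horizon)))
  }
  if (variant == "main") return(0L)
  # days alive and out of hospital within [index_start, death) (in-hospital
  # days up to death count as in hospital)
  alive_end <- min(death_date, end)
  in_hosp <- interval_union_length(spells$admit, spells$discharge,
                                   index_start, alive_end)
  as.integer((alive_end - index_start) - in_hosp)
}

#' Secondary outcomes for one index admission
#'
#' Derives 90-day all-cause mortality and 30-day emergency re-admission.
#' Mortality is death within `[index_start, index_start + horizon)`. The
#' re-admission clock starts at the index discharge: any admission with an
#' emergency method starting within `[discharge, discharge + 30)` counts.
#'
#' @param admissions A data frame of the patient's admissions with columns
#'   `admission_id`, `admission_method` and `admission_date`.
#' @param index_id Admission id of the index admission.
#' @param index_discharge Day offset of the index discharge.
#' @param death_date Day offset of death or `NA`.
#' @param index_start Day offset of the index admission.
#' @param horizon Mortality horizon in days (default 90).
#' @param readmit_days Re-admission window in days (default 30).
#' @return A list with logicals `mortality_90` and `readmit_30`.
#' @export
derive_secondary <- function(admissions, index_id, index_discharge,
                             death_date, index_start, horizon = 90,
                             readmit_days = 30) {
  mortality <- !is.na(death_date) && death_date >= index_start &&
    death_date < index_start + horizon
  em <- admissions$admission_method %in% c("emergency_ed", "emergency_gp")
  re <- admissions$admission_id != index_id & em &
    admissions$admission_date >= index_discharge &
    admissions$admission_date < index_discharge + readmit_days
  list(mortality_90 = mortality, readmit_30 = any(re))
}

#' Derive all outcomes for a cohort
#'
#' Appends `daoh_90`, `daoh_alt_90` (the count-days-for-decedents
#' sensitivity variant), `mortality_90`, `los_90` and `readmit_30` to a
#' cohort, gathering each patient's hospital spells from the full admission
#' dataset.
#'
#' @param data An [admission_data()] object.
#' @param cohort A cohort tibble from [build_cohort()] (needs
#'   `admission_id`, `patient_id`, `index_date`, `discharge_date`).
#' @param horizon Follow-up horizon in days (default 90).
#' @return The cohort with outcome columns appended.
#' @export
derive_outcomes <- function(data, cohort, horizon = 90) {
  adm <- data$admissions
  death <- adm$death_date[match(cohort$admission_id, adm$admission_id)]
  if (is.null(adm$death_date)) death <- rep(NA_integer_, nrow(cohort))
  end <- cohort$index_date + horizon

  # All (cohort row, spell) pairs overlapping the follow-up window.
  idx <- tibble(row = seq_len(nrow(cohort)),
                patient_id = cohort$patient_id,
                index_date = cohort$index_date)
  sp <- inner_join(idx,
                   adm[, c("patient_id", "admission_id", "admission_method",
                           "admission_date", "discharge_date")],
                   by = "patient_id", relationship = "many-to-many")
  sp$a <- pmax(sp$admission_date, sp$index_date)
  sp$d <- pmin(sp$discharge_date, sp$index_date + horizon)
  los <- union_length_by_row(sp$row, sp$a, sp$d, nrow(cohort))

  died <- !is.na(death) & death < end
  cohort$los_90 <- los
  cohort$mortality_90 <- died
  cohort$daoh_90 <- as.integer(ifelse(died, 0L, horizon - los))

  # Sensitivity variant: decedents count days alive and out of hospital.
  alt <- cohort$daoh_90
  if (any(died)) {
    dr <- which(died)
    alive_end <- pmin(death, end)
    spd <- sp[died[sp$row], , drop = FALSE]
    spd$a2 <- pmax(spd$admission_date, spd$index_date)
    spd$d2 <- pmin(spd$discharge_date, alive_end[spd$row])
    ih <- union_length_by_row(spd$row, spd$a2, spd$d2, nrow(cohort))
    alt[dr] <- as.integer((alive_end[dr] - cohort$index_date[dr]) - ih[dr])
  }
  cohort$daoh_alt_90 <- alt

  # 30-day emergency re-admission, clock starting at index discharge.
  em <- sp$admission_method %in% c("emergency_ed", "emergency_gp")
  disch <- cohort$discharge_date[sp$row]
  own <- sp$admission_id == cohort$admission_id[sp$row]
  re <- em & !own & sp$admission_date >= disch & sp$admission_date < disch + 30
  readm <- logical(nrow(cohort))
  readm[unique(sp$row[re])] <- TRUE
  cohort$readmit_30 <- readm
  cohort
}
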