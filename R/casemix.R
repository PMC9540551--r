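#' Charlson comorbidity index from diagnosis codes
#'
#' Scores a vector of diagnosis codes against a Charlson code map. Each
#' comorbidity counts at most once however many codes map to it; the score
#' is the sum of the weights of the comorbidities present; the band
#' collapses scores of three or more into `"3+"`.
#'
#' @param codes Character vector of diagnosis codes (index admission plus
#'   lookback admissions).
#' @param map A code map, see [default_code_map()].
#' @return A list with integer `score` and factor `band`
#'   (levels `0`, `1`, `2`, `3+`).
#' @export
#' @examples
#' charlson_index(c("I219", "I500", "I501"), default_code_map())
charlson_index <- function(codes, map = default_code_map()) {
  map <- validate_code_map(map)
  present <- vapply(map$charlson$prefixes,
                    function(p) any(match_any_prefix(codes, p)), logical(1))
  score <- as.integer(sum(map$charlson$weight[present]))
  list(score = score, band = charlson_band(score))
}

#' @rdname charlson_index
#' @param score Integer Charlson score(s).
#' @export
charlson_band <- function(score) {
  factor(ifelse(score >= 3, "3+", as.character(score)),
         levels = c("0", "1", "2", "3+"))
}

#' Deficit count for the administrative-records frailty index
#'
#' Counts the number of distinct frailty deficits with at least one
#' matching diagnosis code. Multiple codes within one deficit count once.
#'
#' @inheritParams charlson_index
#' @return Integer deficit count (0 to the number of configured deficits).
#' @export
#' @examples
#' frailty_deficit_count(c("R54X", "R541", "F050"), default_code_map())  # 2
frailty_deficit_count <- function(codes, map = default_code_map()) {
  map <- validate_code_map(map)
  present <- vapply(map$frailty$prefixes,
                    function(p) any(match_any_prefix(codes, p)), logical(1))
  as.integer(sum(present))
}

#' Frailty category from a deficit count
#'
#' Bands the deficit count into fit / mild / moderate / severe frailty.
#' Severe frailty is the presence of six or more deficits; the lower
#' cut-points default to fit = 0, mild = 1-2, moderate = 3-5 and are
#' configurable.
#'
#' @param count Integer vector of deficit counts.
#' @param cuts Upper bounds (inclusive) of the fit, mild and moderate
#'   categories; default `c(0, 2, 5)`.
#' @return Factor with levels `fit`, `mild`, `moderate`, `severe`.
#' @export
#' @examples
#' frailty_category(c(0, 2, 4, 6))
frailty_category <- function(count, cuts = c(0, 2, 5)) {
  if (any(is.na(count)) || any(count < 0)) {
    abort("deficit counts must be non-negative and non-missing")
  }
  if (length(cuts) != 3L || is.unsorted(cuts)) {
    stop_config("cuts", "must be three non-decreasing upper bounds")
  }
  cut(count, breaks = c(-Inf, cuts, Inf),
      labels = c("fit", "mild", "moderate", "severe"))
}

# Collect, per cohort row, all diagnosis codes from the index admission and
# from the same patient's admissions starting in the lookback window.
# Returns a flat representation: normalised `codes` plus the cohort row
# index `row_of` each code belongs to.
collect_casemix_codes <- function(data, cohort, lookback_days = 365L) {
  adm <- data$admissions[, c("admission_id", "patient_id", "admission_date")]
  idx <- tibble(row = seq_len(nrow(cohort)),
                admission_id = cohort$admission_id,
                patient_id = cohort$patient_id,
                index_date = cohort$index_date)
  pairs <- inner_join(idx, adm, by = "patient_id",
                      suffix = c("", "_other"), relationship = "many-to-many")
  pairs <- pairs[pairs$admission_id_other == pairs$admission_id |
                   (pairs$admission_date >= pairs$index_date - lookback_days &
                      pairs$admission_date < pairs$index_date), ,
                 drop = FALSE]
  ep <- data$episodes[, c("admission_id", "diag_codes")]
  epj <- inner_join(pairs[, c("row", "admission_id_other")], ep,
                    by = c(admission_id_other = "admission_id"),
                    relationship = "many-to-many")
  parts <- strsplit(epj$diag_codes, "|", fixed = TRUE)
  list(codes = normalize_codes(unlist(parts, use.names = FALSE)),
       row_of = rep(epj$row, lengths(parts)))
}

#' Derive case-mix measures for a cohort
#'
#' Appends the Charlson comorbidity score and band, the frailty deficit
#' count and the frailty category to a cohort, ascertained over the index
#' admission plus the patient's admissions in the preceding
#' `lookback_days`.
#'
#' @param data An [admission_data()] object (must include lookback-period
#'   admissions).
#' @param cohort A cohort tibble from [build_cohort()].
#' @param map Code map, see [default_code_map()].
#' @param lookback_days Ascertainment lookback in days (default 365).
#' @param cuts Frailty category cut-points, see [frailty_category()].
#' @return The cohort with columns `charlson_score`, `charlson_band`,
#'   `deficit_count` and `frailty_category` appended.
#' @export
derive_casemix <- function(data, cohort, map = default_code_map(),
                           lookback_days = 365L, cuts = c(0, 2, 5)) {
  map <- validate_code_map(map)
  cc <- collect_casemix_codes(data, cohort, lookback_days)
  # Flat code vector scanned per condition/deficit with vectorised
  # startsWith over all rows simultaneously.
  n <- nrow(cohort)
  flat <- cc$codes
  row_of <- cc$row_of
  group_hit <- function(prefixes) {
    m <- rep(FALSE, length(flat))
    for (p in prefixes) m <- m | startsWith(flat, p)
    hit <- logical(n)
    hit[row_of[m]] <- TRUE
    hit
  }
  score <- integer(n)
  for (i in seq_len(nrow(map$charlson))) {
    score <- score + map$charlson$weight[i] * group_hit(map$charlson$prefixes[[i]])
  }
  defc <- integer(n)
  for (i in seq_len(nrow(map$frailty))) {
    defc <- defc + group_hit(map$frailty$prefixes[[i]])
  }
  cohort$charlson_score <- as.integer(score)
  cohort$charlson_band <- charlson_band(score)
  cohort$deficit_count <- as.integer(defc)
  cohort$frailty_category <- frailty_category(defc, cuts)
  cohort
}
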