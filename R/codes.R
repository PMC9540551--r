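#' Default comorbidity and frailty code map
#'
#' Returns the code map used to derive the Charlson comorbidity index and
#' the deficit-accumulation frailty index from coded diagnoses. The Charlson
#' component lists 17 conditions with the classic 1/2/3/6 weights and
#' ICD-10-style code prefixes; the frailty component lists 32 deficits
#' spanning functional impairment, geriatric syndromes, nutrition, cognition
#' and mood, and medical comorbidity. Both lists are configurable: any map
#' with the same shape (for example one read with [read_code_map()]) can be
#' passed wherever a `code_map` argument is accepted. The shipped deficit
#' list is a synthetic default — the same map is used by the synthetic data
#' generator, so derivation is exercised end to end — and is intended to be
#' replaced with a locally validated list for real data.
#'
#' @return A list with two tibbles, `charlson` (condition, prefixes, weight)
#'   and `frailty` (deficit, prefixes).
#' @export
#' @examples
#' map <- default_code_map()
#' nrow(map$frailty)  # 32 deficits
default_code_map <- function() {
  charlson <- tibble::tribble(
    ~condition,                   ~prefixes,                        ~weight,
    "myocardial_infarction",      list(c("I21", "I22", "I252")),    1L,
    "heart_failure",              list("I50"),                      1L,
    "peripheral_vascular",        list(c("I70", "I71", "I731")),    1L,
    "cerebrovascular",            list(c("I60", "I61", "I63", "I64", "G45")), 1L,
    "dementia",                   list(c("F00", "F01", "F03", "G30")), 1L,
    "chronic_pulmonary",          list(c("J40", "J41", "J42", "J43", "J44", "J45", "J47")), 1L,
    "rheumatic",                  list(c("M05", "M06", "M32", "M33", "M34")), 1L,
    "peptic_ulcer",               list(c("K25", "K26", "K28")),     1L,
    "mild_liver",                 list(c("K70", "K73", "K74")),     1L,
    "diabetes",                   list(c("E100", "E110", "E119", "E140")), 1L,
    "diabetes_complications",     list(c("E102", "E112", "E142")),  2L,
    "hemiplegia",                 list(c("G81", "G82")),            2L,
    "renal",                      list(c("N18", "N19", "N052")),    2L,
    "malignancy",                 list(c("C0", "C1", "C2", "C3", "C4", "C6")), 2L,
    "severe_liver",               list(c("K721", "K729", "I85")),   3L,
    "metastatic_cancer",          list(c("C77", "C78", "C79")),     6L,
    "aids",                       list(c("B20", "B21", "B22", "B24")), 6L
  )
  frailty <- tibble::tribble(
    ~deficit,                ~prefixes,
    "activity_limitation",   list("Z74"),
    "anaemia",               list("D64"),
    "arthritis",             list("M19"),
    "cerebrovascular_seq",   list("I69"),
    "cognitive_impairment",  list("F06"),
    "delirium",              list("F05"),
    "syncope",               list("R55"),
    "care_dependence",       list("Z75"),
    "depression",            list("F32"),
    "diabetes_frailty",      list("E11"),
    "dizziness",             list("R42"),
    "falls",                 list("W19"),
    "foot_problems",         list("L97"),
    "fragility_fracture",    list("S72"),
    "hearing_impairment",    list("H91"),
    "chronic_pain",          list("R52"),
    "hypotension",           list("I95"),
    "urinary_incontinence",  list("R32"),
    "faecal_incontinence",   list("R15"),
    "malnutrition",          list("E46"),
    "memory_loss",           list("R41"),
    "mobility_problems",     list("R26"),
    "osteoporosis",          list("M81"),
    "parkinsonism",          list("G20"),
    "peptic_ulcer_frailty",  list("K27"),
    "pressure_ulcer",        list("L89"),
    "respiratory_failure",   list("J96"),
    "self_care_difficulty",  list("Z73"),
    "senility",              list("R54"),
    "sleep_disorder",        list("G47"),
    "visual_impairment",     list("H54"),
    "weight_loss",           list("R63")
  )
  charlson$prefixes <- lapply(seq_len(nrow(charlson)), function(i) normalize_codes(unlist(charlson$prefixes[i])))
  frailty$prefixes <- lapply(seq_len(nrow(frailty)), function(i) normalize_codes(unlist(frailty$prefixes[i])))
  validate_code_map(list(charlson = charlson, frailty = frailty))
}

#' Validate a code map
#'
#' Checks a code map for duplicate condition or deficit names, empty prefix
#' lists and non-positive Charlson weights.
#'
#' @param map A list with `charlson` and `frailty` data frames as produced
#'   by [default_code_map()] or [read_code_map()].
#' @return The validated map, invisibly classed as `emergiv_code_map`.
#' @export
validate_code_map <- function(map) {
  if (!is.list(map) || is.null(map$charlson) || is.null(map$frailty)) {
    stop_config("code_map", "must contain `charlson` and `frailty` tables")
  }
  ch <- map$charlson
  fr <- map$frailty
  if (nrow(ch) == 0L) stop_config("charlson", "code map is empty")
  if (anyDuplicated(ch$condition)) stop_config("charlson", "duplicate condition names")
  if (anyDuplicated(fr$deficit)) stop_config("frailty_deficits", "duplicate deficit names")
  if (any(ch$weight < 1)) stop_config("charlson", "weights must be >= 1")
  if (any(lengths(ch$prefixes) == 0L)) stop_config("charlson", "empty prefix list")
  if (any(lengths(fr$prefixes) == 0L)) stop_config("frailty_deficits", "empty prefix list")
  structure(map, class = c("emergiv_code_map", "list"))
}

#' Read or write a code map as YAML
#'
#' The on-disk format is a YAML mapping with `charlson` entries
#' (`name`, `prefixes`, `weight`) and `frailty` entries (`name`,
#' `prefixes`), so locally maintained code lists can be dropped in without
#' touching package code.
#'
#' @param path Path to a YAML file.
#' @return For `read_code_map()`, a validated code map; `write_code_map()`
#'   returns `path` invisibly.
#' @export
read_code_map <- function(path) {
  raw <- yaml::read_yaml(path)
  charlson <- tibble(
    condition = vapply(raw$charlson, `[[`, character(1), "name"),
    prefixes = lapply(raw$charlson, function(x) normalize_codes(unlist(x$prefixes))),
    weight = vapply(raw$charlson, function(x) as.integer(x$weight), integer(1))
  )
  frailty <- tibble(
    deficit = vapply(raw$frailty, `[[`, character(1), "name"),
    prefixes = lapply(raw$frailty, function(x) normalize_codes(unlist(x$prefixes)))
  )
  validate_code_map(list(charlson = charlson, frailty = frailty))
}

#' @rdname read_code_map
#' @param map A code map.
#' @export
write_code_map <- function(map, path) {
  map <- validate_code_map(map)
  out <- list(
    charlson = lapply(seq_len(nrow(map$charlson)), function(i) {
      list(name = map$charlson$condition[i],
           prefixes = as.list(map$charlson$prefixes[[i]]),
           weight = map$charlson$weight[i])
    }),
    frailty = lapply(seq_len(nrow(map$frailty)), function(i) {
      list(name = map$frailty$deficit[i],
           prefixes = as.list(map$frailty$prefixes[[i]]))
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
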