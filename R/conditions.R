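#' Window sentinel: a qualifying procedure any time within the admission
#'
#' For some conditions a qualifying procedure counts as emergency surgery at
#' any point during the emergency admission rather than within a fixed
#' number of days. Use `ANY_TIME` (infinity) as the window in that case.
#'
#' @export
ANY_TIME <- Inf

#' Define a condition-specific eligibility and treatment specification
#'
#' A condition spec carries everything needed to (a) recognise an eligible
#' index admission for one acute condition and (b) classify it as emergency
#' surgery (ES) versus a non-emergency strategy (NES): main-diagnosis code
#' prefixes, an optional second-diagnosis-field rule (used for intestinal
#' obstruction, where the relevant code may sit in the second field when the
#' main diagnosis is colorectal cancer), qualifying procedure code prefixes,
#' the maximum days from admission to a qualifying procedure, stricter
#' sensitivity-analysis variants of the procedure list and window, and the
#' prior-admission exclusion window.
#'
#' @param name Condition label.
#' @param include_codes Character vector of main-diagnosis code prefixes.
#' @param es_procedure_codes Character vector of qualifying procedure code
#'   prefixes.
#' @param es_window_days Maximum days from admission to a qualifying
#'   procedure, or [ANY_TIME].
#' @param second_field_rule Optional list with element `main_prefixes`: when
#'   the main diagnosis matches these prefixes, a relevant code in the
#'   second diagnosis field qualifies.
#' @param strict_es_procedure_codes Stricter procedure prefix list for the
#'   strict-codes sensitivity analysis; must be a subset of
#'   `es_procedure_codes`. Defaults to the main list.
#' @param strict_window_days Window used with the strict list; defaults to
#'   `es_window_days`.
#' @param lookback_exclusion_days Days before the index date within which a
#'   prior relevant emergency admission excludes the index admission
#'   (default 365).
#' @return An object of class `condition_spec`.
#' @export
#' @examples
#' spec <- condition_spec("appendicitis", include_codes = "K35",
#'                        es_procedure_codes = "H01", es_window_days = 7)
condition_spec <- function(name, include_codes, es_procedure_codes,
                           es_window_days,
                           second_field_rule = NULL,
                           strict_es_procedure_codes = es_procedure_codes,
                           strict_window_days = es_window_days,
                           lookback_exclusion_days = 365L) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_config("name", "must be a single non-empty string")
  }
  include_codes <- normalize_codes(include_codes)
  es_procedure_codes <- normalize_codes(es_procedure_codes)
  strict_es_procedure_codes <- normalize_codes(strict_es_procedure_codes)
  if (length(include_codes) == 0L) stop_config("include_codes", "must be non-empty")
  if (length(es_procedure_codes) == 0L) stop_config("es_procedure_codes", "must be non-empty")
  if (!is.numeric(es_window_days) || length(es_window_days) != 1L ||
      (is.finite(es_window_days) && es_window_days < 0)) {
    stop_config("es_window_days", "must be a non-negative number or ANY_TIME")
  }
  if (!all(strict_es_procedure_codes %in% es_procedure_codes)) {
    stop_config("strict_es_procedure_codes", "must be a subset of es_procedure_codes")
  }
  if (strict_window_days > es_window_days) {
    stop_config("strict_window_days", "must not exceed es_window_days")
  }
  if (!is.null(second_field_rule) && is.null(second_field_rule$main_prefixes)) {
    stop_config("second_field_rule", "must carry `main_prefixes`")
  }
  if (!is.null(second_field_rule)) {
    second_field_rule$main_prefixes <- normalize_codes(second_field_rule$main_prefixes)
  }
  structure(list(
    name = name,
    include_codes = include_codes,
    second_field_rule = second_field_rule,
    es_procedure_codes = es_procedure_codes,
    es_window_days = es_window_days,
    strict_es_procedure_codes = strict_es_procedure_codes,
    strict_window_days = strict_window_days,
    lookback_exclusion_days = as.integer(lookback_exclusion_days)
  ), class = "condition_spec")
}

#' Shipped condition specifications for the five acute conditions
#'
#' Returns condition specs for acute appendicitis, gallstone disease,
#' diverticular disease, abdominal wall hernia and intestinal obstruction.
#' The time windows are condition specific: a qualifying procedure must
#' occur within 3 days of admission for hernia, within 7 days for
#' appendicitis, gallstone disease and intestinal obstruction, and at any
#' time within the emergency admission for diverticular disease. For
#' intestinal obstruction a relevant code in the second diagnosis field also
#' qualifies when the main diagnosis is colorectal cancer. The diagnosis and
#' procedure code lists shipped here are synthetic defaults used by the
#' simulator; for real data, supply clinically curated lists via
#' [condition_spec()] or [read_condition_specs()].
#'
#' @return A named list of `condition_spec` objects.
#' @export
default_condition_specs <- function() {
  list(
    appendicitis = condition_spec(
      "appendicitis",
      include_codes = c("K35", "K36", "K37"),
      es_procedure_codes = c("H01", "H02", "H03"),
      es_window_days = 7,
      strict_es_procedure_codes = c("H01", "H02")
    ),
    gallstone_disease = condition_spec(
      "gallstone_disease",
      include_codes = "K80",
      es_procedure_codes = c("J18", "J21"),
      es_window_days = 7,
      strict_es_procedure_codes = "J18"
    ),
    diverticular_disease = condition_spec(
      "diverticular_disease",
      include_codes = "K57",
      es_procedure_codes = c("H33", "H15", "T46"),
      es_window_days = ANY_TIME,
      strict_es_procedure_codes = c("H33", "H15")
    ),
    hernia = condition_spec(
      "hernia",
      include_codes = c("K40", "K41", "K42", "K43", "K45", "K46"),
      es_procedure_codes = c("T19", "T20", "T21", "T22", "T23", "T24", "T25", "T26", "T27"),
      es_window_days = 3,
      strict_es_procedure_codes = c("T19", "T20", "T21", "T22")
    ),
    intestinal_obstruction = condition_spec(
      "intestinal_obstruction",
      include_codes = "K56",
      second_field_rule = list(main_prefixes = c("C18", "C19", "C20")),
      es_procedure_codes = c("G69", "H07", "H29", "T41"),
      es_window_days = 7,
      strict_es_procedure_codes = c("G69", "H07")
    )
  )
}

#' Read or write condition specifications as YAML
#'
#' @param path Path to a YAML file holding a named mapping of condition
#'   specs (fields as in [condition_spec()]; a window of `"any_time"` maps
#'   to [ANY_TIME]).
#' @return `read_condition_specs()` returns a named list of
#'   `condition_spec` objects; `write_condition_specs()` returns `path`
#'   invisibly.
#' @export
read_condition_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    x <- raw[[nm]]
    win <- x$es_window_days
    if (identical(win, "any_time")) win <- ANY_TIME
    swin <- x$strict_window_days %||% win
    if (identical(swin, "any_time")) swin <- ANY_TIME
    sfr <- x$second_field_rule
    condition_spec(
      name = x$name %||% nm,
      include_codes = unlist(x$include_codes),
      second_field_rule = if (!is.null(sfr)) list(main_prefixes = unlist(sfr$main_prefixes)),
      es_procedure_codes = unlist(x$es_procedure_codes),
      es_window_days = win,
      strict_es_procedure_codes = unlist(x$strict_es_procedure_codes %||% x$es_procedure_codes),
      strict_window_days = swin,
      lookback_exclusion_days = x$lookback_exclusion_days %||% 365L
    )
  })
  setNames(out, names(raw))
}

#' @rdname read_condition_specs
#' @param specs A named list of `condition_spec` objects.
#' @export
write_condition_specs <- function(specs, path) {
  ser <- lapply(specs, function(s) {
    win <- if (is.infinite(s$es_window_days)) "any_time" else s$es_window_days
    swin <- if (is.infinite(s$strict_window_days)) "any_time" else s$strict_window_days
    out <- list(
      name = s$name,
      include_codes = as.list(s$include_codes),
      es_procedure_codes = as.list(s$es_procedure_codes),
      es_window_days = win,
      strict_es_procedure_codes = as.list(s$strict_es_procedure_codes),
      strict_window_days = swin,
      lookback_exclusion_days = s$lookback_exclusion_days
    )
    if (!is.null(s$second_field_rule)) {
      out$second_field_rule <- list(main_prefixes = as.list(s$second_field_rule$main_prefixes))
    }
    out
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}
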