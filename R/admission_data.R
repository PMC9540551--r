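#' Construct a coded admission dataset
#'
#' Bundles the three relational tables that represent coded hospital
#' admissions, in the style of an administrative episode database:
#'
#' * `admissions`: one row per admission — `admission_id`, `patient_id`,
#'   `hospital_id`, `admission_method` (one of `emergency_ed`,
#'   `emergency_gp`, `elective`, `other`), `admission_date`,
#'   `discharge_date` (integer day offsets from a fixed epoch, intervals
#'   half-open `[admission, discharge)`), `age` (years at admission), `sex`,
#'   `ethnicity`, `imd_quintile` (1-5 deprivation quintile) and
#'   `death_date` (day offset or `NA`).
#' * `episodes`: one row per consultant episode — `admission_id`,
#'   `episode_order` (1-based, contiguous), `specialty`, and `diag_codes`,
#'   a pipe-delimited code string whose first position is the main
#'   diagnosis.
#' * `procedures`: one row per procedure — `admission_id`, `code`, `date`.
#'
#' @param admissions,episodes,procedures Data frames with the columns
#'   described above.
#' @param validate Check invariants (discharge after admission, contiguous
#'   episode orders, procedure dates within the admission, non-negative
#'   ages)? Default `TRUE`.
#' @return An object of class `admission_data`.
#' @export
admission_data <- function(admissions, episodes, procedures = NULL,
                           validate = TRUE) {
  if (is.null(procedures)) {
    procedures <- tibble(admission_id = integer(0), code = character(0),
                         date = integer(0))
  }
  x <- structure(list(admissions = as_tibble(admissions),
                      episodes = as_tibble(episodes),
                      procedures = as_tibble(procedures)),
                 class = "admission_data")
  if (validate) validate_admission_data(x) else x
}

#' Validate an admission dataset
#'
#' Checks the record-level invariants of [admission_data()]. Malformed
#' records are dropped with a warning naming the reason (record-level
#' rejection rather than a hard failure), except for structurally
#' impossible inputs such as missing columns, which are errors.
#'
#' @param x An `admission_data` object.
#' @return The validated (possibly filtered) `admission_data` object.
#' @export
validate_admission_data <- function(x) {
  adm <- x$admissions
  need <- c("admission_id", "patient_id", "hospital_id", "admission_method",
            "admission_date", "discharge_date", "age")
  miss <- setdiff(need, names(adm))
  if (length(miss)) {
    abort(sprintf("admissions table is missing columns: %s",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(adm$admission_id)) {
    abort("admission_id values must be unique")
  }
  bad <- rep(FALSE, nrow(adm))
  reason <- character(nrow(adm))
  b <- !is.na(adm$discharge_date) & adm$discharge_date < adm$admission_date
  reason[b & !bad] <- "discharge before admission"; bad <- bad | b
  b <- is.na(adm$age) | adm$age < 0
  reason[b & !bad] <- "invalid age"; bad <- bad | b
  if (!is.null(adm$death_date)) {
    b <- !is.na(adm$death_date) & adm$death_date < adm$admission_date
    reason[b & !bad] <- "death before admission"; bad <- bad | b
  }
  if (any(bad)) {
    warn(sprintf("dropping %d malformed admission record(s): %s", sum(bad),
                 paste(unique(reason[bad]), collapse = "; ")))
    adm <- adm[!bad, , drop = FALSE]
  }
  ep <- x$episodes
  ep <- ep[ep$admission_id %in% adm$admission_id, , drop = FALSE]
  ord_ok <- ep |>
    group_by(.data$admission_id) |>
    summarise(ok = all(sort(.data$episode_order) == seq_along(.data$episode_order)),
              .groups = "drop")
  if (!all(ord_ok$ok)) {
    bad_ids <- ord_ok$admission_id[!ord_ok$ok]
    warn(sprintf("dropping %d admission(s) with non-contiguous episode orders",
                 length(bad_ids)))
    adm <- adm[!adm$admission_id %in% bad_ids, , drop = FALSE]
    ep <- ep[!ep$admission_id %in% bad_ids, , drop = FALSE]
  }
  pr <- x$procedures
  pr <- pr[pr$admission_id %in% adm$admission_id, , drop = FALSE]
  if (nrow(pr)) {
    span <- adm[match(pr$admission_id, adm$admission_id),
                c("admission_date", "discharge_date")]
    b <- pr$date < span$admission_date | pr$date > span$discharge_date
    if (any(b)) {
      warn(sprintf("dropping %d procedure(s) dated outside their admission", sum(b)))
      pr <- pr[!b, , drop = FALSE]
    }
  }
  structure(list(admissions = adm, episodes = ep, procedures = pr),
            class = "admission_data")
}

#' @export
print.admission_data <- function(x, ...) {
  cat(sprintf(
    "<admission_data> %d admissions, %d patients, %d hospitals, %d episodes, %d procedures\n",
    nrow(x$admissions), length(unique(x$admissions$patient_id)),
    length(unique(x$admissions$hospital_id)), nrow(x$episodes),
    nrow(x$procedures)))
  invisible(x)
}

#' Write or read an admission dataset as CSV files
#'
#' Writes `admissions.csv`, `episodes.csv` and `procedures.csv` into `dir`.
#' All dates are integer day offsets; `diag_codes` is a pipe-delimited code
#' string with the main diagnosis first (see [admission_data()] for the
#' full column dictionary).
#'
#' @param x An `admission_data` object.
#' @param dir Directory to write into (created if needed).
#' @return `write_admission_data()` returns `dir` invisibly;
#'   `read_admission_data()` returns an `admission_data` object.
#' @export
write_admission_data <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$admissions, file.path(dir, "admissions.csv"), row.names = FALSE)
  write.csv(x$episodes, file.path(dir, "episodes.csv"), row.names = FALSE)
  write.csv(x$procedures, file.path(dir, "procedures.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_admission_data
#' @export
read_admission_data <- function(dir) {
  adm <- read.csv(file.path(dir, "admissions.csv"), stringsAsFactors = FALSE)
  ep <- read.csv(file.path(dir, "episodes.csv"), stringsAsFactors = FALSE)
  pr <- read.csv(file.path(dir, "procedures.csv"), stringsAsFactors = FALSE)
  admission_data(adm, ep, pr)
}
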