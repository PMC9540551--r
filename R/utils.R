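#' @keywords internal
"_PACKAGE"

#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats pnorm dnorm qnorm rnorm rbinom rlnorm rpois runif
#'   quantile sd var lm model.matrix binomial glm.fit lm.fit setNames
#'   complete.cases
#' @importFrom utils head write.csv read.csv
NULL

# Normalise clinical codes: uppercase, trim, strip dots ("K35.2" -> "K352").
normalize_codes <- function(x) {
  gsub(".", "", toupper(trimws(as.character(x))), fixed = TRUE)
}

# TRUE for each code that starts with any of the (already normalised)
# prefixes. Prefix matching is the standard way administrative code lists
# are specified.
match_any_prefix <- function(codes, prefixes) {
  if (length(codes) == 0L) return(logical(0))
  codes <- normalize_codes(codes)
  prefixes <- normalize_codes(prefixes)
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

# Split a pipe-delimited diagnosis string into a code vector.
split_codes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, "|", fixed = TRUE)[[1]]
}

# First code of a pipe-delimited string (the main diagnosis position).
first_code <- function(x) {
  out <- sub("\\|.*$", "", x)
  out[is.na(x) | !nzchar(x)] <- NA_character_
  out
}

# Second code, or NA when there is none.
second_code <- function(x) {
  has2 <- grepl("|", x, fixed = TRUE)
  out <- rep(NA_character_, length(x))
  out[has2] <- sub("^[^|]*\\|([^|]*).*$", "\\1", x[has2])
  out
}

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = "emergiv_config_error")
}

check_prob <- function(value, field) {
  if (!is.numeric(value) || anyNA(value) || any(value < 0) || any(value > 1)) {
    stop_config(field, "must be a probability (or vector of them) in [0, 1]")
  }
  invisible(value)
}

#' Assign age bands used throughout the analysis
#'
#' Bands adults into the five age strata used for case-mix adjustment and
#' subgroup reporting: 18-39, 40-59, 60-74, 75-84 and 85+ years.
#'
#' @param age Numeric vector of ages in years.
#' @return A factor with five ordered levels.
#' @export
#' @examples
#' age_band(c(22, 45, 68, 80, 91))
age_band <- function(age) {
  cut(age, breaks = c(-Inf, 40, 60, 75, 85, Inf), right = FALSE,
      labels = c("18-39", "40-59", "60-74", "75-84", "85+"))
}
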