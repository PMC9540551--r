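# Hospital tendency-to-operate (TTO) instrument and its diagnostics.

#' Compute the tendency-to-operate instrument
#'
#' For each admission, the TTO is the proportion of the same hospital's
#' eligible emergency admissions in the preceding `window_days` that
#' received emergency surgery, excluding the admission itself (and any
#' other admission on the same day, so there is no leakage from the index
#' or the future). Admissions whose lookback window holds fewer than
#' `min_volume` eligible admissions, or that fall within the first
#' `window_days` of the study, are flagged invalid.
#'
#' @param eligible A tibble of eligible admissions (from
#'   [eligible_admissions()]): `admission_id`, `hospital_id`,
#'   `admission_date`, `es`.
#' @param window_days Lookback window in days (default 365).
#' @param min_volume Minimum eligible admissions in the window for a valid
#'   TTO (default 10).
#' @param study_start Day offset of the start of data coverage; defaults to
#'   the earliest eligible admission date.
#' @return A tibble keyed by `admission_id` with `tto`, `n_window` and
#'   `valid`.
#' @export
compute_tto <- function(eligible, window_days = 365, min_volume = 10,
                        study_start = NULL) {
  if (is.null(study_start)) study_start <- min(eligible$admission_date)
  e <- eligible[order(eligible$hospital_id, eligible$admission_date), ,
                drop = FALSE]
  n <- nrow(e)
  split_idx <- split(seq_len(n), e$hospital_id)
  tto <- rep(NA_real_, n)
  n_win <- integer(n)
  for (idx in split_idx) {
    d <- e$admission_date[idx]
    es <- as.numeric(e$es[idx])
    cum_n <- seq_along(d)
    cum_es <- cumsum(es)
    # counts with date strictly before d and within [d - window, d)
    lt <- findInterval(d - 0.5, d)
    lo <- findInterval(d - window_days - 0.5, d)
    n_here <- lt - lo
    es_here <- (c(0, cum_es)[lt + 1L]) - (c(0, cum_es)[lo + 1L])
    n_win[idx] <- n_here
    tto[idx] <- ifelse(n_here > 0, es_here / n_here, NA_real_)
  }
  valid <- n_win >= min_volume &
    e$admission_date >= study_start + window_days
  res <- tibble(admission_id = e$admission_id, tto = tto,
                n_window = n_win, valid = valid)
  res[match(eligible$admission_id, res$admission_id), , drop = FALSE]
}

#' First-stage instrument strength (partial F)
#'
#' Fits a linear first stage of the treatment indicator on the TTO and the
#' covariates and returns the partial F statistic for the instrument. By
#' default the variance is clustered by hospital (CR1); `vcov =
#' "classical"` gives the homoskedastic textbook F, which is useful for
#' small-fixture verification. The conventional weak-instrument rule of
#' thumb requires F > 10.
#'
#' @param cohort Analysis cohort with `es`, `tto`, `hospital_id` and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param vcov `"cluster"` (default) or `"classical"`.
#' @return A list with `F`, `n_clusters` and the fitted linear model.
#' @export
first_stage_strength <- function(cohort, covariates = character(0),
                                 vcov = c("cluster", "classical")) {
  vcov <- match.arg(vcov)
  n_cl <- length(unique(cohort$hospital_id))
  if (n_cl < 2) abort("clustering needs at least 2 hospitals")
  rhs <- paste(c("tto", covariates), collapse = " + ")
  dat <- as.data.frame(cohort)
  dat$es <- as.numeric(dat$es)
  fit <- lm(stats::as.formula(paste("es ~", rhs)), data = dat)
  if (vcov == "cluster") {
    V <- sandwich::vcovCL(fit, cluster = dat$hospital_id, type = "HC1")
  } else {
    V <- stats::vcov(fit)
  }
  b <- stats::coef(fit)["tto"]
  Fstat <- unname(b^2 / V["tto", "tto"])
  list(F = Fstat, n_clusters = n_cl, fit = fit)
}

#' Covariate balance across treatment and instrument levels
#'
#' Computes, for each covariate (numeric, or factor/character expanded to
#' indicator columns), the standardised mean difference (SMD) across
#' treatment groups and across instrument halves (admissions above versus
#' below the median TTO). The SMD is `(mean1 - mean0) / pooled SD`, which
#' is scale-invariant; when the pooled SD is zero it is reported as 0 when
#' the means are equal and flagged otherwise. In an instrument that mimics
#' randomisation, instrument-half SMDs should be small even where
#' treatment-group SMDs are large.
#'
#' @param cohort Analysis cohort with `es`, `tto` and the covariates.
#' @param covariates Character vector of covariate column names.
#' @return A tibble with one row per expanded covariate, sorted by
#'   decreasing treatment-split SMD: `covariate`, `smd_treatment`,
#'   `smd_instrument`, `flagged`.
#' @export
balance_diagnostics <- function(cohort, covariates) {
  expand <- function(v, nm) {
    x <- cohort[[v]]
    if (is.numeric(x) || is.logical(x)) {
      m <- matrix(as.numeric(x), ncol = 1,
                  dimnames = list(NULL, v))
    } else {
      f <- factor(x)
      m <- vapply(levels(f), function(l) as.numeric(f == l),
                  numeric(length(f)))
      colnames(m) <- paste(v, levels(f), sep = ":")
    }
    m
  }
  X <- do.call(cbind, lapply(covariates, expand))
  smd <- function(x, g) {
    m1 <- mean(x[g]); m0 <- mean(x[!g])
    s <- sqrt((var(x[g]) + var(x[!g])) / 2)
    if (!is.finite(s) || s == 0) {
      if (isTRUE(all.equal(m1, m0))) return(c(0, 0)) else return(c(NA_real_, 1))
    }
    c((m1 - m0) / s, 0)
  }
  g_trt <- as.logical(cohort$es)
  g_iv <- cohort$tto > stats::median(cohort$tto)
  res <- tibble(
    covariate = colnames(X),
    smd_treatment = NA_real_, smd_instrument = NA_real_, flagged = FALSE)
  for (j in seq_len(ncol(X))) {
    a <- smd(X[, j], g_trt)
    b <- smd(X[, j], g_iv)
    res$smd_treatment[j] <- a[1]
    res$smd_instrument[j] <- b[1]
    res$flagged[j] <- a[2] == 1 || b[2] == 1
  }
  res[order(-abs(res$smd_treatment)), , drop = FALSE]
}

#' Hospital quality-of-care proxies
#'
#' Raw (unadjusted) per-hospital-year rates used as second-stage
#' adjusters: the count of eligible emergency admissions (a volume-scaled
#' admission rate) and the 90-day mortality rate among them. Years are
#' `floor((admission_date - study_start) / 365)`. Returns both the
#' time-varying table and, for convenience, the time-constant baseline-year
#' values. Hospital-years with no admissions are missing, not zero.
#'
#' @param eligible Eligible admissions with `hospital_id`,
#'   `admission_date` and `mortality_90` (logical).
#' @param study_start Day offset of year 0; defaults to the earliest
#'   admission date.
#' @param baseline_year Year index used for the time-constant proxies
#'   (default 0).
#' @return A tibble with `hospital_id`, `year`, `n_admissions`,
#'   `mortality_rate`, `baseline_n_admissions`, `baseline_mortality_rate`.
#' @export
hospital_quality_proxies <- function(eligible, study_start = NULL,
                                     baseline_year = 0L) {
  if (is.null(study_start)) study_start <- min(eligible$admission_date)
  yr <- as.integer(floor((eligible$admission_date - study_start) / 365))
  tab <- tibble(hospital_id = eligible$hospital_id, year = yr,
                dead = as.numeric(eligible$mortality_90)) |>
    group_by(.data$hospital_id, .data$year) |>
    summarise(n_admissions = dplyr::n(),
              mortality_rate = mean(.data$dead), .groups = "drop")
  base <- tab[tab$year == baseline_year,
              c("hospital_id", "n_admissions", "mortality_rate")]
  names(base) <- c("hospital_id", "baseline_n_admissions",
                   "baseline_mortality_rate")
  left_join(tab, base, by = "hospital_id")
}

#' Join quality proxies to a cohort using the year before each admission
#'
#' Each admission is matched to its hospital's proxies for the year
#' strictly before its index date (time-varying) plus the baseline-year
#' values (time-constant). Admissions whose hospital has no prior-year
#' record get missing values, which the model layer handles as configured.
#'
#' @param cohort Analysis cohort with `hospital_id` and `index_date`.
#' @param proxies From [hospital_quality_proxies()].
#' @param study_start Day offset of year 0 used when building `proxies`.
#' @return The cohort with `qp_prior_volume`, `qp_prior_mortality`,
#'   `qp_base_volume`, `qp_base_mortality` appended.
#' @export
join_quality_proxies <- function(cohort, proxies, study_start) {
  prior_year <- as.integer(floor((cohort$index_date - study_start) / 365)) - 1L
  key <- paste(cohort$hospital_id, prior_year)
  pk <- paste(proxies$hospital_id, proxies$year)
  i <- match(key, pk)
  cohort$qp_prior_volume <- proxies$n_admissions[i]
  cohort$qp_prior_mortality <- proxies$mortality_rate[i]
  j <- match(cohort$hospital_id, proxies$hospital_id)
  cohort$qp_base_volume <- proxies$baseline_n_admissions[j]
  cohort$qp_base_mortality <- proxies$baseline_mortality_rate[j]
  cohort
}
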