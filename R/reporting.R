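# Report tables: baseline characteristics, unadjusted comparisons, IV
# results and forest-plot exports. Rounding follows the conventions of
# published cohort tables: means and SDs to 2 decimal places, percentages
# to 1, and mean differences of magnitude >= 10 to 1 decimal place.

#' Percentage share of a group, to one decimal place
#'
#' @param n Group count(s).
#' @param total Denominator.
#' @return Numeric percentage rounded to 1 decimal place.
#' @export
#' @examples
#' pct_share(247506, 268144)  # 92.3
pct_share <- function(n, total) {
  if (any(total == 0)) return(rep(NA_real_, length(n)))
  round(100 * n / total, 1)
}

# Mean differences as printed: 2 dp, or 1 dp for large differences.
round_mean_diff <- function(x) ifelse(abs(x) >= 10, round(x, 1), round(x, 2))

#' Unadjusted mean difference with a normal-approximation 95% CI
#'
#' ES-minus-NES difference of group means with an unequal-variance
#' (Welch-type) normal interval. For binary outcomes pass proportions in
#' percent and their binomial SDs.
#'
#' @param m1,s1,n1 ES group mean, SD, size.
#' @param m0,s0,n0 NES group mean, SD, size.
#' @return A list with `diff`, `ci_low`, `ci_high` (unrounded) and
#'   `diff_printed` (rounded as in the tables).
#' @export
unadjusted_difference <- function(m1, s1, n1, m0, s0, n0) {
  d <- m1 - m0
  se <- sqrt(s1^2 / n1 + s0^2 / n0)
  if (!is.finite(se) || se == 0) {
    warn("zero-variance outcome: CI collapses to the point estimate")
    se <- 0
  }
  list(diff = d, ci_low = d - 1.96 * se, ci_high = d + 1.96 * se,
       diff_printed = round_mean_diff(d))
}

#' Baseline characteristics table by treatment group
#'
#' Group sizes with shares of the cohort, mean (SD) age, and counts with
#' percentages for sex, Charlson bands and frailty categories, by ES
#' versus NES. Percentages are to 1 decimal place; an empty group reports
#' missing percentages.
#'
#' @param cohort Analysis cohort with case-mix derived.
#' @return A tibble with `variable`, `level`, and per group `n`/`value`
#'   and `pct` columns.
#' @export
table_baseline <- function(cohort) {
  g1 <- cohort[cohort$es, , drop = FALSE]
  g0 <- cohort[!cohort$es, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0); nt <- nrow(cohort)
  cat_rows <- function(variable, f1, f0) {
    levs <- union(levels(factor(f1)), levels(factor(f0)))
    tibble(variable = variable, level = levs,
           es_n = as.integer(table(factor(f1, levels = levs))[levs]),
           es_pct = if (n1 > 0) pct_share(as.integer(table(factor(f1, levels = levs))[levs]), n1) else NA_real_,
           nes_n = as.integer(table(factor(f0, levels = levs))[levs]),
           nes_pct = if (n0 > 0) pct_share(as.integer(table(factor(f0, levels = levs))[levs]), n0) else NA_real_)
  }
  bind_rows(
    tibble(variable = "group", level = c("emergency_surgery", "non_emergency_surgery"),
           es_n = c(n1, NA), es_pct = c(pct_share(n1, nt), NA),
           nes_n = c(NA, n0), nes_pct = c(NA, pct_share(n0, nt))),
    tibble(variable = "age", level = "mean_sd",
           es_n = NA_integer_, es_pct = round(mean(g1$age), 1),
           nes_n = NA_integer_, nes_pct = round(mean(g0$age), 1)),
    cat_rows("sex", g1$sex, g0$sex),
    cat_rows("charlson_band", g1$charlson_band, g0$charlson_band),
    cat_rows("frailty_category", g1$frailty_category, g0$frailty_category)
  )
}

#' Unadjusted outcome comparison table
#'
#' Per outcome: ES and NES group mean (SD) for continuous outcomes or
#' count (%) for binary ones, with the ES-minus-NES difference and its
#' normal-approximation 95% CI. Binary differences are in percentage
#' points.
#'
#' @param cohort Analysis cohort with outcomes derived.
#' @return A tibble with one row per outcome.
#' @export
table_unadjusted <- function(cohort) {
  g1 <- cohort[cohort$es, , drop = FALSE]
  g0 <- cohort[!cohort$es, , drop = FALSE]
  cont_row <- function(outcome) {
    y1 <- g1[[outcome]]; y0 <- g0[[outcome]]
    d <- unadjusted_difference(mean(y1), sd(y1), length(y1),
                               mean(y0), sd(y0), length(y0))
    tibble(outcome = outcome, type = "continuous",
           es_value = round(mean(y1), 2), es_spread = round(sd(y1), 2),
           nes_value = round(mean(y0), 2), nes_spread = round(sd(y0), 2),
           diff = d$diff_printed,
           ci_low = round_mean_diff(d$ci_low),
           ci_high = round_mean_diff(d$ci_high))
  }
  bin_row <- function(outcome) {
    y1 <- as.numeric(g1[[outcome]]); y0 <- as.numeric(g0[[outcome]])
    p1 <- 100 * mean(y1); p0 <- 100 * mean(y0)
    s1 <- 100 * sqrt(mean(y1) * (1 - mean(y1)))
    s0 <- 100 * sqrt(mean(y0) * (1 - mean(y0)))
    d <- unadjusted_difference(p1, s1, length(y1), p0, s0, length(y0))
    tibble(outcome = outcome, type = "binary",
           es_value = sum(y1), es_spread = round(p1, 2),
           nes_value = sum(y0), nes_spread = round(p0, 2),
           diff = d$diff_printed,
           ci_low = round_mean_diff(d$ci_low),
           ci_high = round_mean_diff(d$ci_high))
  }
  bind_rows(cont_row("daoh_90"), bin_row("mortality_90"),
            cont_row("los_90"), bin_row("readmit_30"))
}

#' IV results table and forest-plot export
#'
#' `table_iv()` renders the overall rows of one or more effect-estimate
#' tables (one per outcome) in the published layout: mean difference,
#' 95% CI and p-value, with binary effects scaled to percentage points.
#' `forest_export()` returns the long-format subgroup records (one row per
#' partition level with estimate, CI bounds and subgroup size) that drive
#' a forest plot.
#'
#' @param estimates A named list of [iv_effects()] results (names are
#'   outcome labels), or a single result.
#' @param percent_binary Outcomes (by name) whose effects are multiplied
#'   by 100 for reporting.
#' @return A tibble; `table_iv()` has one row per outcome with a formatted
#'   `printed` column like `"0.60 (-0.10 to 1.30)"`.
#' @export
table_iv <- function(estimates, percent_binary = c("mortality_90", "readmit_30")) {
  if (inherits(estimates, "effect_estimates")) estimates <- list(estimate = estimates)
  rows <- lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    ov <- e[e$partition == "overall", , drop = FALSE]
    if (nrow(ov) == 0) {
      return(tibble(outcome = nm, estimate = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_, printed = NA_character_))
    }
    scale <- if (nm %in% percent_binary) 100 else 1
    est <- round_mean_diff(ov$estimate * scale)
    lo <- round_mean_diff(ov$ci_low * scale)
    hi <- round_mean_diff(ov$ci_high * scale)
    tibble(outcome = nm, estimate = est, ci_low = lo, ci_high = hi,
           p_value = round(ov$p_value, 2),
           printed = if (is.na(lo)) sprintf("%.2f", est) else
             sprintf("%.2f (%.2f to %.2f)", est, lo, hi))
  })
  bind_rows(rows)
}

#' @rdname table_iv
#' @export
forest_export <- function(estimates, percent_binary = c("mortality_90", "readmit_30")) {
  if (inherits(estimates, "effect_estimates")) estimates <- list(estimate = estimates)
  rows <- lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    sg <- e[e$partition != "overall", , drop = FALSE]
    scale <- if (nm %in% percent_binary) 100 else 1
    tibble(outcome = nm, partition = sg$partition, level = sg$level,
           estimate = sg$estimate * scale, ci_low = sg$ci_low * scale,
           ci_high = sg$ci_high * scale, n = sg$n)
  })
  bind_rows(rows)
}

#' Worked-example cohort summary statistics
#'
#' Summary statistics for five acute-condition cohorts in a large national
#' administrative hospital database (emergency admissions, England,
#' 2010-2019), shipped as plain-text CSVs: per-condition ES/NES group
#' sizes, and per-outcome group means and SDs (or counts and percentages).
#' These are used in worked examples and to verify the package's table
#' arithmetic (group shares, unadjusted differences) against independently
#' published values.
#'
#' @return A list of two tibbles, `sizes` (condition, group, n) and
#'   `outcomes` (condition, outcome, type, group means/SDs or counts/%).
#' @export
example_cohort_summary <- function() {
  dir <- system.file("extdata", package = "emergiv")
  list(
    sizes = as_tibble(read.csv(file.path(dir, "example_cohort_sizes.csv"))),
    outcomes = as_tibble(read.csv(file.path(dir, "example_unadjusted_outcomes.csv")))
  )
}
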