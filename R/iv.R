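# Person-level instrumental-variable engine: probit first stage on the
# tendency-to-operate, control-function (two-stage residual inclusion)
# second stage with treatment x covariate and treatment x residual
# interactions, person-level effects by counterfactual prediction, subgroup
# aggregation, and a hospital-clustered bootstrap.

#' Specify the IV model
#'
#' @param covariates Covariate column names adjusted for at both stages
#'   (case-mix and time period).
#' @param interactions Include treatment-by-covariate and
#'   treatment-by-residual interactions in the second stage (default
#'   `TRUE`), so effect heterogeneity over observables and essential
#'   heterogeneity over unobservables are both modelled.
#' @param include_quality_proxies Adjust the second stage for the hospital
#'   quality-of-care proxies (columns `qp_*`, see
#'   [join_quality_proxies()])? Default `FALSE`.
#' @param bootstrap_reps Bootstrap replications (default 300).
#' @param subgroups Column names defining the reporting partitions; each
#'   must be exhaustive and mutually exclusive over the cohort.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `iv_model_spec`.
#' @export
model_spec <- function(covariates = c("age_band", "age", "sex", "ethnicity",
                                      "imd_quintile", "charlson_band",
                                      "charlson_score", "frailty_category",
                                      "deficit_count", "year"),
                       interactions = TRUE,
                       include_quality_proxies = FALSE,
                       bootstrap_reps = 300L,
                       subgroups = c("frailty_category", "age_band", "sex",
                                     "charlson_band"),
                       seed = 1L) {
  if (bootstrap_reps < 1) stop_config("bootstrap_reps", "must be >= 1")
  structure(list(covariates = covariates, interactions = interactions,
                 include_quality_proxies = include_quality_proxies,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 subgroups = subgroups, seed = seed),
            class = "iv_model_spec")
}

# Build the shared design pieces once: treatment, instrument, covariate
# model matrix (no intercept), optional quality proxies, cluster ids and
# subgroup label frames. Complete-case within the analysis, with a logged
# count of dropped rows.
iv_design <- function(cohort, spec) {
  need <- c("es", "tto", "hospital_id", spec$covariates, spec$subgroups)
  if (spec$include_quality_proxies) {
    need <- c(need, grep("^qp_", names(cohort), value = TRUE))
  }
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    abort(sprintf("cohort is missing required columns: %s",
                  paste(unique(miss), collapse = ", ")))
  }
  cc <- complete.cases(cohort[, unique(need), drop = FALSE])
  if (!all(cc)) {
    inform(sprintf("complete-case analysis drops %d of %d rows",
                   sum(!cc), length(cc)))
    cohort <- cohort[cc, , drop = FALSE]
  }
  covdat <- as.data.frame(cohort[, spec$covariates, drop = FALSE])
  for (v in names(covdat)) {
    if (is.character(covdat[[v]]) || is.logical(covdat[[v]])) {
      covdat[[v]] <- factor(covdat[[v]])
    }
    if (is.factor(covdat[[v]])) covdat[[v]] <- droplevels(covdat[[v]])
  }
  C <- model.matrix(~ ., data = covdat)[, -1, drop = FALSE]
  Q <- NULL
  if (spec$include_quality_proxies) {
    qcols <- grep("^qp_", names(cohort), value = TRUE)
    Q <- as.matrix(cohort[, qcols, drop = FALSE])
  }
  sub <- lapply(spec$subgroups, function(v) {
    f <- cohort[[v]]
    if (!is.factor(f)) f <- factor(f)
    droplevels(f)
  })
  names(sub) <- spec$subgroups
  list(es = as.numeric(cohort$es), tto = cohort$tto, C = C, Q = Q,
       hospital = cohort$hospital_id, sub = sub, cohort = cohort)
}

# Stable inverse Mills ratio dnorm(x)/pnorm(x).
mills <- function(x) exp(dnorm(x, log = TRUE) - pnorm(x, log.p = TRUE))

probit_fit <- function(X, y) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(link = "probit"),
            control = list(maxit = 100)))
  if (!fit$converged) {
    abort(sprintf(
      "probit first stage did not converge (deviance %.3f after %d iterations)",
      fit$deviance, fit$iter), class = "emergiv_convergence_error")
  }
  p <- fit$fitted.values
  frac_degenerate <- mean(p <= 1e-12 | p >= 1 - 1e-12)
  if (frac_degenerate > 0.02) {
    abort(sprintf(
      "probit fit separated: %.1f%% of fitted probabilities are degenerate",
      100 * frac_degenerate), class = "emergiv_convergence_error")
  }
  fit
}

#' Fit the probit first stage
#'
#' Maximum-likelihood probit of the treatment indicator on the TTO
#' instrument and the covariates. Returns the fitted propensity and the
#' probit generalised residual `r = es * m(xb) - (1 - es) * m(-xb)` with
#' `m` the inverse Mills ratio; at the MLE the residual has mean
#' approximately zero (the score equation for the intercept).
#'
#' @param cohort Analysis cohort with `es`, `tto` and the covariates.
#' @param spec A [model_spec()].
#' @return A list of class `iv_first_stage` with `coef`, `propensity`,
#'   `residual`, `eta` (linear predictor) and the design.
#' @export
fit_first_stage <- function(cohort, spec = model_spec()) {
  des <- iv_design(cohort, spec)
  fs <- first_stage_impl(des)
  structure(c(fs, list(design = des, spec = spec)),
            class = "iv_first_stage")
}

first_stage_impl <- function(des) {
  X <- cbind(`(Intercept)` = 1, tto = des$tto, des$C)
  fit <- probit_fit(X, des$es)
  beta <- fit$coefficients
  ok <- !is.na(beta)            # aliased columns are dropped by glm.fit
  eta <- drop(X[, ok, drop = FALSE] %*% beta[ok])
  gr <- ifelse(des$es == 1, mills(eta), -mills(-eta))
  list(coef = beta, propensity = pnorm(eta), eta = eta,
       residual = unname(gr))
}

# Assemble the second-stage design matrix from the shared blocks.
second_stage_matrix <- function(des, gr, spec, residual = TRUE) {
  es <- des$es
  parts <- list(`(Intercept)` = rep(1, length(es)), es = es, des$C)
  if (spec$interactions) {
    esC <- des$C * es
    colnames(esC) <- paste0("es:", colnames(des$C))
    parts <- c(parts, list(esC))
  }
  if (residual) {
    parts <- c(parts, list(gr = gr))
    if (spec$interactions) parts <- c(parts, list(`es:gr` = es * gr))
  }
  if (!is.null(des$Q)) parts <- c(parts, list(des$Q))
  X <- do.call(cbind, parts)
  colnames(X)[1] <- "(Intercept)"
  X
}

fit_glm_matrix <- function(X, y, family, drop_aliased = FALSE) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    if (!drop_aliased) {
      abort(sprintf("rank-deficient second stage; collinear terms: %s",
                    paste(aliased, collapse = ", ")),
            class = "emergiv_rank_error")
    }
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
  }
  if (is.null(family)) {
    fit <- lm.fit(X, y)
    beta <- fit$coefficients
  } else {
    fit <- suppressWarnings(glm.fit(X, y, family = family,
                                    control = list(maxit = 100)))
    if (!fit$converged) {
      abort("second-stage GLM did not converge",
            class = "emergiv_convergence_error")
    }
    beta <- fit$coefficients
  }
  beta[is.na(beta)] <- 0
  beta
}

#' Fit the control-function second stage
#'
#' Generalised linear model of the outcome on treatment, covariates,
#' treatment-by-covariate interactions, the first-stage generalised
#' residual, the treatment-by-residual interaction and (optionally) the
#' hospital quality proxies. The link is identity for continuous outcomes
#' (DAOH, LOS) and probit for binary ones (mortality, re-admission).
#'
#' @param fs An [fit_first_stage()] result.
#' @param outcome Outcome column name in the cohort.
#' @param drop_aliased Drop collinear columns instead of erroring?
#' @return A list of class `iv_second_stage` with the coefficient vector
#'   and everything needed for counterfactual prediction.
#' @export
fit_second_stage <- function(fs, outcome, drop_aliased = FALSE) {
  des <- fs$design
  spec <- fs$spec
  y <- des$cohort[[outcome]]
  binary <- is.logical(y) || all(y %in% c(0, 1))
  y <- as.numeric(y)
  X <- second_stage_matrix(des, fs$residual, spec)
  family <- if (binary) binomial(link = "probit") else NULL
  beta <- fit_glm_matrix(X, y, family, drop_aliased = drop_aliased)
  structure(list(coef = beta, outcome = outcome, binary = binary,
                 design = des, spec = spec, residual = fs$residual,
                 X = X),
            class = "iv_second_stage")
}

# Untreated linear predictor (lp0) and treatment contrast (delta) implied
# by a coefficient vector, with covariates and residual held fixed.
linear_parts <- function(beta, des, gr, spec) {
  nm <- names(beta)
  b <- function(term) if (term %in% nm) beta[[term]] else 0
  delta <- rep(b("es"), length(des$es))
  if (spec$interactions) {
    int_cols <- intersect(paste0("es:", colnames(des$C)), nm)
    if (length(int_cols)) {
      bc <- beta[int_cols]
      delta <- delta +
        drop(des$C[, sub("^es:", "", int_cols), drop = FALSE] %*% bc)
    }
    delta <- delta + gr * b("es:gr")
  }
  lp0 <- rep(b("(Intercept)"), length(des$es))
  ccols <- intersect(colnames(des$C), nm)
  if (length(ccols)) lp0 <- lp0 + drop(des$C[, ccols, drop = FALSE] %*% beta[ccols])
  lp0 <- lp0 + gr * b("gr")
  if (!is.null(des$Q)) {
    qcols <- intersect(colnames(des$Q), nm)
    if (length(qcols)) lp0 <- lp0 + drop(des$Q[, qcols, drop = FALSE] %*% beta[qcols])
  }
  list(lp0 = unname(lp0), delta = unname(delta))
}

# Per-row treatment effect by counterfactual prediction: set the treatment
# (and its interactions) to 1 and 0 with covariates and residual held
# fixed; identity-link effects are the linear contrast, probit-link effects
# are differences of link-inverse values (risk differences).
person_effects_impl <- function(beta, des, gr, spec, binary) {
  lp <- linear_parts(beta, des, gr, spec)
  if (!binary) return(lp$delta)
  pnorm(lp$lp0 + lp$delta) - pnorm(lp$lp0)
}

# Composite DAOH person effects from the mortality and LOS components:
# DAOH = (1 - death) * (horizon - LOS), so the per-arm prediction combines
# the probit-2SRI mortality probability with the identity-2SRI LOS
# prediction (clipped to [0, horizon]). Putting the mortality component on
# its own probit scale matters in high-mortality strata (e.g. severe
# frailty), where unmeasured severity shifts death risk through a steep
# region of the link and a single linear residual term in a direct DAOH
# model cannot absorb it.
composite_person_effects <- function(des, gr, y, spec, horizon,
                                     residual = TRUE, drop_aliased = FALSE,
                                     naive = FALSE) {
  X <- second_stage_matrix(des, gr, spec, residual = residual)
  bin_family <- binomial(link = if (naive) "logit" else "probit")
  inv <- if (naive) stats::plogis else pnorm
  bm <- fit_glm_matrix(X, y$mort, bin_family, drop_aliased = drop_aliased)
  lm_ <- linear_parts(bm, des, gr, spec)
  p1 <- inv(lm_$lp0 + lm_$delta); p0 <- inv(lm_$lp0)
  bl <- fit_glm_matrix(X, y$los, NULL, drop_aliased = drop_aliased)
  ll <- linear_parts(bl, des, gr, spec)
  clip <- function(x) pmin(pmax(x, 0), horizon)
  l1 <- clip(ll$lp0 + ll$delta); l0 <- clip(ll$lp0)
  (1 - p1) * (horizon - l1) - (1 - p0) * (horizon - l0)
}

#' Person-level treatment effects from a fitted second stage
#'
#' @param ss An [fit_second_stage()] result.
#' @return Numeric vector of per-row effects (outcome scale for continuous
#'   outcomes, probability scale for binary ones).
#' @export
person_effects <- function(ss) {
  person_effects_impl(ss$coef, ss$design, ss$residual, ss$spec, ss$binary)
}

#' Aggregate person-level effects overall and by subgroup
#'
#' The overall estimate is the mean person-level effect; each subgroup
#' estimate is the mean within the subgroup, so the overall estimate is
#' exactly the size-weighted mean of any partition's subgroup estimates.
#' Empty subgroups are reported as missing.
#'
#' @param pe Person-level effects.
#' @param sub Named list of factors partitioning the rows (as in the
#'   design), or a data frame of them.
#' @return A tibble with `partition`, `level`, `estimate`, `n`; the first
#'   row is the overall estimate (`partition = "overall"`).
#' @export
aggregate_effects <- function(pe, sub) {
  if (is.data.frame(sub)) sub <- as.list(sub)
  out <- list(tibble(partition = "overall", level = "overall",
                     estimate = mean(pe), n = length(pe)))
  for (v in names(sub)) {
    f <- sub[[v]]
    if (!is.factor(f)) f <- factor(f)
    levs <- levels(f)
    est <- vapply(levs, function(l) {
      m <- f == l
      if (!any(m)) NA_real_ else mean(pe[m])
    }, numeric(1))
    n <- as.integer(table(f)[levs])
    out[[length(out) + 1]] <- tibble(partition = v, level = levs,
                                     estimate = unname(est), n = n)
  }
  bind_rows(out)
}

# One full IV (or naive) point fit on a design subset; returns the
# aggregate tibble. For the composite DAOH estimator, `y` is a list with
# `mort` and `los` components.
pipeline_point <- function(des, y, binary, spec, method = c("iv", "naive"),
                           drop_aliased = FALSE, horizon = 90) {
  method <- match.arg(method)
  naive <- method == "naive"
  if (naive) {
    gr <- rep(0, length(des$es))
  } else {
    fs <- first_stage_impl(des)
    gr <- fs$residual
  }
  if (is.list(y)) {
    pe <- composite_person_effects(des, gr, y, spec, horizon,
                                   residual = !naive,
                                   drop_aliased = drop_aliased, naive = naive)
    return(aggregate_effects(pe, des$sub))
  }
  X <- second_stage_matrix(des, gr, spec, residual = !naive)
  family <- if (binary) binomial(link = if (naive) "logit" else "probit")
  beta <- fit_glm_matrix(X, y, family, drop_aliased = drop_aliased)
  if (binary && naive) {
    # marginal standardisation under the logit link
    lp <- linear_parts(beta, des, gr, spec)
    pe <- stats::plogis(lp$lp0 + lp$delta) - stats::plogis(lp$lp0)
  } else {
    pe <- person_effects_impl(beta, des, gr, spec, binary)
  }
  aggregate_effects(pe, des$sub)
}

# Subset the shared design by row index (bootstrap replicate).
subset_design <- function(des, idx) {
  list(es = des$es[idx], tto = des$tto[idx],
       C = des$C[idx, , drop = FALSE],
       Q = if (!is.null(des$Q)) des$Q[idx, , drop = FALSE],
       hospital = des$hospital[idx],
       sub = lapply(des$sub, function(f) f[idx]))
}

#' Estimate treatment effects with hospital-clustered bootstrap CIs
#'
#' Runs the full person-level estimator (probit first stage on the TTO,
#' control-function second stage, person-level effects, aggregation
#' overall and by subgroup) and attaches percentile confidence intervals
#' from a cluster bootstrap that resamples hospitals with replacement and
#' re-runs both stages in every replicate. Replicates whose fits fail
#' (e.g. non-convergence) are dropped and counted; more than 10% failures
#' is an error. Two-sided p-values are the symmetric bootstrap tail
#' position of zero.
#'
#' @param cohort Analysis cohort (case-mix, outcomes and TTO derived).
#' @param outcome Outcome column name, or `"daoh_composite"` to estimate
#'   DAOH effects through their mortality and LOS components: a
#'   probit-2SRI model for 90-day death and an identity-2SRI model for LOS
#'   are combined per arm as `(1 - p_death) * (90 - LOS)`. The direct
#'   identity-link `"daoh"` model targets the same estimand and is the
#'   default for overall effects; the composite is preferable for subgroup
#'   effects in strata with materially different mortality (e.g. severe
#'   frailty), where death-risk confounding acts through a steep region of
#'   the probit link (see the methods vignette).
#' @param spec A [model_spec()].
#' @param method `"iv"` (default) or `"naive"` — the latter is the
#'   regression comparator that assumes no unobserved confounding
#'   (ordinary least squares for continuous outcomes, logistic regression
#'   with marginal standardisation for binary ones).
#' @param reps Bootstrap replications; `0` skips the bootstrap (point
#'   estimates only). Defaults to `spec$bootstrap_reps`.
#' @param seed Bootstrap seed; defaults to `spec$seed`.
#' @return A tibble of class `effect_estimates` with `partition`, `level`,
#'   `estimate`, `ci_low`, `ci_high`, `p_value`, `n`; attributes
#'   `boot_draws` (matrix), `boot_failed`, `boot_retained`.
#' @export
iv_effects <- function(cohort, outcome, spec = model_spec(),
                       method = c("iv", "naive"),
                       reps = spec$bootstrap_reps, seed = spec$seed) {
  method <- match.arg(method)
  des <- iv_design(cohort, spec)
  if (outcome == "daoh_composite") {
    y <- list(mort = as.numeric(des$cohort$mortality_90),
              los = as.numeric(des$cohort$los_90))
    binary <- FALSE
  } else {
    y <- des$cohort[[outcome]]
    binary <- is.logical(y) || all(y %in% c(0, 1))
    y <- as.numeric(y)
  }
  point <- pipeline_point(des, y, binary, spec, method)
  point$ci_low <- NA_real_; point$ci_high <- NA_real_
  point$p_value <- NA_real_
  if (reps < 1) {
    return(structure(point, class = c("effect_estimates", class(point))))
  }
  hospitals <- unique(des$hospital)
  if (length(hospitals) < 2) abort("cluster bootstrap needs >= 2 hospitals")
  rows_by_h <- split(seq_along(des$hospital), des$hospital)
  draws <- matrix(NA_real_, nrow = reps, ncol = nrow(point))
  failed <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(reps)) {
      hs <- sample(names(rows_by_h), length(rows_by_h), replace = TRUE)
      idx <- unlist(rows_by_h[hs], use.names = FALSE)
      y_b <- if (is.list(y)) lapply(y, `[`, idx) else y[idx]
      res <- tryCatch(
        pipeline_point(subset_design(des, idx), y_b, binary, spec,
                       method, drop_aliased = TRUE),
        error = function(e) NULL)
      if (is.null(res)) { failed <- failed + 1L; next }
      draws[b, ] <- res$estimate[match(paste(point$partition, point$level),
                                       paste(res$partition, res$level))]
    }
  })
  if (failed == reps) abort("all bootstrap replicates failed")
  if (failed > 0.10 * reps) {
    abort(sprintf("%d of %d bootstrap replicates failed (> 10%%)",
                  failed, reps))
  }
  ok <- !is.na(draws[, 1])
  for (j in seq_len(nrow(point))) {
    dj <- draws[ok, j]
    dj <- dj[!is.na(dj)]
    if (length(dj) < 2) next
    qs <- quantile(dj, c(0.025, 0.975), names = FALSE)
    point$ci_low[j] <- qs[1]
    point$ci_high[j] <- qs[2]
    lo <- (1 + sum(dj <= 0)) / (length(dj) + 1)
    hi <- (1 + sum(dj >= 0)) / (length(dj) + 1)
    point$p_value[j] <- min(1, 2 * min(lo, hi))
  }
  structure(point, class = c("effect_estimates", class(point)),
            boot_draws = draws[ok, , drop = FALSE], boot_failed = failed,
            boot_retained = sum(ok))
}

#' Naive regression comparator
#'
#' Covariate-adjusted regression contrast assuming no unobserved
#' confounding; shorthand for `iv_effects(..., method = "naive")`.
#'
#' @inheritParams iv_effects
#' @return See [iv_effects()].
#' @export
naive_estimate <- function(cohort, outcome, spec = model_spec(),
                           reps = 0, seed = spec$seed) {
  iv_effects(cohort, outcome, spec, method = "naive", reps = reps,
             seed = seed)
}
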