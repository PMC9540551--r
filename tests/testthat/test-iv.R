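# Two-stage residual-inclusion IV engine.

# Small cohort-like tibble drawn from a known probit treatment model.
probit_cohort <- function(n, seed, b_tto = 0.8, b_x = -0.4, b0 = 0.3) {
  withr::with_seed(seed, {
    tibble::tibble(
      tto = runif(n),
      x = rnorm(n),
      hospital_id = sample(sprintf("H%02d", 1:20), n, TRUE),
      g = factor(sample(c("a", "b"), n, TRUE)),
      es = runif(n) < pnorm(b0 + b_tto * tto + b_x * x))
  })
}

simple_spec <- function(...) {
  model_spec(covariates = "x", subgroups = "g", ...)
}

test_that("the probit first stage recovers known coefficients", {
  co <- probit_cohort(20000, seed = 81)
  fs <- fit_first_stage(co, simple_spec())
  expect_equal(unname(fs$coef["tto"]), 0.8, tolerance = 0.12)
  expect_equal(unname(fs$coef["x"]), -0.4, tolerance = 0.08)
  expect_equal(unname(fs$coef["(Intercept)"]), 0.3, tolerance = 0.08)
  # score property: generalised residual has mean ~ 0 at the MLE
  expect_lt(abs(mean(fs$residual)), 1e-6 * sd(fs$residual))
  expect_true(all(fs$propensity > 0 & fs$propensity < 1))
})

test_that("an irrelevant instrument's coefficient is centred on zero", {
  covers <- vapply(1:20, function(s) {
    co <- probit_cohort(1500, seed = 300 + s, b_tto = 0)
    fs <- fit_first_stage(co, simple_spec())
    X <- cbind(1, co$tto, co$x)
    # observed-information standard error for the tto coefficient
    w <- as.numeric(stats::dnorm(fs$eta)^2 /
                      (fs$propensity * (1 - fs$propensity)))
    V <- chol2inv(chol(crossprod(X * sqrt(w))))
    abs(fs$coef["tto"]) < 1.96 * sqrt(V[2, 2])
  }, logical(1))
  expect_gte(mean(covers), 0.80)   # ~95% nominal, 20 draws
})

test_that("person effects reduce to closed forms", {
  co <- probit_cohort(500, seed = 82)
  co$y <- 1 + 2 * co$x + 5 * as.numeric(co$es) + rnorm(500)
  # identity link, no interactions: every person effect equals the treatment
  # coefficient
  sp <- simple_spec(interactions = FALSE)
  fs <- fit_first_stage(co, sp)
  ss <- fit_second_stage(fs, "y")
  pe <- person_effects(ss)
  expect_equal(unname(pe), rep(unname(ss$coef[["es"]]), 500))
  # all treatment-involving coefficients zero => all person effects zero
  sp2 <- simple_spec()
  fs2 <- fit_first_stage(co, sp2)
  ss2 <- fit_second_stage(fs2, "y")
  beta0 <- ss2$coef
  beta0[grepl("^es", names(beta0))] <- 0
  pe0 <- emergiv:::person_effects_impl(beta0, fs2$design, fs2$residual, sp2,
                                       binary = FALSE)
  expect_true(all(pe0 == 0))
  # probit link with hand-set coefficients: Phi(a + b) - Phi(a)
  beta <- setNames(rep(0, length(ss2$coef)), names(ss2$coef))
  beta[["(Intercept)"]] <- -1; beta[["es"]] <- 0.7; beta[["x"]] <- 0.2
  pe_bin <- emergiv:::person_effects_impl(beta, fs2$design, fs2$residual, sp2,
                                          binary = TRUE)
  expect_equal(pe_bin, pnorm(-1 + 0.2 * co$x + 0.7) - pnorm(-1 + 0.2 * co$x))
})

test_that("rank-deficient second stages name the collinear terms", {
  co <- probit_cohort(300, seed = 83)
  co$x2 <- co$x          # exact duplicate
  co$y <- rnorm(300)
  sp <- model_spec(covariates = c("x", "x2"), subgroups = "g")
  fs <- fit_first_stage(co, sp)
  expect_error(fit_second_stage(fs, "y"), "collinear.*x2|x2.*collinear")
})

test_that("aggregation satisfies the partition identity exactly", {
  set.seed(84)
  pe <- rnorm(1000)
  f <- factor(sample(c("p", "q", "r"), 1000, TRUE))
  agg <- aggregate_effects(pe, list(grp = f))
  ov <- agg$estimate[agg$partition == "overall"]
  sg <- agg[agg$partition == "grp", ]
  expect_identical(ov, mean(pe))
  expect_equal(sum(sg$estimate * sg$n) / sum(sg$n), ov)
  # single-subgroup partition equals the overall estimate
  agg1 <- aggregate_effects(pe, list(one = factor(rep("all", 1000))))
  expect_equal(agg1$estimate[2], ov)
  # empty level reported missing
  f2 <- factor(rep("p", 1000), levels = c("p", "q"))
  agg2 <- aggregate_effects(pe, list(grp = f2))
  expect_true(is.na(agg2$estimate[agg2$level == "q"]))
  expect_equal(agg2$n[agg2$level == "q"], 0L)
})

test_that("the cluster bootstrap is seed-reproducible with bookkeeping", {
  cfg <- scenario_presets("unconfounded", seed = 85, n_hospitals = 15,
                          admissions_per_hospital = 40)
  sim <- generate_dataset(cfg)
  prep <- suppressMessages(prepare_analysis_data(sim$data,
                                                 condition = cfg$condition))
  sp <- model_spec(seed = 9)
  e1 <- iv_effects(prep$cohort, "daoh", sp, reps = 40)
  e2 <- iv_effects(prep$cohort, "daoh", sp, reps = 40)
  expect_identical(e1$ci_low, e2$ci_low)
  expect_identical(e1$ci_high, e2$ci_high)
  expect_identical(e1$p_value, e2$p_value)
  expect_lte(attr(e1, "boot_retained"), 40L)
  expect_true(all(e1$ci_low <= e1$ci_high, na.rm = TRUE))
  # a different seed gives different draws
  e3 <- iv_effects(prep$cohort, "daoh", model_spec(seed = 10), reps = 40)
  expect_false(identical(e1$ci_low, e3$ci_low))
})

test_that("naive and IV agree without confounding; IV alone stays near a null truth", {
  cfg <- scenario_presets("unconfounded", seed = 86, n_hospitals = 30,
                          admissions_per_hospital = 150)
  sim <- generate_dataset(cfg)
  prep <- suppressMessages(prepare_analysis_data(sim$data,
                                                 condition = cfg$condition))
  tr <- true_effects(sim$truth, ids = prep$cohort$admission_id)
  nv <- naive_estimate(prep$cohort, "daoh")
  expect_lt(abs(nv$estimate[1] - tr$true_ate), 1.0)
  cfg0 <- scenario_presets("null_effect", seed = 87, n_hospitals = 30,
                           admissions_per_hospital = 150)
  sim0 <- generate_dataset(cfg0)
  prep0 <- suppressMessages(prepare_analysis_data(sim0$data,
                                                  condition = cfg0$condition))
  iv0 <- iv_effects(prep0$cohort, "daoh", reps = 0)
  nv0 <- naive_estimate(prep0$cohort, "daoh")
  expect_lt(abs(iv0$estimate[1]), 2.5)
  # the naive estimate is visibly pulled away from the null by confounding
  expect_gt(abs(nv0$estimate[1]), 1.0)
})

test_that("the composite DAOH estimator agrees with the direct model overall", {
  cfg <- scenario_presets("strong_iv_confounded", seed = 89, n_hospitals = 20,
                          admissions_per_hospital = 120)
  sim <- generate_dataset(cfg)
  prep <- suppressMessages(prepare_analysis_data(sim$data,
                                                 condition = cfg$condition))
  direct <- iv_effects(prep$cohort, "daoh", reps = 0)
  comp <- iv_effects(prep$cohort, "daoh_composite", reps = 0)
  expect_lt(abs(comp$estimate[1] - direct$estimate[1]), 1.5)
  expect_true(all(is.finite(comp$estimate[comp$n > 0])))
  # the composite respects the DAOH scale: no effect can exceed the horizon
  expect_true(all(abs(comp$estimate) <= 90, na.rm = TRUE))
  # it supports the cluster bootstrap like any other outcome
  cb <- iv_effects(prep$cohort, "daoh_composite", model_spec(seed = 2),
                   reps = 20)
  expect_true(all(cb$ci_low <= cb$ci_high, na.rm = TRUE))
})

test_that("binary outcomes are modelled on the probability scale", {
  cfg <- scenario_presets("strong_iv_confounded", seed = 88, n_hospitals = 15,
                          admissions_per_hospital = 60)
  sim <- generate_dataset(cfg)
  prep <- suppressMessages(prepare_analysis_data(sim$data,
                                                 condition = cfg$condition))
  e <- iv_effects(prep$cohort, "mortality_90", reps = 0)
  expect_true(all(abs(e$estimate) <= 1, na.rm = TRUE))
  nvb <- naive_estimate(prep$cohort, "mortality_90")
  expect_true(abs(nvb$estimate[1]) <= 1)
})
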