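# Tendency-to-operate instrument, strength and balance diagnostics.

test_that("TTO is the prior-window ES proportion, excluding the index admission", {
  elig <- tibble::tibble(
    admission_id = 1:11,
    hospital_id = "H001",
    admission_date = c(seq(50, 140, by = 10), 400),
    es = c(rep(TRUE, 7), rep(FALSE, 3), TRUE))
  tto <- compute_tto(elig, min_volume = 10, study_start = 0)
  expect_equal(tto$tto[11], 0.7)                      # 7 ES of 10 eligible
  expect_equal(tto$n_window[11], 10L)
  expect_true(tto$valid[11])
  # self-exclusion: flipping the index admission's own flag changes nothing
  elig2 <- elig
  elig2$es[11] <- FALSE
  expect_equal(compute_tto(elig2, min_volume = 10, study_start = 0)$tto[11], 0.7)
  # all-ES window gives 1.0
  elig3 <- elig
  elig3$es[1:10] <- TRUE
  expect_equal(compute_tto(elig3, min_volume = 10, study_start = 0)$tto[11], 1)
  # insufficient lookback coverage or volume flags invalid
  expect_false(compute_tto(elig, min_volume = 11, study_start = 0)$valid[11])
  early <- compute_tto(elig, min_volume = 1, study_start = 0)
  expect_false(any(early$valid[1:10]))                # all within first 365 days
})

test_that("TTO uses only the hospital's own prior window", {
  elig <- tibble::tibble(
    admission_id = 1:22,
    hospital_id = rep(c("A", "B"), each = 11),
    admission_date = rep(c(seq(50, 140, by = 10), 400), 2),
    es = c(rep(TRUE, 10), FALSE, rep(FALSE, 10), TRUE))
  tto <- compute_tto(elig, min_volume = 5, study_start = 0)
  expect_equal(tto$tto[tto$admission_id == 11], 1)
  expect_equal(tto$tto[tto$admission_id == 22], 0)
})

test_that("the classical partial F matches the sum-of-squares oracle", {
  set.seed(71)
  n <- 90
  x <- rnorm(n)
  z <- rnorm(n)
  es <- as.numeric(0.4 * z + 0.2 * x + rnorm(n) > 0)
  cohort <- tibble::tibble(es = es, tto = z, x = x,
                           hospital_id = paste0("H", seq_len(n)))
  got <- first_stage_strength(cohort, "x", vcov = "classical")
  expect_equal(got$F, oracle_partial_F(es, z, cbind(x)), tolerance = 1e-8)
  expect_equal(got$n_clusters, n)
  expect_error(first_stage_strength(cohort[cohort$hospital_id == "H1", ], "x"),
               "at least 2 hospitals")
})

test_that("an irrelevant (permuted) instrument fails the F > 10 rule", {
  cfg <- scenario_presets("strong_iv_confounded", seed = 61, n_hospitals = 20,
                          admissions_per_hospital = 100)
  sim <- generate_dataset(cfg)
  prep <- suppressMessages(prepare_analysis_data(sim$data,
                                                 condition = cfg$condition))
  co <- prep$cohort
  below <- vapply(1:3, function(s) {
    withr::with_seed(s, co$tto <- sample(co$tto))
    first_stage_strength(co, c("age_band", "sex"))$F < 10
  }, logical(1))
  expect_true(sum(below) >= 2)
})

test_that("first-stage F increases with instrument strength", {
  fs <- vapply(c(0.05, 0.3, 1), function(str) {
    cfg <- sim_config(n_hospitals = 20, admissions_per_hospital = 100,
                      instrument_strength = str, seed = 62)
    sim <- generate_dataset(cfg)
    prep <- suppressMessages(prepare_analysis_data(sim$data))
    first_stage_strength(prep$cohort, c("age_band", "sex"))$F
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("standardised mean differences are scale-invariant and zero under identity", {
  set.seed(72)
  cohort <- tibble::tibble(es = rep(c(TRUE, FALSE), each = 50),
                           tto = runif(100), x = rnorm(100),
                           g = sample(c("a", "b"), 100, TRUE),
                           const = 1)
  b <- balance_diagnostics(cohort, c("x", "g", "const"))
  cohort2 <- cohort
  cohort2$x <- cohort2$x * 1000
  b2 <- balance_diagnostics(cohort2, c("x", "g", "const"))
  expect_equal(b$smd_treatment[b$covariate == "x"],
               b2$smd_treatment[b2$covariate == "x"])
  expect_equal(b$smd_treatment[b$covariate == "const"], 0)  # zero SD, equal means
  expect_false(b$flagged[b$covariate == "const"])
  # identical distributions in both groups: SMD exactly 0
  cohort3 <- cohort
  cohort3$x <- rep(c(1, 2), 50)
  b3 <- balance_diagnostics(cohort3, "x")
  expect_equal(b3$smd_treatment, 0)
})

test_that("a severity-linked covariate is better balanced across instrument halves", {
  cfg <- scenario_presets("strong_iv_confounded", seed = 63, n_hospitals = 30,
                          admissions_per_hospital = 200)
  sim <- generate_dataset(cfg)
  prep <- suppressMessages(prepare_analysis_data(sim$data,
                                                 condition = cfg$condition))
  b <- balance_diagnostics(prep$cohort, "deficit_count")
  expect_gt(abs(b$smd_treatment), abs(b$smd_instrument))
})

test_that("quality proxies are per-hospital-year rates joined at the prior year", {
  elig <- tibble::tibble(
    hospital_id = rep("H001", 150),
    admission_date = c(rep(100, 100), rep(500, 50)),
    mortality_90 = c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 5), rep(FALSE, 45)))
  qp <- hospital_quality_proxies(elig, study_start = 0)
  expect_equal(qp$mortality_rate[qp$year == 0], 0.10)
  expect_equal(qp$n_admissions[qp$year == 1], 50L)
  # hospital-year with no admissions is absent, not zero
  expect_false(2 %in% qp$year)
  cohort <- tibble::tibble(hospital_id = c("H001", "H001", "H002"),
                           index_date = c(500, 900, 500))
  j <- join_quality_proxies(cohort, qp, study_start = 0)
  expect_equal(j$qp_prior_mortality, c(0.10, 0.10, NA))  # year strictly before
  expect_equal(j$qp_prior_volume[2], 50L)
  expect_true(is.na(j$qp_base_volume[3]))
})
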