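# Report tables, worked-example arithmetic helpers and the CLI.

test_that("percentage shares round to one decimal place", {
  expect_equal(pct_share(247506, 268144), 92.3)
  expect_equal(pct_share(40550, 133073), 30.5)
  expect_equal(pct_share(10, 10), 100.0)
  expect_true(is.na(pct_share(0, 0)))
})

test_that("unadjusted differences follow the printed rounding conventions", {
  d <- unadjusted_difference(84.78, 6.07, 247506, 82.50, 11.41, 20638)
  expect_equal(d$diff_printed, 2.28)
  expect_true(d$ci_low < 2.28 && d$ci_high > 2.28)
  d2 <- unadjusted_difference(60.92, 26.23, 15772, 79.94, 16.71, 123097)
  expect_equal(d2$diff_printed, -19.0)    # large differences to 1 dp
  expect_warning(unadjusted_difference(1, 0, 10, 1, 0, 10), "zero-variance")
})

small_prep <- function() {
  cfg <- scenario_presets("strong_iv_confounded", seed = 91, n_hospitals = 10,
                          admissions_per_hospital = 60)
  sim <- generate_dataset(cfg)
  suppressMessages(prepare_analysis_data(sim$data, condition = cfg$condition))
}

test_that("baseline and unadjusted tables carry the documented shape", {
  prep <- small_prep()
  tb <- table_baseline(prep$cohort)
  grp <- tb[tb$variable == "group", ]
  expect_equal(grp$es_pct[1] + grp$nes_pct[2], 100, tolerance = 0.11)
  frail <- tb[tb$variable == "frailty_category", ]
  expect_equal(sum(frail$es_n), sum(prep$cohort$es))
  expect_equal(sum(frail$es_pct), 100, tolerance = 0.3)
  tu <- table_unadjusted(prep$cohort)
  expect_equal(tu$outcome, c("daoh_90", "mortality_90", "los_90", "readmit_30"))
  daoh <- tu[tu$outcome == "daoh_90", ]
  expect_equal(daoh$diff,
               emergiv:::round_mean_diff(
                 mean(prep$cohort$daoh_90[prep$cohort$es]) -
                   mean(prep$cohort$daoh_90[!prep$cohort$es])),
               tolerance = 0.011)
  expect_true(all(tu$ci_low <= tu$diff + 1e-9 & tu$diff <= tu$ci_high + 1e-9))
  # a one-group cohort reports 100% shares
  all_es <- prep$cohort[prep$cohort$es, ]
  tb1 <- table_baseline(all_es)
  expect_equal(tb1$es_pct[tb1$variable == "group"][1], 100.0)
})

test_that("IV tables and forest exports render estimates stably", {
  est <- tibble::tibble(partition = c("overall", "frailty_category",
                                      "frailty_category"),
                        level = c("overall", "fit", "severe"),
                        estimate = c(0.60, 0.93, -5.72),
                        ci_low = c(-0.10, 0.48, -11.3),
                        ci_high = c(1.30, 1.39, -0.2),
                        p_value = c(0.09, 0.01, 0.04),
                        n = c(100L, 60L, 40L))
  class(est) <- c("effect_estimates", class(est))
  ti <- table_iv(list(daoh = est))
  expect_equal(ti$printed, "0.60 (-0.10 to 1.30)")
  fe <- forest_export(list(daoh = est))
  expect_equal(nrow(fe), 2L)                       # sum of partition levels
  expect_equal(fe$estimate, c(0.93, -5.72))
  # binary outcomes scale to percentage points
  ti2 <- table_iv(list(mortality_90 = est))
  expect_equal(ti2$estimate, 60)
  # empty estimate list gives an empty table
  expect_equal(nrow(table_iv(list())), 0L)
})

test_that("report tables regenerate identically from persisted CSVs", {
  prep <- small_prep()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(prep$cohort, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  back$frailty_category <- factor(back$frailty_category,
                                  levels = levels(prep$cohort$frailty_category))
  back$charlson_band <- factor(back$charlson_band,
                               levels = levels(prep$cohort$charlson_band))
  expect_equal(as.data.frame(table_unadjusted(back)),
               as.data.frame(table_unadjusted(prep$cohort)))
  expect_equal(as.data.frame(table_baseline(back)),
               as.data.frame(table_baseline(prep$cohort)))
})

test_that("the worked-example summary ships with the package", {
  ex <- example_cohort_summary()
  expect_equal(nrow(ex$sizes), 10L)
  expect_equal(sort(unique(ex$sizes$condition)),
               sort(names(default_condition_specs())))
  expect_equal(nrow(ex$outcomes), 20L)
})

test_that("the CLI runs end to end from a config file", {
  dir <- withr::local_tempdir()
  data_dir <- file.path(dir, "data")
  cfg <- sim_config(n_hospitals = 8, admissions_per_hospital = 40, seed = 92)
  write_sim(generate_dataset(cfg), data_dir)
  cfg_path <- file.path(dir, "analysis.yaml")
  yaml::write_yaml(list(data_dir = data_dir,
                        output_dir = file.path(dir, "out"),
                        condition = "appendicitis",
                        min_volume = 5,
                        bootstrap_reps = 20,
                        outcomes = list("daoh"),
                        seed = 4), cfg_path)
  status <- suppressMessages(emergiv_cli(c("run", "--config", cfg_path)))
  expect_equal(status, 0L)
  for (f in c("cohort.csv", "exclusions.csv", "iv_daoh.csv", "naive_daoh.csv",
              "table_baseline.csv", "table_unadjusted.csv", "table_iv.csv",
              "forest.csv")) {
    expect_true(file.exists(file.path(dir, "out", f)), label = f)
  }
  expect_error(emergiv:::read_analysis_config({
    p <- file.path(dir, "bad.yaml")
    yaml::write_yaml(list(data_dir = data_dir, not_a_key = 1), p)
    p
  }), "unknown config key")
})

test_that("CLI simulation is deterministic across invocations", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(emergiv_cli(c("simulate", "--preset", "weak_instrument",
                                 "--seed", "7", "--out", d1)))
  suppressMessages(emergiv_cli(c("simulate", "--preset", "weak_instrument",
                                 "--seed", "7", "--out", d2)))
  expect_identical(readLines(file.path(d1, "admissions.csv")),
                   readLines(file.path(d2, "admissions.csv")))
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
})
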