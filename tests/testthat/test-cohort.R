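# Eligibility rules and emergency-surgery classification.

specs <- default_condition_specs()

test_that("eligibility excludes by episode order, age, method and prior admission", {
  ok <- make_admission(1)
  ep3 <- make_admission(2, episodes = list(
    list(order = 1, specialty = "general_surgery", diag = "R69X"),
    list(order = 2, specialty = "general_surgery", diag = "R10X"),
    list(order = 3, specialty = "general_surgery", diag = "K35X")))
  young <- make_admission(3, age = 17)
  elective <- make_admission(4, method = "elective")
  medical <- make_admission(5, episodes = list(
    list(order = 1, specialty = "general_medicine", diag = "K35X")))
  prior <- make_admission(6, patient = "P7", admit = 200)   # relevant, emergency
  index7 <- make_admission(7, patient = "P7", admit = 400)  # 200 days later
  data <- bind_admissions(ok, ep3, young, elective, medical, prior, index7)
  built <- build_cohort(data, specs$appendicitis, index_start = 390,
                        index_end = 600)
  expect_setequal(built$cohort$admission_id, 1)
  tally <- built$exclusions
  count <- function(r) tally$n[tally$rule == r]
  expect_equal(count("no_qualifying_diagnosis"), 1L)   # diagnosis only in episode 3
  expect_equal(count("age_under_minimum"), 1L)
  expect_equal(count("non_emergency_method"), 1L)
  expect_equal(count("non_surgical_specialty"), 1L)
  expect_equal(count("prior_relevant_admission"), 1L)
  # tally + cohort = candidates in the index window
  expect_equal(sum(tally$n[tally$rule != "outside_index_window"]) +
                 nrow(built$cohort), 6L)
})

test_that("the 12-month prior-admission rule is a strict 365-day window", {
  prior <- make_admission(1, patient = "PX", admit = 30)
  index <- make_admission(2, patient = "PX", admit = 400)   # 370 days later
  data <- bind_admissions(prior, index)
  built <- build_cohort(data, specs$appendicitis, index_start = 395,
                        index_end = 600)
  expect_true(2 %in% built$cohort$admission_id)
  # a non-relevant prior emergency admission never excludes
  prior2 <- make_admission(3, patient = "PY", admit = 300, episodes = list(
    list(order = 1, specialty = "general_surgery", diag = "R10X")))
  index2 <- make_admission(4, patient = "PY", admit = 420)
  data2 <- bind_admissions(prior2, index2)
  built2 <- build_cohort(data2, specs$appendicitis, index_start = 395,
                         index_end = 600)
  expect_true(4 %in% built2$cohort$admission_id)
})

test_that("the second-diagnosis-field rule applies to intestinal obstruction only", {
  obs <- make_admission(1, episodes = list(
    list(order = 1, specialty = "general_surgery", diag = "C18X|K56X")))
  built <- build_cohort(bind_admissions(obs), specs$intestinal_obstruction,
                        index_start = 390, index_end = 600)
  expect_equal(nrow(built$cohort), 1L)
  # same structure under appendicitis: K35 in second field does not qualify
  app <- make_admission(2, episodes = list(
    list(order = 1, specialty = "general_surgery", diag = "C18X|K35X")))
  built2 <- build_cohort(bind_admissions(app), specs$appendicitis,
                         index_start = 390, index_end = 600)
  expect_equal(nrow(built2$cohort), 0L)
})

test_that("treatment classification honours condition-specific time windows", {
  hern <- make_admission(1, los = 10, episodes = list(
    list(order = 1, specialty = "general_surgery", diag = "K40X")),
    procedures = list(list(code = "T20X", day = 4)))
  built <- build_cohort(bind_admissions(hern), specs$hernia,
                        index_start = 390, index_end = 600)
  expect_false(built$cohort$es)                      # hernia window is 3 days
  app <- make_admission(2, los = 10, procedures = list(
    list(code = "H01X", day = 2)))
  built <- build_cohort(bind_admissions(app), specs$appendicitis,
                        index_start = 390, index_end = 600)
  expect_true(built$cohort$es)
  expect_equal(built$cohort$days_to_surgery, 2L)     # within the 7-day window
  div <- make_admission(3, los = 25, episodes = list(
    list(order = 1, specialty = "general_surgery", diag = "K57X")),
    procedures = list(list(code = "H33X", day = 20)))
  built <- build_cohort(bind_admissions(div), specs$diverticular_disease,
                        index_start = 390, index_end = 600)
  expect_true(built$cohort$es)                       # any time within admission
  # earliest qualifying procedure defines days_to_surgery
  app2 <- make_admission(4, los = 10, procedures = list(
    list(code = "H01X", day = 5), list(code = "H02X", day = 1)))
  built <- build_cohort(bind_admissions(app2), specs$appendicitis,
                        index_start = 390, index_end = 600)
  expect_equal(built$cohort$days_to_surgery, 1L)
  bad <- data.frame(admission_id = 4, code = "H01X", date = 300)
  expect_error(
    classify_treatment(built$cohort |>
                         dplyr::rename(admission_date = index_date),
                       bad, specs$appendicitis),
    "before admission")
})

test_that("sensitivity definitions re-derive ES flags as specified", {
  mk <- function(id, day, code = "H01X") {
    make_admission(id, los = 12, procedures = list(list(code = code, day = day)))
  }
  data <- bind_admissions(mk(1, 1), mk(2, 2), mk(3, 4), mk(4, 4), mk(5, 5),
                          mk(6, 9, "H03X"))
  spec <- specs$appendicitis
  built <- build_cohort(data, spec, index_start = 390, index_end = 600)
  expect_equal(sum(built$cohort$es), 5L)
  # upper quartile of observed days-to-surgery (1,2,4,4,5) is 4
  red <- apply_sensitivity_definition(built$cohort, data, spec, "reduced_window")
  expect_equal(red$threshold, 4)
  expect_false(red$cohort$es[red$cohort$admission_id == 5])  # day 5 flips to NES
  expect_true(all(red$cohort$es[red$cohort$admission_id %in% c(1, 2, 3, 4)]))
  # strict codes: H03 procedures no longer qualify
  data2 <- bind_admissions(mk(7, 1), mk(8, 2, "H03X"))
  built2 <- build_cohort(data2, spec, index_start = 390, index_end = 600)
  strict <- apply_sensitivity_definition(built2$cohort, data2, spec, "strict_codes")
  expect_true(strict$cohort$es[strict$cohort$admission_id == 7])
  expect_false(strict$cohort$es[strict$cohort$admission_id == 8])
  # strict list equal to the full list leaves flags unchanged
  spec_same <- condition_spec("appendicitis", include_codes = spec$include_codes,
                              es_procedure_codes = spec$es_procedure_codes,
                              es_window_days = spec$es_window_days)
  same <- apply_sensitivity_definition(built2$cohort, data2, spec_same,
                                       "strict_codes")
  expect_equal(same$cohort$es, built2$cohort$es)
  empty <- built2$cohort[0, ]
  expect_error(apply_sensitivity_definition(empty, data2, spec, "reduced_window"),
               "no ES rows")
})

test_that("shrinking the window or code list never converts NES to ES", {
  cfg <- sim_config(n_hospitals = 4, admissions_per_hospital = 40, seed = 31)
  sim <- generate_dataset(cfg)
  spec <- specs$appendicitis
  built <- build_cohort(sim$data, spec)
  for (w in c(5, 3, 1)) {
    cls <- classify_treatment(
      data.frame(admission_id = built$cohort$admission_id,
                 admission_date = built$cohort$index_date,
                 discharge_date = built$cohort$discharge_date),
      sim$data$procedures, spec, window_days = w)
    expect_true(all(built$cohort$es[match(cls$admission_id[cls$es],
                                          built$cohort$admission_id)]))
  }
  cls2 <- classify_treatment(
    data.frame(admission_id = built$cohort$admission_id,
               admission_date = built$cohort$index_date,
               discharge_date = built$cohort$discharge_date),
    sim$data$procedures, spec, codes = spec$es_procedure_codes[1])
  expect_true(all(built$cohort$es[match(cls2$admission_id[cls2$es],
                                        built$cohort$admission_id)]))
})

test_that("vectorised cohort construction matches the brute-force scan", {
  for (cond in c("appendicitis", "intestinal_obstruction")) {
    cfg <- sim_config(n_hospitals = 3, admissions_per_hospital = 25,
                      condition = cond, seed = 77)
    sim <- generate_dataset(cfg)
    spec <- specs[[cond]]
    built <- build_cohort(sim$data, spec)
    orc <- oracle_cohort(sim$data, spec, built$index_start, built$index_end)
    expect_setequal(built$cohort$admission_id, orc$admission_id)
    m <- match(orc$admission_id, built$cohort$admission_id)
    expect_equal(built$cohort$es[m], orc$es)
    expect_equal(built$cohort$days_to_surgery[m], as.integer(orc$days_to_surgery))
    expect_equal(built$cohort$qualifying_episode_order[m],
                 as.integer(orc$qualifying_episode_order))
  }
})

test_that("condition specs survive a YAML round trip and validate inputs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_condition_specs(specs, path)
  back <- read_condition_specs(path)
  expect_equal(names(back), names(specs))
  expect_equal(back$diverticular_disease$es_window_days, ANY_TIME)
  expect_equal(back$hernia$es_window_days, 3)
  expect_equal(back$intestinal_obstruction$second_field_rule$main_prefixes,
               specs$intestinal_obstruction$second_field_rule$main_prefixes)
  expect_error(condition_spec("x", "K35", "H01", 7,
                              strict_es_procedure_codes = "H99"),
               "strict_es_procedure_codes")
  expect_error(condition_spec("x", character(0), "H01", 7), "include_codes")
})
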