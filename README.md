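# emergiv

Comparative effectiveness of emergency surgery versus non-emergency
management strategies for acute abdominal admissions, estimated from coded
hospital records with a hospital-preference instrument.

## The problem

For emergency admissions with appendicitis, gallstone disease,
diverticular disease, abdominal wall hernia or intestinal obstruction,
clinicians choose between emergency surgery (ES) and non-emergency
strategies (NES — medical management, interventional radiology, deferred
surgery). In administrative data this choice is confounded by disease
severity that is largely uncoded, so a case-mix-adjusted regression is
biased. Hospitals, however, differ persistently in how readily they
operate; a patient of given prognosis may receive ES at one hospital and
NES at another. That practice variation supplies an instrument: the
hospital's **tendency to operate (TTO)**, the proportion of its eligible
emergency admissions in the previous 12 months that received ES.

`emergiv` implements the full pipeline:

* **Cohort construction** from relational admission/episode/procedure
  tables: eligibility rules (adult, emergency, relevant diagnosis in
  episode 1–2 under a surgical specialty, no relevant emergency admission
  in the prior 365 days) and ES classification by condition-specific
  procedure lists and time windows (3 days for hernia, 7 for appendicitis,
  gallstone disease and obstruction, any time within the admission for
  diverticular disease), with strict-code and reduced-window sensitivity
  variants.
* **Case-mix**: Charlson comorbidity index and a 32-deficit
  administrative frailty index (severe = 6+ deficits), from configurable
  YAML code maps.
* **Outcomes**: days alive and out of hospital at 90 days (DAOH-90; zero
  for decedents, 90 − total LOS for survivors), 90-day mortality, LOS
  within 90 days, 30-day emergency re-admission, plus the
  count-days-for-decedents DAOH variant.
* **Instrument machinery**: per-admission TTO with self-exclusion and
  minimum-volume guard, first-stage partial F with hospital-clustered
  variance (weak-instrument rule F > 10), covariate balance by
  standardised mean differences across treatment and instrument splits,
  and raw hospital quality proxies.
* **Person-level IV estimation**: probit first stage on the TTO, a
  two-stage residual-inclusion second stage (GLM with identity or probit
  link, treatment × covariate and treatment × residual interactions),
  person-level effects by counterfactual prediction, aggregation overall
  and by subgroup, and hospital-clustered bootstrap percentile CIs
  (default 300 replications), with a naive no-unmeasured-confounding
  comparator.
* **A synthetic admissions generator** with known causal ground truth
  (hospital preference instrument, unobserved severity confounder,
  heterogeneous effects by frailty), so the whole pipeline — including
  bias removal — is validated end to end.

## Worked example

```r
library(emergiv)

cfg  <- scenario_presets("heterogeneous_frailty", seed = 42)  # 40 hospitals, ~20k admissions
sim  <- generate_dataset(cfg)
prep <- prepare_analysis_data(sim$data, condition = cfg$condition)

first_stage_strength(prep$cohort, c("age_band", "sex", "charlson_band",
                                    "frailty_category"))$F
#> [1] 8844.7

est <- iv_effects(prep$cohort, "daoh", model_spec(seed = 1), reps = 300)
est[est$partition %in% c("overall", "frailty_category"), ]
#>          partition    level estimate     n ci_low ci_high p_value
#> 1          overall  overall    3.174 17547  2.134    4.41 0.00664
#> 2 frailty_category      fit    4.962  4966  3.817    6.45 0.00664
#> 3 frailty_category     mild    4.640  7593  3.667    5.84 0.00664
#> 4 frailty_category moderate    0.556  3797 -0.994    2.20 0.41860
#> 5 frailty_category   severe   -5.277  1191 -9.416   -1.16 0.01993

naive_estimate(prep$cohort, "daoh")$estimate[1]
#> [1] 1.56

true_effects(sim$truth, ids = prep$cohort$admission_id)$true_ate
#> [1] 3.51
```

Reading the numbers: the instrument is strong (F ≫ 10). The generator's
realised true average effect of ES on DAOH-90 in this cohort is +3.51
days, with the effect reversed for severe frailty (true severe-frailty
effect −3.59 days). The IV estimate, 3.17 days (95% CI 2.13–4.41),
recovers the truth and the qualitative reversal for severe frailty
(−5.28, CI −9.42 to −1.16), while the naive case-mix-adjusted regression
(1.56 days) is pulled down by unmeasured severity. For subgroup effects in
high-mortality strata, `iv_effects(..., outcome = "daoh_composite")`
estimates the DAOH effect through its mortality and LOS components, which
the methods vignette shows is better calibrated there. Report-shaped outputs
come from `table_baseline()`, `table_unadjusted()`, `table_iv()` and
`forest_export()`, and the whole pipeline is scriptable via the
`inst/exec/emergiv` CLI (`simulate`, `build`, `analyze`, `report`, `run`).

## Layout

```
R/                  implementation (generator, cohort, casemix, outcomes,
                    instrument, IV engine, reporting, CLI)
inst/extdata/       worked-example cohort summary CSVs
inst/exec/emergiv   command-line wrapper
tests/testthat/     unit, property and acceptance tests with oracles
scripts/acceptance.R
vignettes/          methods vignette
```
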