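Package: emergiv
Title: Comparative Effectiveness of Emergency Surgery via a Hospital
    Preference Instrument
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating emergency surgery against non-emergency
    management strategies for acute abdominal admissions using coded
    hospital records. Provides cohort construction from admission, episode
    and procedure tables with condition-specific eligibility rules; Charlson
    comorbidity and deficit-accumulation frailty case-mix derivation;
    construction of days alive and out of hospital (DAOH) and related
    outcomes; a hospital tendency-to-operate preference instrument with
    strength and balance diagnostics; and a person-level two-stage
    residual-inclusion instrumental-variable estimator with subgroup
    effects and hospital-clustered bootstrap confidence intervals. Includes
    a synthetic admissions generator with known causal ground truth so the
    whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    sandwich,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
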