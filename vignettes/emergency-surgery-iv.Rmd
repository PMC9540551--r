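---
title: "Estimating the effectiveness of emergency surgery with a hospital preference instrument"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the effectiveness of emergency surgery with a hospital preference instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emergiv)
```

## The problem

For emergency admissions with common acute abdominal conditions —
appendicitis, gallstone disease, diverticular disease, abdominal wall
hernia, intestinal obstruction — clinicians choose between emergency
surgery (ES) and non-emergency strategies (NES: medical management,
interventional radiology, deferred surgery). Administrative hospital data
hold the scale needed to compare these strategies, but treatment choice is
confounded by disease severity, much of which is never coded. A naive
regression that adjusts only for coded case-mix therefore attributes part
of the severity gradient to the treatment.

`emergiv` implements the full analysis pipeline for this problem on coded
admission records: cohort construction, case-mix derivation, outcome
construction, a preference-based instrument, and a person-level
instrumental-variable (IV) estimator, together with a synthetic data
generator whose causal structure is known exactly, so that every stage of
the pipeline — including the estimator's ability to remove unmeasured
confounding — is testable.

## Cohort and treatment definition

An admission is eligible when a consultant episode within it carries a
relevant main diagnosis in the first or second episode, under a surgical
specialty, within an emergency admission, for an adult (18+), with no
relevant emergency admission in the preceding 365 days. For intestinal
obstruction, a relevant code in the second diagnosis field also qualifies
when the main diagnosis is colorectal cancer. Exclusions are tallied
against the first failing rule in a fixed order so that flow-diagram
accounting is reproducible.

Emergency surgery is a qualifying procedure within a condition-specific
window of admission: 3 days for hernia; 7 days for appendicitis, gallstone
disease and intestinal obstruction; any time within the admission for
diverticular disease. Everything else is the non-emergency strategy,
including qualifying procedures performed after the window. Two
sensitivity re-classifications are built in: a stricter procedure list,
and a reduced window set at the upper quartile of the observed
days-to-surgery distribution among default-ES admissions.

Code matching is prefix-based on normalised, dot-stripped uppercase codes.
The shipped diagnosis and procedure code lists are synthetic defaults used
by the generator; both the condition specs and the case-mix code maps are
YAML-configurable so curated lists can be dropped in for real data.

## Case-mix

Two indices are derived from the diagnosis codes of the index admission
plus the patient's admissions in the preceding 365 days (the same lookback
as the eligibility rule; the ascertainment window is a configurable
choice):

* the Charlson comorbidity index, with each condition counted once and the
  classic 1/2/3/6 weights (configurable), banded 0 / 1 / 2 / 3+;
* a deficit-accumulation frailty index over 32 configured deficits, banded
  fit (0), mild (1–2), moderate (3–5), severe (≥ 6). Only the severe
  threshold is fixed by the index's definition; the lower cut-points are
  defaults and can be overridden.

## Outcomes

The primary outcome is days alive and out of hospital over 90 days
(DAOH-90). Spells occupy half-open intervals `[admission, discharge)`, so a
same-day discharge contributes zero days and LOS equals discharge minus
admission; overlapping or adjacent spells are merged and spells crossing
the horizon are truncated. Patients who die within the horizon score zero;
survivors score 90 minus total LOS, so DAOH + LOS = 90 for every survivor
— an identity the tests enforce on every fixture. A sensitivity variant
instead counts decedents' days alive and out of hospital before death; it
dominates the main definition row-wise and coincides for survivors.
Secondary outcomes are 90-day mortality, total LOS within 90 days, and
emergency re-admission within 30 days of the index discharge (conventions
for the re-admission clock vary; the discharge anchor is the standard
administrative metric and is documented here as a package choice).

## The instrument

The tendency to operate (TTO) of a hospital is the proportion of its
eligible emergency admissions in the previous 365 days that received ES,
excluding the index admission itself (and same-day admissions, so nothing
leaks from the index or the future). Admissions with fewer than
`min_volume = 10` eligible admissions in the window, or within the first
lookback year of data coverage, are flagged invalid and excluded from IV
fitting with a logged count; the default guards against degenerate 0/1
rates from tiny denominators.

Instrument strength is assessed as the partial F statistic for the TTO in
a linear first stage with hospital-clustered (CR1) variance — the F > 10
rule of thumb is defined for linear first stages even though estimation
uses a probit. Covariate balance is summarised as standardised mean
differences across treatment groups and across instrument halves (above
versus below the median TTO; the two-group split is the simplest rendering
of "levels of the instrument" and is configurable).

The second stage can adjust for raw hospital quality proxies: eligible
emergency admission volume and 90-day mortality per hospital-year, joined
at the year strictly before each admission, plus time-constant
baseline-year values. Hospital-years without admissions are missing, never
zero.

## The estimator

The person-level IV model is a two-stage residual-inclusion (control
function) estimator:

1. **First stage.** Probit of ES receipt on the TTO, case-mix covariates
   and time period. From the fit we keep the propensity and the probit
   generalised residual \(r = T\,\lambda(x\beta) - (1-T)\,\lambda(-x\beta)\),
   with \(\lambda\) the inverse Mills ratio; at the MLE the residual has
   mean zero (the intercept's score equation), which the tests assert on
   every converged fit.
2. **Second stage.** GLM of the outcome on treatment, covariates,
   treatment × covariate interactions, the generalised residual and
   treatment × residual, with identity link for DAOH/LOS and probit link
   for mortality/re-admission. The residual terms absorb unmeasured
   severity; the interactions allow effect modification over observables
   and over unobservables (essential heterogeneity).
3. **Person-level effects.** For each row, the predicted outcome with
   treatment set to 1 minus the prediction with treatment set to 0,
   covariates and residual held fixed; binary outcomes contrast the
   link-inverse values, so effects are risk differences.
4. **Aggregation.** The overall estimate is the mean person-level effect;
   subgroup estimates are within-subgroup means, so the overall estimate
   is exactly the size-weighted mean of any partition's estimates (checked
   exactly on every run).
5. **Inference.** A cluster bootstrap resamples hospitals with replacement
   (same number of clusters) and re-runs both stages, person effects and
   aggregation in each replicate; 2.5/97.5 percentile CIs; two-sided
   p-values from the symmetric bootstrap tail position of zero. Replicates
   that fail to converge are dropped and counted, with an error if more
   than 10% fail. Percentile intervals need not contain the point estimate
   in principle; `ci_low <= ci_high` always holds. The default is 300
   replications.

### Direct versus composite DAOH effects

DAOH is a composite: `(1 - death) * (90 - LOS)` up to interval
bookkeeping. The package estimates DAOH effects two ways. The direct route
models DAOH itself with an identity link — simple, and validated unbiased
for overall effects. The composite route (`outcome = "daoh_composite"`)
fits the probit-2SRI mortality model and the identity-2SRI LOS model and
combines their per-arm predictions as `(1 - p_death) * (90 - LOS)` (LOS
clipped to the horizon).

The distinction matters for subgroup effects in strata with materially
different mortality. Unmeasured severity shifts the *latent* death index
linearly, but its effect on the death *probability* — and hence on DAOH —
scales with the density of the link at the stratum's baseline risk, which
is several times larger for severe frailty than for fit patients. A direct
DAOH model carries a single linear residual term, so this steepening leaks
into the treatment × frailty coefficients; in validation runs the direct
model understated the severe-frailty effect by about 2 days, and
stratum-specific residual slopes were too collinear with the treatment ×
frailty terms to help. The composite model needs no such slopes: the
nonlinearity lives in the probit link of the mortality component, where
the residual term is on the scale on which unmeasured severity is actually
linear. In the same validation runs the composite estimator's
severe-frailty bias was indistinguishable from zero. Overall estimates
from the two routes agree; the package therefore reports overall effects
from the direct model and recommends the composite for frailty (or other
high-mortality-contrast) subgroup effects. The composite multiplies two
fitted components, so it is noisier than the direct model and needs
cohorts large enough for a stable stratum-level mortality model (its
validation used the full ~20,000-admission scenario); on small cohorts its
subgroup estimates can be erratic.

The exact published form of person-centred IV estimators varies across the
methodological literature (residual inclusion, local-IV/MTE integrations);
the residual-inclusion rendering with counterfactual prediction was chosen
as the form most directly compatible with a probit first stage, GLM second
stages and person-level effect language, and is validated against ground
truth below. The naive comparator (`method = "naive"`) is the same
machinery without the residual terms — OLS for continuous outcomes,
logistic regression with marginal standardisation for binary ones — and
assumes no unobserved confounding.

Model covariates default to age band plus continuous age, sex, ethnicity,
deprivation quintile, Charlson band plus score, frailty category plus
deficit count, and admission year. The continuous terms matter: with
banded terms alone, within-band severity gradients leave a residual
confounding of roughly 0.15 DAOH days in validation runs, affecting naive
and IV estimates alike. Missing covariates are handled complete-case with
a logged count.

## The synthetic data generator

`generate_dataset()` draws hospitals with a latent operating preference on
the probit scale (SD = `preference_spread`), patients with demographics,
an unobserved severity factor U, Bernoulli deficits and comorbidities
whose probabilities rise with age and U, and a treatment latent index
combining `instrument_strength` × preference, case-mix, and
`confounding_strength` × U. Outcomes are built, not drawn: death within 90
days follows a probit in age, frailty and U; the index stay is a truncated
log-normal count shifted by the treatment effect; re-admissions arrive
after a random gap. Both potential spell sets are constructed per
admission and DAOH is derived from them with the same interval logic the
outcomes module uses, so each person's true effect on DAOH is known
exactly, and the emitted records exercise the cohort, case-mix, outcome
and instrument modules end to end (comorbidity and deficit codes are
emitted through the same code maps the case-mix module reads).

Defaults describe 40 hospitals with ~500 eligible admissions each over a
two-year index window after a one-year lookback (~20,000 analysable
admissions), a preference SD of 0.6 (first-stage F in the hundreds to
thousands, matching the range seen in national data), ~3.5% 90-day
mortality, a median index stay around 10 days, and ~10% re-admission.
`ate_days = 5` shifts the index stay of treated survivors by five days;
decedents' effects are zero by construction and stays are floored at one
day, so the realised population ATE is about 4.6 days — the generator
reports the realised truth exactly per dataset, and recovery is always
judged against it. The severity confounder has no quantitative description
in routine data; its loadings (0.5 on the treatment latent scale, 0.3 on
the death probit, 0.2 on log-LOS) were chosen once to make the naive
estimator's bias clearly material (≈ 2 days) while keeping outcome scales
realistic.

Named presets pin the validation scenarios: `null_effect`,
`unconfounded`, `strong_iv_confounded`, `heterogeneous_frailty` (effect
modifiers −3 moderate, −10 severe, reversing the sign of the effect for
severe frailty), and `weak_instrument` (preference coefficient near zero,
for F < 10 detection). Deliberate fractions of ineligible records
(under-18, elective, relevant diagnosis only in episode 3, non-surgical
specialty), repeat prior admissions, late and non-qualifying procedures
exercise every exclusion and classification rule.

What the generator does not emulate: real coding dialects and episode
nesting beyond an episode-order integer, hospital-level outcome effects
(the exclusion restriction holds by construction), transfers or
overlapping admissions (flagged with a warning, kept), and
condition-specific clinical detail. Passing validation therefore shows the
machinery is correct under the stated causal structure, not that the
structure matches any particular real dataset.

## Numerical and design choices

* Dates are integer day offsets; all intervals are half-open. Days to
  surgery are whole days from admission (floor).
* The inverse Mills ratio is computed on the log scale
  (`exp(log dnorm - log pnorm)`), stable for extreme linear predictors.
* First-stage fits drop aliased columns as `glm.fit` pivots; user-facing
  second stages error on rank deficiency naming the collinear terms, while
  bootstrap replicates drop aliased columns instead (resampled subsets can
  lose factor levels). A probit fit counts as separated only when more
  than 2% of fitted probabilities are degenerate; the bootstrap tolerates
  up to 10% failed replicates.
* Continuous DAOH is modelled with an identity link and unbounded
  predictions (no truncation to [0, 90]); the target is a mean difference,
  and this is a documented limitation.
* Bootstrap quantiles use the default type-7 definition; p-values use the
  add-one tail estimate `2·min((1+#{draws ≤ 0}), (1+#{draws ≥ 0}))/(B+1)`.
* The reduced-window sensitivity threshold is the type-7 upper quartile of
  the observed days-to-surgery.
* Rounding in report tables: means and SDs to 2 decimal places,
  percentages to 1, mean differences of magnitude ≥ 10 to 1 decimal place.
  The unadjusted table's CI is an unequal-variance normal approximation —
  the convention behind such published tables is rarely stated, so these
  intervals are presentation aids, not inferential claims.

## Validation problem sizes

The shipped test suite validates, among other things: DAOH/LOS against a
day-by-day occupancy oracle on 1,000 random spell fixtures; cohort
membership against a brute-force per-admission scan; first-stage F
detection over 20 seeds per preset at the default scenario size; parameter
recovery over 50 replicate datasets of `strong_iv_confounded` (40
hospitals, ~20,000 admissions) with the naive comparator biased by about 2
days; severe-frailty CATE recovery over 20 replicates of
`heterogeneous_frailty`; and bootstrap CI coverage over 100 replicate
datasets of a scaled-down `unconfounded` scenario (30 hospitals, ~1,700
analysable admissions, 200 bootstrap replications). These sizes were
chosen to give stable Monte-Carlo checks at desk scale; the estimator
itself has no size-dependent switches.

## Known limitations

* TTO is hospital-level; surgeon-level preference instruments are out of
  scope.
* The IV estimand and its validity rest on the instrument assumptions;
  the package verifies relevance (F) and observable balance, but exclusion
  is untestable and simply holds in the generator.
* The naive/IV contrast validates bias removal under the generator's
  structure; with real data the residual-inclusion form is an
  approximation whose adequacy depends on how unmeasured severity enters
  outcomes.
* Overlapping admissions (transfers) are kept with a warning rather than
  merged; administrative sources differ in how they should be handled.
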