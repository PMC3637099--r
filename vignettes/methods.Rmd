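---
title: "Validating claims-code CKD algorithms against an eGFR reference standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating claims-code CKD algorithms against an eGFR reference standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdcodes)
```

## The validation design

Administrative claims carry no laboratory values, so chronic kidney disease
(CKD) is often imputed from diagnosis codes. `ckdcodes` quantifies how well
such a code rule agrees with the laboratory truth in an elderly cohort. The
design anchors everything to an **index date** — the first eligible
outpatient prescription per patient — because the outpatient setting
captures patients at clinical stability and pharmacoepidemiologic studies
accrue on prescriptions. Eligibility demands a serum creatinine in the year
before the index (so a reference standard exists), age at least 66
completed years (guaranteeing a year of drug-plan history under a 65+
benefit), and no recent hospitalization (2-day washout), dialysis (1 year)
or kidney transplant (5 years), which would either contaminate the
"first initiated outpatient" interpretation or make low eGFR a treatment
artefact rather than chronic disease.

The **reference standard** converts the baseline creatinine to an estimated
glomerular filtration rate with the 2009 CKD-EPI creatinine equation and
thresholds it. The primary disease definition is eGFR < 45 mL/min per
1.73 m² (stage IIIb or worse — a clinically important reduction in elderly
patients, and more stable on retest than milder reductions); < 60 and < 30
are companion thresholds. Thresholds, not mutually exclusive stages, mirror
how the algorithm is used in practice. The three labels nest
(<30 ⊂ <45 ⊂ <60), and the five reporting categories (≥60, 45–59, 30–44,
15–29, <15) use lower-inclusive boundaries so that eGFR = 45 falls in
45–59.

The **index test** is a code-list rule: positive if at least *k* (default 1)
qualifying code occurrences appear in `[index − 5y, index)`. Codes combine
by Boolean OR only. Agreement is summarised by sensitivity, specificity,
positive and negative predictive value from the 2×2 table, each with a
Wilson score interval, overall and within strata (age 66–80 vs >80; women
vs men; each threshold).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `lab_lookback_days` | 365 | days | a creatinine older than a year no longer reflects baseline function |
| `min_age_years` | 66 | completed years | one full year of baseline drug-plan data |
| `hospitalization_washout_days` | 2 | days | prescriptions issued at discharge are not outpatient-initiated |
| `dialysis_lookback_days` / `transplant_lookback_years` | 365 d / 5 y | | kidney-failure treatment pre-empts "chronic disease by eGFR" |
| `lookback_years` (codes) | 5 | years | chronic codes accumulate slowly; 5 years balances sensitivity against stale codes |
| `min_occurrences` | 1 | count | the ≥2 variant trades sensitivity for PPV |
| `min_sensitivity` (assembly) | 0.03 | proportion | codes below 3% sensitivity add noise unless conceptually tied to included codes |
| `level` | 0.95 | | Wilson intervals at the conventional level; z is the exact normal quantile (1.959964), not 1.96 |

## What the simulator emulates — and what it does not

The generator produces a five-table administrative bundle (patients, labs,
codes, prescriptions, events) plus a ground-truth table that the pipeline
never reads. Its defaults are the study conditions of a large elderly
Ontario-style cohort:

* **eGFR categories** in proportions 63.6 / 21.0 / 11.1 / 3.7 / 0.5 %
  (≥60, 45–59, 30–44, 15–29, <15), the marginal distribution reported for
  such cohorts; within a category the true eGFR is uniform. The paperless
  choice of a within-category shape is deliberate: only the category
  margins are knowable, and uniform draws add no spurious structure. The
  <15 band is bounded below at 2 mL/min per 1.73 m² to keep eGFR positive.
* **Demographics**: 54.4% women; age 66 plus a gamma(1.3, scale 8) tail,
  giving median ≈ 75 and IQR ≈ 70–81, capped at 105.
* **Labs**: the baseline creatinine is obtained by closed-form inversion of
  CKD-EPI at the patient's completed age and sex, so the reference standard
  recovers the true eGFR to machine precision and labels are consistent by
  construction (the inverse is unique because the equation is strictly
  decreasing in creatinine). 75% of baseline draws are outpatient, 20%
  inpatient, 5% emergency; simulated inpatient stays hold a single value
  dated at discharge, so the pre-discharge selection rule is exercised as
  an identity there and its substitution behaviour is tested on
  constructed fixtures. 42.2% of patients carry a prior test 90–365 days
  earlier whose eGFR is the truth plus Gaussian noise (SD 7.4 mL/min per
  1.73 m², calibrated so the median absolute retest gap is ≈ 5).
* **Codes**: per (patient, code) Bernoulli draws with probabilities
  conditional on the true eGFR stratum, dated uniformly over the look-back.
  The default map assigns each of the 11 catalog codes its observed
  single-code sensitivity when eGFR < 45 and its false-positive rate
  (1 − specificity) otherwise. Half of 3-character ICD-10 emissions are
  recorded as 4-character children to exercise prefix matching.
* **Rule violators**: independent fractions of patients (1–2% each) are
  made to violate each eligibility rule and carry exactly one prescription,
  so each exclusion is decisive and the tally is interpretable; eligible
  patients may carry later decoy prescriptions to test "selected once"
  logic.

Limitations of the emulation — and therefore of what passing tests show
about real data: codes are emitted **independently**, whereas real CKD
codes co-occur strongly. Under independence the 11-code union reaches a
sensitivity near 0.47 at the same single-code rates, where correlated real
coding gives ≈ 0.33; union sensitivity from this simulator is an upper
bound, and direction-of-effect tests (men vs women; k = 2 vs k = 1) are the
meaningful checks, not absolute union sensitivity. The simulator also
draws age/sex independently of eGFR category by default (a joint
distribution is not identifiable from marginal tables; per-stratum
probabilities can be supplied), generates no comorbidity or income
structure, and models only the two creatinine tests the stability check
needs.

## Numerical and convention choices

* **Windows.** Labs: `(index − 365 d, index]` — a same-day pre-prescription
  draw qualifies. Codes: `[index − 5 y, index)` — codes must precede the
  prescription; a closed right end is available by configuration. Dialysis
  and transplant look-backs are open on both ends. Calendar-year
  subtraction rolls month-ends back (Feb 29 safe).
* **Hospitalization washout.** Read as disqualifying the accrual event
  (the stated aim is prescriptions first initiated as an outpatient); the
  alternative reading — discard the baseline labs of recently hospitalized
  patients — is available as `hospitalization_rule = "exclude_lab"`.
* **Exclusion attribution.** Patients are scanned prescription by
  prescription; a patient with no qualifying prescription is counted once
  under the *first-failing* rule of their *last* candidate, in the fixed
  order age, lab, hospitalization, dialysis, transplant.
* **Ties.** Several creatinine values on the selected day resolve to the
  lowest (transient elevations are the enemy; configurable to highest).
  Tied prescriptions on the same date resolve by input order, making runs
  deterministic and independent of row shuffling.
* **Occurrence counting.** Pooled across codes on distinct (code, day)
  pairs: the same code twice on one day counts once, two different codes on
  different days count twice; raw-record counting is a config switch.
  ICD-10 children normalise to their catalog prefix before deduplication.
* **CKD-EPI details.** The race multiplier (1.159) is off by default —
  these administrative data carry no race field — but can be enabled. Age
  enters as completed years at index. eGFR is carried at full precision;
  rounding happens only at display.
* **Degenerate inputs.** Zero denominators (e.g. PPV of a never-observed
  code) yield `NA`, with a warning in interactive use; an empty stratum
  yields a null row with a warning; `n_patients = 0` yields an empty,
  schema-complete bundle.
* **Comparison test.** Between-stratum sensitivity differences use the
  two-proportion Pearson chi-square without continuity correction
  (`prop.test(correct = FALSE)`), two-sided; Fisher's exact test is the
  small-stratum alternative. The choice of test is an implementation
  decision documented here, not a claim about what any particular study
  used.
* **Percentiles.** Medians use the midpoint convention for even counts;
  IQRs are type-7 linearly interpolated quantiles.
* **Reproducibility.** One seed drives every random draw; identical
  parameters give byte-identical bundles and reports. The run manifest
  hashes the configuration and each input table (and deliberately omits
  wall-clock timestamps so reruns are byte-identical).
* **Bit-exact I/O.** Doubles are written with `%.17g` and re-parsed with
  `strtod`, so a written bundle re-reads identically to the last bit.

## Problem sizes in the test suite

Unit tests run on constructed fixtures and cohorts of 300–8,000 simulated
patients. Distributional checks use 50,000 patients (category frequencies
within 3 binomial SDs). The calibration check runs 200 replicates of a
20,000-patient cohort with code-emission probability 0.40 in the diseased
stratum and 0.03 elsewhere, and verifies that the Wilson 95% interval
around the pipeline's sensitivity estimate covers 0.40 at close to the
nominal rate. These sizes give Monte-Carlo error well below the tolerances
asserted while keeping the suite fast on a single CPU.

## Known limitations

Absolute multi-code performance in simulation overstates correlated
real-world coding (see above). The pipeline validates *point-in-time* eGFR:
clinical CKD diagnosis requires two reduced measurements ≥ 3 months apart,
which the stability summary approximates but does not enforce.
Proteinuria-defined CKD without low eGFR is out of scope, as are
ROC/threshold-free summaries and any automated semantic grouping of codes
(the "conceptually similar" additions to an assembled algorithm are an
explicit, human-supplied list).
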