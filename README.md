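# ckdcodes

Validation tools for administrative-database code algorithms that detect
chronic kidney disease (CKD).

## The problem

Health-services researchers often need to identify patients with CKD in
claims databases where no laboratory results are available — only hospital
encounter diagnoses (ICD-10) and physician billing claims. A *case-finding
algorithm* is a rule over those coded records: a patient is classified CKD
positive when at least *k* codes from a code list appear in a look-back
window before an index date. Before such an algorithm can be trusted, its
agreement with a laboratory reference standard must be quantified.

`ckdcodes` implements that validation pipeline for an elderly cohort
accrued at an index outpatient prescription:

1. **Cohort accrual** — one index date per patient from outpatient
   prescriptions, with eligibility rules (age ≥ 66; a serum creatinine in
   the prior year; no hospitalization in the 2 days before the
   prescription; no dialysis in the prior year; no transplant in the prior
   5 years).
2. **Reference standard** — the most recent baseline serum creatinine
   (pre-discharge value for inpatient stays) converted to an estimated
   glomerular filtration rate with the 2009 CKD-EPI creatinine equation

   eGFR = 141 · min(Scr/κ, 1)^α · max(Scr/κ, 1)^(−1.209) · 0.993^age · 1.018[female]

   (Scr in mg/dL = μmol/L ÷ 88.4; κ = 0.7/0.9, α = −0.329/−0.411 for
   women/men), classified at the thresholds eGFR < 60, < 45 (primary),
   and < 30 mL/min per 1.73 m².
3. **Code algorithm** — code-list rules over a 5-year look-back, including
   the final 11-code CKD list (ICD-10 E102, E112, E132, E142, I12, I13,
   N08, N18, N19; physician claims 403, 585), with per-code evaluation
   and greedy assembly (sensitivity ≥ 3% or explicit conceptual adds).
4. **Validity statistics** — 2×2 tables; sensitivity, specificity, PPV,
   NPV, prevalence with Wilson score 95% confidence intervals; stratified
   reports by age band and sex with chi-square sensitivity comparisons;
   median (IQR) creatinine/eGFR contrasts by algorithm flag.
5. **Synthetic cohort generator** — because real claims data cannot be
   shipped, a simulator produces complete input bundles (patients, labs,
   codes, prescriptions, events) with known ground truth: true eGFR drawn
   from realistic category proportions, creatinine back-computed by exact
   inversion of CKD-EPI, and codes emitted with probabilities conditional
   on the true eGFR stratum. Every stage of the pipeline is testable
   end-to-end and generating parameters are recoverable.

## Worked example

```r
library(ckdcodes)

params <- sim_params(n_patients = 20000, seed = 2024)
bundle <- simulate_cohort(params)

cohort <- accrue(bundle$patients, bundle$prescriptions,
                 bundle$labs, bundle$events)
exclusion_tally(cohort)
#>   reason              n
#> 1 age               184
#> 2 no_baseline_lab   405
#> 3 hospitalization   411
#> 4 dialysis          197
#> 5 transplant        102

ref   <- reference_standard(cohort, bundle$labs)
spec  <- algorithm_spec("ckd_final", ckd_final_codes())
flags <- flag_patients(cohort, bundle$codes, spec)

metrics(contingency(flags, ref, label = "lt45"))
#> <ckd_validity> n = 18701 (tp 1416, fp 718, fn 1471, tn 15096)
#>   sensitivity   49.0% (95% CI: 47.2 to 50.9)
#>   specificity   95.5% (95% CI: 95.1 to 95.8)
#>   ppv           66.4% (95% CI: 64.3 to 68.3)
#>   npv           91.1% (95% CI: 90.7 to 91.5)
#>   prevalence    15.4% (95% CI: 14.9 to 16.0)
#>   positives     11.4% (95% CI: 11.0 to 11.9)
```

Of 20,000 simulated patients, 18,701 enter the cohort; 15.4% have an eGFR
below 45. The 11-code algorithm flags 11.4% of patients; roughly half of
truly diseased patients carry a code (sensitivity 49.0%) while specificity
is high (95.5%) — the characteristic behaviour of claims-based CKD
detection: flagged patients very likely have CKD, but many cases go
uncoded. (The simulator emits codes independently, so the multi-code union
is somewhat more sensitive than real, correlated coding behaviour; see the
methods vignette.)

The whole analysis, including stratified tables and the eGFR stability
check, is one configuration-driven call:

```r
rep <- run_pipeline(list(seed = 2024, simulate = list(n_patients = 20000)))
rep
#> <ckd_report> 20000 patients, 18701 included, algorithm "ckd_final"
#>   eGFR <60: sens 23.8%, spec 95.5%, PPV 75.0%, NPV 69.0%
#>   eGFR <45: sens 49.0%, spec 95.5%, PPV 66.4%, NPV 91.1%
#>   eGFR <30: sens 53.8%, spec 90.4%, PPV 19.7%, NPV 97.8%
write_report(rep, "report/")
```

`rep$performance` holds the full stratified table (age 66–80 vs >80,
women vs men, each threshold, Wilson intervals, comparison p-values);
`rep$contrasts` the median (IQR) creatinine/eGFR by flag; `rep$stability`
the eGFR agreement with a prior test 90–365 days earlier. Variant
analyses — requiring ≥ 2 codes, restricting to outpatient labs, an
alternative code list from a YAML file — are one-line config changes.

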