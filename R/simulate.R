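#' Simulation parameters for a synthetic claims cohort
#'
#' Bundles and validates the parameters of [simulate_cohort()]. Defaults
#' emulate an elderly Ontario-style cohort: accrual window mid-2007 to
#' end-2010, minimum age 66 (median ~75), 54.4% female, baseline eGFR
#' category proportions matching the marginal distribution of a large
#' published elderly cohort (63.6% / 21.0% / 11.1% / 3.7% / 0.5% across
#' >=60, 45-59, 30-44, 15-29, <15), 75% of baseline creatinine draws from
#' an outpatient laboratory, and per-code emission probabilities
#' conditional on the eGFR <45 stratum (see [table2_emission()]).
#'
#' @param n_patients Number of patients to simulate (may be 0).
#' @param seed Integer RNG seed; the bundle is deterministic given the seed.
#' @param accrual_start,accrual_end Accrual window (`Date`).
#' @param age_range Length-2 numeric, minimum (>= 66) and maximum age of the
#'   eligible population, in years.
#' @param prop_female Probability a patient is female.
#' @param egfr_category_probs Named probability vector over the five eGFR
#'   categories `c(">=60", "45-59", "30-44", "15-29", "<15")`; must sum to 1
#'   (within 1e-12).
#' @param within_category_egfr Named list of `c(lower, upper)` uniform bounds
#'   (mL/min per 1.73 m^2) for the true eGFR within each category. The `<15`
#'   category is bounded below at 2 to keep eGFR positive.
#' @param code_emission Tibble with columns `code`, `system`, `category`,
#'   `prob`: the per-5-year probability that a patient in that true-eGFR
#'   category receives the code at least once in the look-back window.
#' @param exclusion_rates Named probabilities with which a patient is made to
#'   violate each inclusion rule: `underage`, `no_lab`, `hospitalization`
#'   (hospitalized within 2 days before the prescription), `dialysis`
#'   (dialysis in the prior year), `transplant` (transplant in the prior
#'   5 years). Violations are drawn independently.
#' @param lab_timing_max_days Baseline creatinine draws uniformly within this
#'   many days before the index prescription (default 365, i.e. within the
#'   one-year eligibility window).
#' @param prop_lab_setting Named probabilities for the baseline lab care
#'   setting (`outpatient`, `inpatient`, `ed`).
#' @param prop_prior_test Probability a patient has an additional creatinine
#'   test 90-365 days before the baseline test (used by [stability_check()]).
#' @param prior_egfr_sd Standard deviation (mL/min per 1.73 m^2) of the
#'   within-patient noise added to true eGFR for the prior test.
#' @param lookback_years Code look-back window length used when dating
#'   emitted diagnosis codes.
#' @param prop_decoy_rx Probability an eligible patient has extra
#'   prescriptions after the index (exercises "selected once" logic).
#' @param icd10_child_prob Probability a 3-character ICD-10 category code is
#'   emitted as a 4-character child code (e.g. "N18" recorded as "N183"),
#'   exercising prefix matching.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_patients,
                       seed = 1L,
                       accrual_start = as.Date("2007-07-01"),
                       accrual_end = as.Date("2010-12-31"),
                       age_range = c(66, 105),
                       prop_female = 0.544,
                       egfr_category_probs = c(
                         ">=60" = 78584, "45-59" = 25904, "30-44" = 13749,
                         "15-29" = 4624, "<15" = 638
                       ) / 123499,
                       within_category_egfr = list(
                         ">=60" = c(60, 95), "45-59" = c(45, 60),
                         "30-44" = c(30, 45), "15-29" = c(15, 30),
                         "<15" = c(2, 15)
                       ),
                       code_emission = table2_emission(),
                       exclusion_rates = c(
                         underage = 0.01, no_lab = 0.02,
                         hospitalization = 0.02, dialysis = 0.01,
                         transplant = 0.005
                       ),
                       lab_timing_max_days = 365,
                       prop_lab_setting = c(outpatient = 0.75,
                                            inpatient = 0.20, ed = 0.05),
                       prop_prior_test = 0.422,
                       prior_egfr_sd = 7.4,
                       lookback_years = 5,
                       prop_decoy_rx = 0.5,
                       icd10_child_prob = 0.5) {
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 0) {
    abort("`n_patients` must be a single non-negative integer")
  }
  if (accrual_start >= accrual_end) abort("`accrual_start` must precede `accrual_end`")
  if (age_range[1] < 66) abort("`age_range` minimum must be at least 66")
  if (abs(sum(egfr_category_probs) - 1) > 1e-12) {
    abort("`egfr_category_probs` must sum to 1 (within 1e-12)")
  }
  if (!setequal(names(egfr_category_probs), EGFR_CATEGORIES)) {
    abort("`egfr_category_probs` must be named by the five eGFR categories")
  }
  assert_prob(egfr_category_probs, "egfr_category_probs")
  assert_prob(prop_female, "prop_female")
  assert_prob(exclusion_rates, "exclusion_rates")
  assert_prob(prop_prior_test, "prop_prior_test")
  assert_prob(code_emission$prob, "code_emission$prob")
  if (abs(sum(prop_lab_setting) - 1) > 1e-8) {
    abort("`prop_lab_setting` must sum to 1")
  }
  ok_bounds <- vapply(within_category_egfr,
                      function(b) length(b) == 2 && b[1] > 0 && b[1] < b[2],
                      logical(1))
  if (!all(ok_bounds)) abort("`within_category_egfr` bounds must be positive increasing pairs")
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      accrual_start = accrual_start, accrual_end = accrual_end,
      age_range = age_range, prop_female = prop_female,
      egfr_category_probs = egfr_category_probs[EGFR_CATEGORIES],
      within_category_egfr = within_category_egfr[EGFR_CATEGORIES],
      code_emission = code_emission, exclusion_rates = exclusion_rates,
      lab_timing_max_days = lab_timing_max_days,
      prop_lab_setting = prop_lab_setting,
      prop_prior_test = prop_prior_test, prior_egfr_sd = prior_egfr_sd,
      lookback_years = lookback_years, prop_decoy_rx = prop_decoy_rx,
      icd10_child_prob = icd10_child_prob
    ),
    class = "sim_params"
  )
}

#' Default code-emission probabilities
#'
#' Per-code emission probabilities for the 11 codes of the final CKD
#' algorithm, conditional on the true eGFR stratum. For patients with true
#' eGFR <45 (categories 30-44, 15-29, <15) the emission probability is each
#' code's observed sensitivity; for eGFR >=45 it is one minus the observed
#' specificity. Codes are emitted independently of one another, which
#' overstates the sensitivity of multi-code unions relative to real coding
#' behaviour (real codes co-occur); see the methods vignette.
#'
#' @return A tibble with columns `code`, `system`, `category`, `prob`.
#' @export
table2_emission <- function() {
  perf <- ckd_final_codes()
  sens <- c(0.0017, 0.0555, 0.0001, 0.0086, 0.0720, 0.0049, 0.0375,
            0.1224, 0.0451, 0.0308, 0.2239)
  fpr <- 1 - c(0.9999, 0.9942, 1.0000, 0.9992, 0.9960, 0.9998, 0.9975,
               0.9945, 0.9958, 0.9974, 0.9820)
  diseased <- c("30-44", "15-29", "<15")
  tidyr::crossing(perf[c("code", "system")],
                  category = factor(EGFR_CATEGORIES, levels = EGFR_CATEGORIES)) |>
    left_join(tibble::tibble(code = perf$code, sens = sens, fpr = fpr),
              by = "code") |>
    mutate(prob = ifelse(.data$category %in% diseased, .data$sens, .data$fpr)) |>
    select("code", "system", "category", "prob")
}

#' Uniform two-stratum emission map
#'
#' Convenience builder for an emission map with one probability for the
#' diseased stratum (true eGFR <45) and another for everyone else, applied
#' to each code in `codes`.
#'
#' @param codes Tibble with columns `code` and `system`.
#' @param p_diseased,p_healthy Emission probabilities.
#' @return A tibble with columns `code`, `system`, `category`, `prob`.
#' @export
flat_emission <- function(codes, p_diseased, p_healthy) {
  assert_prob(c(p_diseased, p_healthy), "emission probability")
  diseased <- c("30-44", "15-29", "<15")
  tidyr::crossing(codes[c("code", "system")],
                  category = factor(EGFR_CATEGORIES, levels = EGFR_CATEGORIES)) |>
    mutate(prob = ifelse(.data$category %in% diseased, p_diseased, p_healthy))
}

#' Generate a synthetic administrative-data bundle
#'
#' Simulates a complete input bundle — patients, creatinine labs, diagnosis
#' codes, prescriptions, and dialysis/transplant/hospitalization events —
#' with known ground truth, so the whole validation pipeline can run and be
#' verified without real health data.
#'
#' For each patient a true eGFR is drawn by category then uniformly within
#' the category bounds, and the recorded baseline creatinine is obtained by
#' closed-form inversion of the CKD-EPI equation at that patient's age and
#' sex ([invert_ckd_epi()]), so the reference standard recovers the truth
#' exactly. Each patient has exactly one designated eligible index
#' prescription; configurable fractions violate each inclusion rule (and
#' then carry only that single prescription, so the violation is decisive),
#' while eligible patients may carry decoy prescriptions after the index.
#' Diagnosis codes are emitted per (patient, code) with the probability the
#' emission map assigns to the patient's true eGFR category, dated uniformly
#' within the look-back window.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `ckd_bundle` with tibbles `patients`, `labs`,
#'   `codes`, `prescriptions`, `events`, and `truth` (ground truth, never
#'   read by the pipeline), plus the `params` used.
#' @examples
#' b <- simulate_cohort(sim_params(200, seed = 42))
#' nrow(b$patients)
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_patients
  if (n == 0) return(empty_bundle(params))
  set.seed(params$seed)

  patient_id <- sprintf("P%07d", seq_len(n))
  sex <- ifelse(runif(n) < params$prop_female, "F", "M")
  window_days <- as.integer(params$accrual_end - params$accrual_start)
  index_date <- params$accrual_start +
    sample.int(window_days + 1L, n, replace = TRUE) - 1L

  viol <- lapply(params$exclusion_rates,
                 function(p) runif(n) < p)

  # continuous age: shifted gamma gives median ~75 and IQR ~70-81 above the
  # floor of 66; underage violators sit just below the eligibility floor
  age_cont <- pmin(params$age_range[1] + rgamma(n, shape = 1.3, scale = 8),
                   params$age_range[2])
  age_cont[viol$underage] <- runif(sum(viol$underage), 60, 65.2)
  birth_date <- index_date - round(age_cont * 365.25)
  age_at_index <- age_completed_years(birth_date, index_date)
  # rounding birth dates to days can nudge completed age across the floor;
  # repair so eligibility status matches the violation assignment
  low <- !viol$underage & age_at_index < params$age_range[1]
  birth_date[low] <- birth_date[low] - 370L
  high <- viol$underage & age_at_index >= params$age_range[1]
  birth_date[high] <- birth_date[high] + 370L
  age_at_index <- age_completed_years(birth_date, index_date)

  category <- factor(
    EGFR_CATEGORIES[sample.int(5L, n, replace = TRUE,
                               prob = params$egfr_category_probs)],
    levels = EGFR_CATEGORIES
  )
  bounds <- do.call(rbind, params$within_category_egfr)[as.integer(category), ,
                                                       drop = FALSE]
  true_egfr <- runif(n, bounds[, 1], bounds[, 2])
  creat <- invert_ckd_epi(true_egfr, age_at_index, sex)

  patients <- tibble::tibble(patient_id, sex, birth_date)
  truth <- tibble::tibble(patient_id, true_egfr, true_category = category)

  # baseline creatinine lab: within the prior year, or pushed out of the
  # window for no-lab violators
  lag_days <- sample.int(params$lab_timing_max_days, n, replace = TRUE) - 1L
  lag_days[viol$no_lab] <- params$lab_timing_max_days +
    sample.int(100L, sum(viol$no_lab), replace = TRUE) + 35L
  setting <- sample(names(params$prop_lab_setting), n, replace = TRUE,
                    prob = params$prop_lab_setting)
  draw_date <- index_date - lag_days
  labs <- tibble::tibble(
    patient_id, draw_date,
    creatinine_umol_l = creat,
    setting,
    # simulated inpatient stays hold a single value dated at discharge, so
    # the pre-discharge selection rule returns the same value
    discharge_date = dplyr::if_else(setting == "inpatient", draw_date,
                                    as.Date(NA))
  )

  has_prior <- runif(n) < params$prop_prior_test & !viol$no_lab
  if (any(has_prior)) {
    k <- sum(has_prior)
    prior_egfr <- pmax(true_egfr[has_prior] +
                         rnorm(k, sd = params$prior_egfr_sd), 2)
    labs <- bind_rows(labs, tibble::tibble(
      patient_id = patient_id[has_prior],
      draw_date = draw_date[has_prior] -
        (89L + sample.int(365L - 89L, k, replace = TRUE)),
      creatinine_umol_l = invert_ckd_epi(prior_egfr,
                                         age_at_index[has_prior],
                                         sex[has_prior]),
      setting = "outpatient",
      discharge_date = as.Date(NA)
    ))
  }

  excluded_any <- Reduce(`|`, viol)
  rx <- tibble::tibble(patient_id, rx_date = index_date)
  decoy <- !excluded_any & runif(n) < params$prop_decoy_rx
  if (any(decoy)) {
    k <- sum(decoy)
    rx <- bind_rows(rx, tibble::tibble(
      patient_id = patient_id[decoy],
      rx_date = index_date[decoy] + sample.int(200L, k, replace = TRUE)
    ))
  }
  rx <- arrange(rx, .data$patient_id, .data$rx_date)

  events <- bind_rows(
    tibble::tibble(
      patient_id = patient_id[viol$hospitalization],
      event = "hospitalization",
      start_date = index_date[viol$hospitalization] - 2L,
      end_date = index_date[viol$hospitalization] - 1L
    ),
    tibble::tibble(
      patient_id = patient_id[viol$dialysis],
      event = "dialysis",
      start_date = index_date[viol$dialysis] -
        sample.int(364L, sum(viol$dialysis), replace = TRUE),
      end_date = as.Date(NA)
    ),
    tibble::tibble(
      patient_id = patient_id[viol$transplant],
      event = "transplant",
      start_date = index_date[viol$transplant] -
        sample.int(1825L, sum(viol$transplant), replace = TRUE),
      end_date = as.Date(NA)
    )
  )
  # benign old hospitalizations on some eligible patients exercise the
  # non-overlap branch of the washout rule
  old_hosp <- !excluded_any & runif(n) < 0.1
  if (any(old_hosp)) {
    end <- index_date[old_hosp] -
      (9L + sample.int(290L, sum(old_hosp), replace = TRUE))
    events <- bind_rows(events, tibble::tibble(
      patient_id = patient_id[old_hosp], event = "hospitalization",
      start_date = end - 7L, end_date = end
    ))
  }
  events <- arrange(events, .data$patient_id, .data$event, .data$start_date)

  codes <- emit_codes(
    mutate(truth, index_date = index_date),
    params$code_emission,
    lookback_years = params$lookback_years,
    icd10_child_prob = params$icd10_child_prob
  )

  structure(
    list(patients = patients, labs = labs, codes = codes,
         prescriptions = rx, events = events, truth = truth,
         params = params),
    class = "ckd_bundle"
  )
}

#' Emit diagnosis-code records conditional on true eGFR category
#'
#' For each patient and each code in the emission map, a code record is
#' emitted with the probability the map assigns to the patient's true eGFR
#' category, independently across patients and codes, dated uniformly within
#' the look-back window before the index date.
#'
#' @param truth Tibble with columns `patient_id`, `true_category`, and
#'   `index_date`.
#' @param emission Emission map tibble (`code`, `system`, `category`, `prob`);
#'   every category present in `truth` must be covered for every code.
#' @param lookback_years Length of the look-back window.
#' @param icd10_child_prob See [sim_params()].
#' @return A `codes` tibble (`patient_id`, `code_date`, `code`, `system`).
#' @export
emit_codes <- function(truth, emission, lookback_years = 5,
                       icd10_child_prob = 0) {
  assert_columns(truth, c("patient_id", "true_category", "index_date"), "truth")
  assert_columns(emission, c("code", "system", "category", "prob"), "emission")
  assert_prob(emission$prob, "emission$prob")

  grid <- tidyr::crossing(
    truth[c("patient_id", "true_category", "index_date")],
    distinct(emission[c("code", "system")])
  ) |>
    left_join(emission,
              by = c("code", "system", "true_category" = "category"))
  if (anyNA(grid$prob)) {
    abort("emission map does not cover every (code, category) pair in `truth`")
  }
  hit <- grid[runif(nrow(grid)) < grid$prob, , drop = FALSE]
  if (nrow(hit) == 0) {
    return(tibble::tibble(patient_id = character(), code_date = as.Date(character()),
                          code = character(), system = character()))
  }
  window_start <- years_before(hit$index_date, lookback_years)
  span <- as.integer(hit$index_date - window_start)  # code_date in [start, index)
  code <- hit$code
  expand <- hit$system == "ICD10" & nchar(code) == 3L &
    runif(nrow(hit)) < icd10_child_prob
  code[expand] <- paste0(code[expand],
                         sample(0:9, sum(expand), replace = TRUE))
  tibble::tibble(
    patient_id = hit$patient_id,
    code_date = window_start + floor(runif(nrow(hit)) * span),
    code = code,
    system = hit$system
  ) |>
    arrange(.data$patient_id, .data$code_date, .data$code)
}

empty_bundle <- function(params = NULL) {
  structure(
    list(
      patients = tibble::tibble(patient_id = character(), sex = character(),
                                birth_date = as.Date(character())),
      labs = tibble::tibble(patient_id = character(),
                            draw_date = as.Date(character()),
                            creatinine_umol_l = double(), setting = character(),
                            discharge_date = as.Date(character())),
      codes = tibble::tibble(patient_id = character(),
                             code_date = as.Date(character()),
                             code = character(), system = character()),
      prescriptions = tibble::tibble(patient_id = character(),
                                     rx_date = as.Date(character())),
      events = tibble::tibble(patient_id = character(), event = character(),
                              start_date = as.Date(character()),
                              end_date = as.Date(character())),
      truth = tibble::tibble(patient_id = character(), true_egfr = double(),
                             true_category = factor(character(),
                                                    levels = EGFR_CATEGORIES)),
      params = params
    ),
    class = "ckd_bundle"
  )
}

#' @export
print.ckd_bundle <- function(x, ...) {
  cat("<ckd_bundle>\n")
  for (nm in c("patients", "labs", "codes", "prescriptions", "events", "truth")) {
    cat(sprintf("  %-13s %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
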