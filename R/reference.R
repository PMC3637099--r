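#' Select the baseline serum creatinine for each cohort patient
#'
#' Picks the most recent creatinine in `(index - lookback_days, index]` from
#' any care setting. If that value was drawn mid-way through an inpatient
#' stay, the last value of the same stay dated on or before its discharge
#' date is used instead — discharge values avoid transient elevations from
#' acute kidney injury that resolve before discharge. With
#' `outpatient_only = TRUE`, inpatient and emergency-department labs are
#' ignored entirely (the outpatient-restriction analysis); patients whose
#' window then holds no qualifying lab are dropped with a warning.
#'
#' @param labs Labs tibble (`patient_id`, `draw_date`, `creatinine_umol_l`,
#'   `setting`, `discharge_date`).
#' @param cohort A `ckd_cohort`; only included patients are processed.
#' @param lookback_days Lab eligibility window, days before index.
#' @param outpatient_only Restrict to outpatient laboratory values?
#' @param tie_break How to resolve several values on the selected day:
#'   `"lowest"` (default; avoids transient elevations) or `"highest"`.
#' @return Tibble: `patient_id`, `draw_date`, `creatinine_umol_l`,
#'   `setting`, one row per patient with a qualifying lab.
#' @export
select_baseline_creatinine <- function(labs, cohort, lookback_days = 365,
                                       outpatient_only = FALSE,
                                       tie_break = c("lowest", "highest")) {
  tie_break <- match.arg(tie_break)
  assert_columns(labs, c("patient_id", "draw_date", "creatinine_umol_l",
                         "setting", "discharge_date"), "labs")
  idx <- cohort |> filter(.data$included) |>
    select("patient_id", "index_date")
  pool <- labs
  if (outpatient_only) pool <- filter(pool, .data$setting == "outpatient")
  cand <- idx |>
    inner_join(pool, by = "patient_id",
               relationship = "one-to-many") |>
    filter(.data$draw_date <= .data$index_date,
           .data$draw_date > .data$index_date - lookback_days)

  pick_latest <- function(df) {
    df <- arrange(df, .data$patient_id, dplyr::desc(.data$draw_date),
                  if (tie_break == "lowest") .data$creatinine_umol_l
                  else dplyr::desc(.data$creatinine_umol_l))
    df[!duplicated(df$patient_id), , drop = FALSE]
  }
  chosen <- pick_latest(cand)

  # pre-discharge substitution for values drawn mid-stay
  inpat <- chosen |> filter(.data$setting == "inpatient",
                            !is.na(.data$discharge_date))
  if (nrow(inpat) > 0) {
    stay_last <- inpat |>
      select("patient_id", "discharge_date") |>
      inner_join(filter(labs, .data$setting == "inpatient"),
                 by = c("patient_id", "discharge_date"),
                 relationship = "one-to-many") |>
      filter(.data$draw_date <= .data$discharge_date) |>
      pick_latest()
    chosen <- chosen |>
      dplyr::rows_update(
        stay_last[c("patient_id", "draw_date", "creatinine_umol_l", "setting")],
        by = "patient_id")
  }

  missing <- setdiff(idx$patient_id, chosen$patient_id)
  if (length(missing) > 0) {
    warn(sprintf(
      "%d included patient(s) have no qualifying baseline creatinine%s; dropped",
      length(missing),
      if (outpatient_only) " under the outpatient-only restriction" else ""))
  }
  chosen |>
    select("patient_id", "draw_date", "creatinine_umol_l", "setting") |>
    arrange(.data$patient_id)
}

#' Compute the eGFR reference standard for a cohort
#'
#' Selects each included patient's baseline creatinine
#' ([select_baseline_creatinine()]), estimates GFR with the CKD-EPI
#' equation at the patient's age (completed years at index) and sex, and
#' assigns the five eGFR categories and the nested disease labels
#' eGFR <60, <45, <30 ([classify_egfr()]). eGFR is carried at full
#' precision; round only for display.
#'
#' @inheritParams select_baseline_creatinine
#' @param cohort A `ckd_cohort` from [accrue()].
#' @param race_coefficient Passed to [ckd_epi_egfr()].
#' @return A tibble of class `ckd_reference`: `patient_id`, `draw_date`,
#'   `baseline_creatinine_umol_l`, `egfr`, `category`, `lt60`, `lt45`,
#'   `lt30`.
#' @examples
#' b <- simulate_cohort(sim_params(300, seed = 7))
#' ch <- accrue(b$patients, b$prescriptions, b$labs, b$events)
#' ref <- reference_standard(ch, b$labs)
#' table(ref$category)
#' @export
reference_standard <- function(cohort, labs, lookback_days = 365,
                               outpatient_only = FALSE,
                               tie_break = c("lowest", "highest"),
                               race_coefficient = FALSE) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  base <- select_baseline_creatinine(labs, cohort, lookback_days,
                                     outpatient_only, tie_break)
  out <- base |>
    inner_join(cohort[c("patient_id", "age_at_index", "sex")],
               by = "patient_id") |>
    mutate(egfr = ckd_epi_egfr(.data$creatinine_umol_l, .data$age_at_index,
                               .data$sex, race_coefficient))
  cls <- classify_egfr(out$egfr)
  out <- out |>
    transmute(
      .data$patient_id, .data$draw_date,
      baseline_creatinine_umol_l = .data$creatinine_umol_l,
      .data$egfr,
      category = cls$category,
      lt60 = cls$lt60, lt45 = cls$lt45, lt30 = cls$lt30
    )
  class(out) <- c("ckd_reference", class(out))
  out
}

#' eGFR stability between the study test and a prior test
#'
#' For each patient with at least one additional creatinine test 90 to 365
#' days before the study (baseline) test, takes the closest such prior
#' test, estimates eGFR for both at the patient's index age, and summarises
#' the absolute difference.
#'
#' @param reference A `ckd_reference` from [reference_standard()].
#' @param labs The labs tibble.
#' @param cohort The `ckd_cohort` (for age and sex).
#' @param race_coefficient Passed to [ckd_epi_egfr()].
#' @return One-row tibble: `n_with_prior_test`, `median_abs_diff`,
#'   `q25_abs_diff`, `q75_abs_diff` (mL/min per 1.73 m^2; `NA` when no
#'   patient has a prior test).
#' @export
stability_check <- function(reference, labs, cohort,
                            race_coefficient = FALSE) {
  stopifnot(inherits(reference, "ckd_reference"))
  prior <- reference |>
    select("patient_id", study_date = "draw_date", study_egfr = "egfr") |>
    inner_join(labs[c("patient_id", "draw_date", "creatinine_umol_l")],
               by = "patient_id", relationship = "one-to-many") |>
    filter(.data$study_date - .data$draw_date >= 90,
           .data$study_date - .data$draw_date <= 365) |>
    arrange(.data$patient_id, dplyr::desc(.data$draw_date)) |>
    filter(!duplicated(.data$patient_id)) |>
    inner_join(cohort[c("patient_id", "age_at_index", "sex")],
               by = "patient_id") |>
    mutate(
      prior_egfr = ckd_epi_egfr(.data$creatinine_umol_l, .data$age_at_index,
                                .data$sex, race_coefficient),
      abs_diff = abs(.data$study_egfr - .data$prior_egfr)
    )
  if (nrow(prior) == 0) {
    return(tibble::tibble(n_with_prior_test = 0L, median_abs_diff = NA_real_,
                          q25_abs_diff = NA_real_, q75_abs_diff = NA_real_))
  }
  tibble::tibble(
    n_with_prior_test = nrow(prior),
    median_abs_diff = median(prior$abs_diff),
    q25_abs_diff = unname(quantile(prior$abs_diff, 0.25)),
    q75_abs_diff = unname(quantile(prior$abs_diff, 0.75))
  )
}
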