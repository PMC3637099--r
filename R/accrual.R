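#' Accrual configuration
#'
#' Windows and thresholds for cohort accrual at an index outpatient
#' prescription. Defaults mirror the validation-study design: accrual from
#' 2007-07-01 to 2010-12-31, minimum age 66 (guaranteeing one year of
#' baseline prescription history under a 65+ drug plan), a serum creatinine
#' within the prior 365 days, no hospitalization within the 2 days before
#' the prescription, no dialysis in the prior year, and no kidney
#' transplant in the prior 5 years.
#'
#' @param accrual_start,accrual_end Accrual window (`Date` or ISO-8601
#'   strings).
#' @param min_age_years Minimum age, completed years, at the index date.
#' @param lab_lookback_days Baseline creatinine must fall in
#'   `(index - lab_lookback_days, index]`.
#' @param hospitalization_washout_days A hospitalization interval touching
#'   `[index - washout, index]` disqualifies the prescription.
#' @param dialysis_lookback_days Dialysis events in
#'   `(index - lookback, index)` disqualify the patient.
#' @param transplant_lookback_years Transplant events in
#'   `(index - lookback, index)` disqualify the patient.
#' @param hospitalization_rule `"exclude_accrual"` (default) treats a recent
#'   hospitalization as disqualifying the accrual event itself;
#'   `"exclude_lab"` instead discards the baseline laboratory tests of
#'   recently hospitalized patients, so such patients fail the lab
#'   criterion (the alternative reading of the washout rule).
#' @return A list of class `accrual_config`.
#' @export
accrual_config <- function(accrual_start = as.Date("2007-07-01"),
                           accrual_end = as.Date("2010-12-31"),
                           min_age_years = 66,
                           lab_lookback_days = 365,
                           hospitalization_washout_days = 2,
                           dialysis_lookback_days = 365,
                           transplant_lookback_years = 5,
                           hospitalization_rule = c("exclude_accrual",
                                                    "exclude_lab")) {
  accrual_start <- parse_date_strict(accrual_start, "accrual_start")
  accrual_end <- parse_date_strict(accrual_end, "accrual_end")
  if (accrual_start >= accrual_end) abort("`accrual_start` must precede `accrual_end`")
  stopifnot(lab_lookback_days > 0, hospitalization_washout_days >= 0,
            dialysis_lookback_days > 0, transplant_lookback_years > 0)
  structure(
    list(accrual_start = accrual_start, accrual_end = accrual_end,
         min_age_years = min_age_years,
         lab_lookback_days = lab_lookback_days,
         hospitalization_washout_days = hospitalization_washout_days,
         dialysis_lookback_days = dialysis_lookback_days,
         transplant_lookback_years = transplant_lookback_years,
         hospitalization_rule = match.arg(hospitalization_rule)),
    class = "accrual_config"
  )
}

#' Accrue a cohort at index outpatient prescriptions
#'
#' Scans each patient's prescriptions in date order within the accrual
#' window; the first prescription satisfying all criteria becomes that
#' patient's index date (each patient enters at most once). Criteria, in
#' the fixed order used for attributing exclusions: age at the prescription
#' at least `min_age_years`; at least one creatinine in the prior-year
#' window; no hospitalization overlapping the washout interval; no dialysis
#' in the prior year; no transplant in the prior 5 years. Patients with no
#' qualifying prescription are reported once, with the first-failing rule
#' of their last candidate prescription as the exclusion reason.
#'
#' @param patients Tibble: `patient_id`, `sex`, `birth_date`.
#' @param prescriptions Tibble: `patient_id`, `rx_date`. Prescriptions
#'   outside the accrual window are skipped silently.
#' @param labs Tibble: `patient_id`, `draw_date`, `creatinine_umol_l`,
#'   `setting`, `discharge_date`.
#' @param events Tibble: `patient_id`, `event` (one of `dialysis`,
#'   `transplant`, `hospitalization`), `start_date`, `end_date`.
#' @param config An [accrual_config()].
#' @return A tibble of class `ckd_cohort`, one row per patient with at
#'   least one in-window prescription: `patient_id`, `index_date` (`NA` if
#'   excluded), `age_at_index`, `sex`, `included`, `exclusion_reason`
#'   (`NA` if included). Summarise exclusions with [exclusion_tally()].
#' @examples
#' b <- simulate_cohort(sim_params(300, seed = 7))
#' ch <- accrue(b$patients, b$prescriptions, b$labs, b$events)
#' exclusion_tally(ch)
#' @export
accrue <- function(patients, prescriptions, labs, events,
                   config = accrual_config()) {
  stopifnot(inherits(config, "accrual_config"))
  assert_columns(patients, c("patient_id", "sex", "birth_date"), "patients")
  assert_columns(prescriptions, c("patient_id", "rx_date"), "prescriptions")
  assert_columns(labs, c("patient_id", "draw_date"), "labs")
  assert_columns(events, c("patient_id", "event", "start_date", "end_date"),
                 "events")
  patients <- mutate(patients, birth_date = parse_date_strict(.data$birth_date, "patients$birth_date"))
  prescriptions <- mutate(prescriptions, rx_date = parse_date_strict(.data$rx_date, "prescriptions$rx_date"))
  labs <- mutate(labs, draw_date = parse_date_strict(.data$draw_date, "labs$draw_date"))
  events <- mutate(events,
                   start_date = parse_date_strict(.data$start_date, "events$start_date"),
                   end_date = parse_date_strict(.data$end_date, "events$end_date"))

  cand <- prescriptions |>
    mutate(.offset = dplyr::row_number()) |>
    filter(.data$rx_date >= config$accrual_start,
           .data$rx_date <= config$accrual_end) |>
    inner_join(patients[c("patient_id", "sex", "birth_date")],
               by = "patient_id") |>
    arrange(.data$patient_id, .data$rx_date, .data$.offset) |>
    mutate(
      .cand = dplyr::row_number(),
      age_at_index = age_completed_years(.data$birth_date, .data$rx_date),
      lab_min = .data$rx_date - config$lab_lookback_days,
      wash_min = .data$rx_date - config$hospitalization_washout_days,
      dial_min = .data$rx_date - config$dialysis_lookback_days,
      tx_min = years_before(.data$rx_date, config$transplant_lookback_years)
    )
  if (nrow(cand) == 0) {
    return(new_cohort(tibble::tibble(
      patient_id = character(), index_date = as.Date(character()),
      age_at_index = integer(), sex = character(), included = logical(),
      exclusion_reason = factor(character(), levels = EXCLUSION_REASONS)
    ), config))
  }

  hit_ids <- function(joined) unique(joined$.cand)
  lab_ok_ids <- cand |>
    inner_join(labs[c("patient_id", "draw_date")],
               by = dplyr::join_by(patient_id,
                                   x$lab_min < y$draw_date,
                                   x$rx_date >= y$draw_date)) |>
    hit_ids()
  ev <- function(type) filter(events, .data$event == type)
  hosp <- ev("hospitalization") |>
    mutate(end_eff = dplyr::coalesce(.data$end_date, .data$start_date))
  hosp_hit_ids <- cand |>
    inner_join(hosp[c("patient_id", "start_date", "end_eff")],
               by = dplyr::join_by(patient_id,
                                   x$rx_date >= y$start_date,
                                   x$wash_min <= y$end_eff)) |>
    hit_ids()
  dial_hit_ids <- cand |>
    inner_join(ev("dialysis")[c("patient_id", "start_date")],
               by = dplyr::join_by(patient_id,
                                   x$dial_min < y$start_date,
                                   x$rx_date > y$start_date)) |>
    hit_ids()
  tx_hit_ids <- cand |>
    inner_join(ev("transplant")[c("patient_id", "start_date")],
               by = dplyr::join_by(patient_id,
                                   x$tx_min < y$start_date,
                                   x$rx_date > y$start_date)) |>
    hit_ids()

  cand <- cand |>
    mutate(
      ok_age = .data$age_at_index >= config$min_age_years,
      ok_lab = .data$.cand %in% lab_ok_ids,
      hosp_hit = .data$.cand %in% hosp_hit_ids,
      ok_dial = !.data$.cand %in% dial_hit_ids,
      ok_tx = !.data$.cand %in% tx_hit_ids
    )
  if (config$hospitalization_rule == "exclude_lab") {
    cand <- mutate(cand,
                   ok_lab = .data$ok_lab & !.data$hosp_hit,
                   ok_hosp = TRUE)
  } else {
    cand <- mutate(cand, ok_hosp = !.data$hosp_hit)
  }
  cand <- cand |>
    mutate(
      pass = .data$ok_age & .data$ok_lab & .data$ok_hosp &
        .data$ok_dial & .data$ok_tx,
      first_fail = dplyr::case_when(
        !ok_age ~ "age",
        !ok_lab ~ "no_baseline_lab",
        !ok_hosp ~ "hospitalization",
        !ok_dial ~ "dialysis",
        !ok_tx ~ "transplant",
        .default = NA_character_
      )
    )

  cohort <- cand |>
    group_by(.data$patient_id) |>
    summarise(
      included = any(.data$pass),
      # first qualifying prescription, else the last candidate's failure
      .pick = if (any(pass)) min(.cand[pass]) else max(.cand),
      .groups = "drop"
    ) |>
    left_join(cand[c(".cand", "rx_date", "age_at_index", "sex", "first_fail")],
              by = c(".pick" = ".cand")) |>
    transmute(
      .data$patient_id,
      index_date = dplyr::if_else(.data$included, .data$rx_date, as.Date(NA)),
      age_at_index = .data$age_at_index,
      sex = .data$sex,
      included = .data$included,
      exclusion_reason = factor(
        ifelse(.data$included, NA_character_, .data$first_fail),
        levels = EXCLUSION_REASONS
      )
    ) |>
    arrange(.data$patient_id)
  new_cohort(cohort, config)
}

new_cohort <- function(df, config) {
  structure(df, config = config,
            class = c("ckd_cohort", class(tibble::tibble())))
}

#' Tally exclusions by first-failing rule
#'
#' @param cohort A `ckd_cohort` from [accrue()].
#' @return A tibble with one row per exclusion reason (fixed order: age,
#'   no_baseline_lab, hospitalization, dialysis, transplant) and the number
#'   of patients excluded for it, plus the included count as attribute-free
#'   rows are easy to sum: `included + excluded = patients with >=1
#'   in-window prescription`.
#' @export
exclusion_tally <- function(cohort) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  tibble::tibble(reason = factor(EXCLUSION_REASONS, levels = EXCLUSION_REASONS)) |>
    left_join(
      cohort |> filter(!.data$included) |> count(.data$exclusion_reason),
      by = c(reason = "exclusion_reason")
    ) |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
}
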