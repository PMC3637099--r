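# small builders for hand-traced accrual/reference scenarios

d <- function(x) as.Date(x)

empty_labs <- function() {
  tibble::tibble(patient_id = character(), draw_date = as.Date(character()),
                 creatinine_umol_l = double(), setting = character(),
                 discharge_date = as.Date(character()))
}

empty_events <- function() {
  tibble::tibble(patient_id = character(), event = character(),
                 start_date = as.Date(character()),
                 end_date = as.Date(character()))
}

lab_row <- function(id, draw, creat = 80, setting = "outpatient",
                    discharge = NA) {
  tibble::tibble(patient_id = id, draw_date = d(draw),
                 creatinine_umol_l = creat, setting = setting,
                 discharge_date = d(if (is.na(discharge)) NA else discharge))
}

event_row <- function(id, event, start, end = NA) {
  tibble::tibble(patient_id = id, event = event, start_date = d(start),
                 end_date = d(if (is.na(end)) NA else end))
}

patient_row <- function(id, sex = "F", birth = "1935-01-01") {
  tibble::tibble(patient_id = id, sex = sex, birth_date = d(birth))
}

rx_row <- function(id, date) {
  tibble::tibble(patient_id = id, rx_date = d(date))
}

code_row <- function(id, date, code, system = "ICD10") {
  tibble::tibble(patient_id = id, code_date = d(date), code = code,
                 system = system)
}

# a minimal included cohort without running accrue(), for unit tests of
# downstream stages; ages/sex given per patient
toy_cohort <- function(ids, index_dates, ages = 75, sexes = "F") {
  patients <- tibble::tibble(
    patient_id = ids, sex = rep_len(sexes, length(ids)),
    birth_date = d(index_dates) - round((rep_len(ages, length(ids)) + 0.5) * 365.25)
  )
  prescriptions <- tibble::tibble(patient_id = ids, rx_date = d(index_dates))
  labs <- tibble::tibble(patient_id = ids, draw_date = d(index_dates) - 30,
                         creatinine_umol_l = 80, setting = "outpatient",
                         discharge_date = d(NA))
  accrue(patients, prescriptions, labs, empty_events(),
         accrual_config(accrual_start = min(d(index_dates)) - 1,
                        accrual_end = max(d(index_dates)) + 1))
}

# independent per-patient scan: the brute-force oracle for flag_patients
oracle_flag <- function(cohort, codes_table, spec) {
  inc <- cohort[cohort$included, ]
  pos <- vapply(seq_len(nrow(inc)), function(i) {
    id <- inc$patient_id[i]
    index <- inc$index_date[i]
    lo <- index %m-% lubridate::years(spec$lookback_years)
    recs <- codes_table[codes_table$patient_id == id, ]
    occ <- character()
    for (j in seq_len(nrow(recs))) {
      in_window <- recs$code_date[j] >= lo &&
        (if (spec$include_index) recs$code_date[j] <= index
         else recs$code_date[j] < index)
      if (!in_window) next
      for (k in seq_len(nrow(spec$codes))) {
        sys_ok <- recs$system[j] == spec$codes$system[k]
        code_ok <- if (spec$codes$system[k] == "ICD10" &&
                       spec$icd10_match == "prefix") {
          startsWith(recs$code[j], spec$codes$code[k])
        } else {
          recs$code[j] == spec$codes$code[k]
        }
        if (sys_ok && code_ok) {
          occ <- c(occ, paste(spec$codes$code[k], recs$code_date[j],
                              if (spec$count == "records") j))
          break
        }
      }
    }
    length(unique(occ)) >= spec$min_occurrences
  }, logical(1))
  tibble::tibble(patient_id = inc$patient_id, algorithm = spec$name,
                 positive = pos) |>
    dplyr::arrange(patient_id)
}

`%m-%` <- lubridate::`%m-%`
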