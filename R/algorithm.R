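#' Define a code-list algorithm
#'
#' A case-finding algorithm: a patient is algorithm positive when at least
#' `min_occurrences` qualifying code records fall in the look-back window
#' `[index - lookback_years, index)` (the index date itself is excluded —
#' codes must precede the prescription). Codes are combined with Boolean
#' OR; for `min_occurrences > 1`, occurrences are pooled across codes and,
#' by default, counted on distinct (code, day) pairs, so the same code
#' recorded twice on one day counts once but two different codes on
#' different days count as two.
#'
#' @param name Algorithm name.
#' @param codes Tibble with columns `code` and `system` (`"ICD10"` or
#'   `"OHIP"`); pairs must be unique.
#' @param lookback_years Look-back window length, years.
#' @param min_occurrences Minimum qualifying occurrences (>= 1).
#' @param icd10_match `"prefix"` (default; a 3-character entry such as
#'   `"I12"` matches recorded children like `"I120"`) or `"exact"`.
#' @param count `"distinct_days"` (default) counts distinct (code, date)
#'   pairs; `"records"` counts raw records.
#' @param include_index Close the window at the index date (include codes
#'   dated on the index)? Default `FALSE`.
#' @return A list of class `algorithm_spec`.
#' @examples
#' algorithm_spec("n18_only",
#'                tibble::tibble(code = "N18", system = "ICD10"))
#' @export
algorithm_spec <- function(name, codes, lookback_years = 5,
                           min_occurrences = 1L,
                           icd10_match = c("prefix", "exact"),
                           count = c("distinct_days", "records"),
                           include_index = FALSE) {
  assert_columns(codes, c("code", "system"), "codes")
  if (nrow(codes) == 0) abort("`codes` must be non-empty")
  if (anyDuplicated(codes[c("code", "system")])) {
    abort("(code, system) pairs must be unique")
  }
  if (!all(codes$system %in% c("ICD10", "OHIP"))) {
    abort('unknown coding system: `system` must be "ICD10" or "OHIP"')
  }
  if (lookback_years <= 0) abort("`lookback_years` must be positive")
  if (min_occurrences < 1) abort("`min_occurrences` must be >= 1")
  structure(
    list(name = name,
         codes = tibble::as_tibble(codes[c("code", "system")]),
         lookback_years = lookback_years,
         min_occurrences = as.integer(min_occurrences),
         icd10_match = match.arg(icd10_match),
         count = match.arg(count),
         include_index = include_index),
    class = "algorithm_spec"
  )
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat(sprintf("<algorithm_spec> %s: %d code(s), %g-year look-back, >=%d occurrence(s)\n",
              x$name, nrow(x$codes), x$lookback_years, x$min_occurrences))
  invisible(x)
}

#' The 11-code CKD algorithm catalog
#'
#' The final chronic-kidney-disease case-finding code list: nine ICD-10
#' hospital-encounter codes (diabetic nephropathy E102/E112/E132/E142,
#' hypertensive renal disease I12/I13, glomerular disorders N08, chronic
#' and unspecified renal failure N18/N19) and two physician-claim codes
#' (403 hypertensive renal disease, 585 chronic renal failure/uremia).
#'
#' @return Tibble: `code`, `system`, `description`.
#' @export
ckd_final_codes <- function() {
  tibble::tribble(
    ~code, ~system, ~description,
    "E102", "ICD10", "Type 1 diabetes mellitus with incipient diabetic nephropathy",
    "E112", "ICD10", "Type 2 diabetes mellitus with incipient diabetic nephropathy",
    "E132", "ICD10", "Other specified diabetes mellitus with incipient diabetic nephropathy",
    "E142", "ICD10", "Unspecified diabetes mellitus with incipient diabetic nephropathy",
    "I12",  "ICD10", "Hypertensive renal disease",
    "I13",  "ICD10", "Hypertensive renal and heart disease",
    "N08",  "ICD10", "Glomerular disorders in diseases classified elsewhere",
    "N18",  "ICD10", "Chronic renal failure",
    "N19",  "ICD10", "Unspecified renal failure",
    "403",  "OHIP",  "Hypertensive renal disease",
    "585",  "OHIP",  "Chronic renal failure, uremia"
  )
}

#' Read an algorithm definition from a YAML file
#'
#' Expected keys: `name`, `lookback_years`, `min_occurrences`, and `codes`
#' (a list of `{code, system}` maps). The shipped final CKD algorithm is at
#' `system.file("extdata", "ckd_final.yaml", package = "ckdcodes")`.
#'
#' @param path Path to a YAML algorithm definition.
#' @param ... Overrides passed to [algorithm_spec()].
#' @return An `algorithm_spec`.
#' @export
read_algorithm <- function(path, ...) {
  if (!file.exists(path)) abort(sprintf("algorithm file not found: %s", path))
  y <- yaml::read_yaml(path)
  for (k in c("name", "codes")) {
    if (is.null(y[[k]])) abort(sprintf("algorithm file missing key `%s`", k))
  }
  codes <- purrr::map_dfr(y$codes, ~ tibble::tibble(code = as.character(.x$code),
                                                    system = .x$system))
  args <- list(name = y$name, codes = codes)
  if (!is.null(y$lookback_years)) args$lookback_years <- y$lookback_years
  if (!is.null(y$min_occurrences)) args$min_occurrences <- y$min_occurrences
  args <- utils::modifyList(args, list(...))
  do.call(algorithm_spec, args)
}

match_codes <- function(codes_table, spec) {
  hits <- rep(FALSE, nrow(codes_table))
  # matched code strings are normalised to the catalog entry so pooled
  # distinct-day counting treats "N183" and "N184" as the same code
  matched_as <- rep(NA_character_, nrow(codes_table))
  for (i in seq_len(nrow(spec$codes))) {
    code <- spec$codes$code[i]
    sys <- spec$codes$system[i]
    m <- codes_table$system == sys &
      if (sys == "ICD10" && spec$icd10_match == "prefix") {
        startsWith(codes_table$code, code)
      } else {
        codes_table$code == code
      }
    matched_as[m & !hits] <- code
    hits <- hits | m
  }
  codes_table$matched_code <- matched_as
  codes_table[hits, , drop = FALSE]
}

#' Flag algorithm-positive patients
#'
#' Applies an [algorithm_spec()] to the cohort: a patient is positive when
#' the number of qualifying code occurrences in the look-back window
#' reaches `min_occurrences`.
#'
#' @param cohort A `ckd_cohort`; only included patients are flagged.
#' @param codes_table Codes tibble (`patient_id`, `code_date`, `code`,
#'   `system`).
#' @param spec An `algorithm_spec`.
#' @return Tibble: `patient_id`, `algorithm`, `positive`.
#' @examples
#' b <- simulate_cohort(sim_params(300, seed = 7))
#' ch <- accrue(b$patients, b$prescriptions, b$labs, b$events)
#' spec <- algorithm_spec("ckd_final", ckd_final_codes())
#' mean(flag_patients(ch, b$codes, spec)$positive)
#' @export
flag_patients <- function(cohort, codes_table, spec) {
  stopifnot(inherits(cohort, "ckd_cohort"), inherits(spec, "algorithm_spec"))
  assert_columns(codes_table, c("patient_id", "code_date", "code", "system"),
                 "codes_table")
  bad <- setdiff(unique(codes_table$system), c("ICD10", "OHIP"))
  if (length(bad) > 0) {
    abort(sprintf("unknown coding system in codes table: %s",
                  paste(bad, collapse = ", ")))
  }
  inc0 <- filter(cohort, .data$included)
  inc <- tibble::tibble(patient_id = inc0$patient_id,
                        index_date = inc0$index_date)
  matched <- match_codes(codes_table, spec) |>
    inner_join(inc, by = "patient_id") |>
    mutate(window_start = years_before(.data$index_date, spec$lookback_years)) |>
    filter(.data$code_date >= .data$window_start,
           if (spec$include_index) .data$code_date <= .data$index_date
           else .data$code_date < .data$index_date)
  counts <- if (spec$count == "distinct_days") {
    matched |> distinct(.data$patient_id, .data$matched_code, .data$code_date) |>
      count(.data$patient_id)
  } else {
    matched |> count(.data$patient_id)
  }
  inc |>
    left_join(counts, by = "patient_id") |>
    transmute(.data$patient_id, algorithm = spec$name,
              positive = dplyr::coalesce(.data$n, 0L) >= spec$min_occurrences) |>
    arrange(.data$patient_id)
}

#' Evaluate each catalog code as a one-code algorithm
#'
#' Builds a single-code algorithm for every code in `catalog`, flags the
#' cohort, and computes sensitivity, specificity, PPV, and NPV against the
#' reference label — the per-code performance table from which the final
#' algorithm is assembled.
#'
#' @param cohort A `ckd_cohort`.
#' @param codes_table Codes tibble.
#' @param catalog Tibble of candidate codes (`code`, `system`, optionally
#'   `description`).
#' @param reference A `ckd_reference`.
#' @param label Which reference label defines disease; default `"lt45"`.
#' @param ... Passed to [algorithm_spec()] (look-back, matching, counting).
#' @return Tibble with one row per code: `code`, `system`, `sensitivity`,
#'   `specificity`, `ppv`, `npv` (NA when a denominator is zero, e.g. PPV
#'   of a never-observed code).
#' @export
evaluate_single_codes <- function(cohort, codes_table, catalog, reference,
                                  label = "lt45", ...) {
  assert_columns(catalog, c("code", "system"), "catalog")
  purrr::pmap_dfr(catalog[c("code", "system")], function(code, system) {
    spec <- algorithm_spec(code, tibble::tibble(code = code, system = system),
                           ...)
    fl <- flag_patients(cohort, codes_table, spec)
    m <- metrics(contingency(fl, reference, label), warn_null = FALSE)
    tibble::tibble(code = code, system = system,
                   sensitivity = m$estimates$sensitivity,
                   specificity = m$estimates$specificity,
                   ppv = m$estimates$ppv, npv = m$estimates$npv)
  })
}

#' Assemble a final algorithm from per-code performance
#'
#' Selects the union of codes whose single-code sensitivity reaches
#' `min_sensitivity` and an explicit `manual_includes` list standing in for
#' codes retained on conceptual grounds (e.g. rarer diabetic-nephropathy
#' codes riding along with their common sibling). Conceptual similarity is
#' deliberately not automated.
#'
#' @param per_code_metrics Output of [evaluate_single_codes()].
#' @param min_sensitivity Sensitivity threshold for automatic inclusion
#'   (default 0.03).
#' @param manual_includes Character vector of codes to include regardless.
#' @param name Name for the resulting algorithm.
#' @param ... Passed to [algorithm_spec()].
#' @return An `algorithm_spec` over the selected codes.
#' @export
build_algorithm <- function(per_code_metrics, min_sensitivity = 0.03,
                            manual_includes = character(),
                            name = "combined", ...) {
  assert_columns(per_code_metrics, c("code", "system", "sensitivity"),
                 "per_code_metrics")
  keep <- per_code_metrics |>
    filter((!is.na(.data$sensitivity) &
              .data$sensitivity >= min_sensitivity) |
             .data$code %in% manual_includes)
  if (nrow(keep) == 0) {
    abort("no codes selected: no sensitivity reaches `min_sensitivity` and `manual_includes` is empty")
  }
  algorithm_spec(name, keep[c("code", "system")], ...)
}
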