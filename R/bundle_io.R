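#' Write a synthetic bundle to CSV files
#'
#' Writes the six tables of a [simulate_cohort()] bundle as headered CSV
#' with ISO-8601 dates: `patients.csv`, `labs.csv`, `codes.csv`,
#' `prescriptions.csv`, `events.csv`, and `truth.csv` (ground truth; written
#' alongside but never read by the pipeline). [read_bundle()] round-trips
#' the tables exactly.
#'
#' @param bundle A `ckd_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ckd_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in BUNDLE_TABLES) {
    df <- bundle[[nm]] |>
      # %.17g guarantees doubles survive the text round trip bit-exactly
      mutate(across(dplyr::where(is.double) & !dplyr::where(lubridate::is.Date),
                    ~ ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))))
    readr::write_csv(df, file.path(dir, paste0(nm, ".csv")), na = "")
  }
  invisible(dir)
}

#' Read a bundle of administrative tables from CSV files
#'
#' Reads `patients.csv`, `labs.csv`, `codes.csv`, `prescriptions.csv`, and
#' `events.csv` from `dir` with strict column types, plus `truth.csv` when
#' present (and `truth = TRUE`). Schema violations are errors.
#'
#' @param dir Directory containing the CSV tables.
#' @param truth Read `truth.csv` if it exists? Default `TRUE`.
#' @return A `ckd_bundle` list of tibbles.
#' @export
read_bundle <- function(dir, truth = TRUE) {
  if (!dir.exists(dir)) abort(sprintf("directory not found: %s", dir))
  out <- empty_bundle()
  for (nm in setdiff(BUNDLE_TABLES, "truth")) {
    out[[nm]] <- read_table_csv(file.path(dir, paste0(nm, ".csv")), nm)
  }
  truth_path <- file.path(dir, "truth.csv")
  if (truth && file.exists(truth_path)) {
    out$truth <- read_table_csv(truth_path, "truth")
  }
  out
}

BUNDLE_TABLES <- c("patients", "labs", "codes", "prescriptions", "events",
                   "truth")

BUNDLE_SCHEMAS <- list(
  patients = readr::cols(patient_id = readr::col_character(),
                         sex = readr::col_character(),
                         birth_date = readr::col_date()),
  # doubles are read as text and converted with strtod(): vroom's fast
  # double parser can be off by an ulp, breaking the bit-exact round trip
  labs = readr::cols(patient_id = readr::col_character(),
                     draw_date = readr::col_date(),
                     creatinine_umol_l = readr::col_character(),
                     setting = readr::col_character(),
                     discharge_date = readr::col_date()),
  codes = readr::cols(patient_id = readr::col_character(),
                      code_date = readr::col_date(),
                      code = readr::col_character(),
                      system = readr::col_character()),
  prescriptions = readr::cols(patient_id = readr::col_character(),
                              rx_date = readr::col_date()),
  events = readr::cols(patient_id = readr::col_character(),
                       event = readr::col_character(),
                       start_date = readr::col_date(),
                       end_date = readr::col_date()),
  truth = readr::cols(patient_id = readr::col_character(),
                      true_egfr = readr::col_character(),
                      true_category = readr::col_character())
)

DOUBLE_COLUMNS <- list(labs = "creatinine_umol_l", truth = "true_egfr")

read_table_csv <- function(path, nm) {
  if (!file.exists(path)) abort(sprintf("expected file not found: %s", path))
  schema <- BUNDLE_SCHEMAS[[nm]]
  # readr warns on mismatches; we re-check below and raise hard errors
  df <- suppressWarnings(
    readr::read_csv(path, col_types = schema, na = "",
                    progress = FALSE, show_col_types = FALSE))
  expected <- names(schema$cols)
  if (!identical(names(df), expected)) {
    abort(sprintf("%s: expected columns %s, found %s", basename(path),
                  paste(expected, collapse = ", "),
                  paste(names(df), collapse = ", ")))
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("%s: %d parsing problem(s); first at row %d (%s)",
                  basename(path), nrow(probs), probs$row[1],
                  probs$expected[1]))
  }
  for (col in DOUBLE_COLUMNS[[nm]]) {
    v <- as.numeric(df[[col]])
    if (anyNA(v) && !all(is.na(df[[col]][is.na(v)]))) {
      abort(sprintf("%s: non-numeric value in `%s`", basename(path), col))
    }
    df[[col]] <- v
  }
  if (nm == "truth") {
    df$true_category <- factor(df$true_category, levels = EGFR_CATEGORIES)
  }
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  class(df) <- c("tbl_df", "tbl", "data.frame")
  df
}
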