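#' Run the full validation pipeline
#'
#' Sequences the whole analysis: simulate (or load) an administrative-data
#' bundle, accrue the cohort, compute the eGFR reference standard, flag
#' patients with the code algorithm, and evaluate stratified diagnostic
#' accuracy. The run is deterministic given the seed, and a manifest of
#' configuration and input hashes makes reruns verifiable.
#'
#' The configuration is a nested list (or a path to a YAML file with the
#' same structure):
#' \describe{
#'   \item{seed}{integer RNG seed (default 1).}
#'   \item{simulate}{list of [sim_params()] arguments (needs `n_patients`),
#'     or `NULL` to read an existing bundle.}
#'   \item{input_dir}{directory of CSV tables when `simulate` is `NULL`.}
#'   \item{accrual}{list of [accrual_config()] arguments.}
#'   \item{reference}{list: `outpatient_only`, `tie_break`,
#'     `race_coefficient`.}
#'   \item{algorithm}{`"ckd_final"`, a path to a YAML definition, an
#'     [algorithm_spec()], or a list of `algorithm_spec()` arguments with a
#'     `codes` data frame.}
#'   \item{strata, thresholds, age_break, level}{passed to
#'     [stratified_report()].}
#' }
#'
#' @param config A list as described, or a YAML file path.
#' @return A list of class `ckd_report`: `bundle`, `cohort`, `tally`,
#'   `reference`, `flags`, `performance` (a `ckd_strat_report`),
#'   `contrasts`, `stability`, and `manifest`.
#' @examples
#' rep <- run_pipeline(list(seed = 3, simulate = list(n_patients = 500)))
#' rep$performance
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "simulate", "input_dir", "accrual", "reference",
             "algorithm", "strata", "thresholds", "age_break", "level")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  seed <- config$seed %||% 1L

  bundle <- if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    simulate_cohort(do.call(sim_params, sim_args))
  } else if (!is.null(config$input_dir)) {
    read_bundle(config$input_dir, truth = FALSE)
  } else {
    abort("config needs either `simulate` parameters or an `input_dir`")
  }

  acc <- do.call(accrual_config, as_date_args(config$accrual %||% list()))
  cohort <- accrue(bundle$patients, bundle$prescriptions, bundle$labs,
                   bundle$events, acc)
  tally <- exclusion_tally(cohort)

  ref_args <- config$reference %||% list()
  reference <- reference_standard(
    cohort, bundle$labs,
    lookback_days = acc$lab_lookback_days,
    outpatient_only = ref_args$outpatient_only %||% FALSE,
    tie_break = ref_args$tie_break %||% "lowest",
    race_coefficient = ref_args$race_coefficient %||% FALSE
  )
  # under outpatient-only restriction some included patients lose their lab
  if (!setequal(reference$patient_id,
                cohort$patient_id[cohort$included])) {
    keep <- cohort$patient_id %in% reference$patient_id | !cohort$included
    cohort <- new_cohort(cohort[keep, ], attr(cohort, "config"))
  }

  spec <- resolve_algorithm(config$algorithm %||% "ckd_final")
  flags <- flag_patients(cohort, bundle$codes, spec)

  performance <- stratified_report(
    cohort, reference, flags,
    strata = config$strata %||% c("overall", "age", "sex"),
    thresholds = config$thresholds %||% c(60, 45, 30),
    age_break = config$age_break %||% 80,
    level = config$level %||% 0.95
  )
  contrasts <- flag_contrasts(cohort, reference, flags)
  stability <- stability_check(reference, bundle$labs, cohort)

  manifest <- list(
    config_hash = hash(config),
    seed = seed,
    algorithm = spec$name,
    input_hashes = lapply(bundle[setdiff(BUNDLE_TABLES, "truth")], hash),
    n_patients = nrow(bundle$patients),
    n_included = sum(cohort$included),
    package_version = as.character(utils::packageVersion("ckdcodes"))
  )
  structure(
    list(bundle = bundle, cohort = cohort, tally = tally,
         reference = reference, flags = flags, performance = performance,
         contrasts = contrasts, stability = stability, manifest = manifest),
    class = "ckd_report"
  )
}

as_date_args <- function(args) {
  for (k in c("accrual_start", "accrual_end")) {
    if (!is.null(args[[k]])) args[[k]] <- parse_date_strict(args[[k]], k)
  }
  args
}

resolve_algorithm <- function(algorithm) {
  if (inherits(algorithm, "algorithm_spec")) return(algorithm)
  if (is.character(algorithm) && length(algorithm) == 1) {
    if (identical(algorithm, "ckd_final")) {
      return(algorithm_spec("ckd_final", ckd_final_codes()))
    }
    if (file.exists(algorithm)) return(read_algorithm(algorithm))
    abort(sprintf(
      "config key `algorithm`: unknown algorithm \"%s\" (not \"ckd_final\" and no such file)",
      algorithm))
  }
  if (is.list(algorithm)) {
    algorithm$codes <- tibble::as_tibble(algorithm$codes)
    return(do.call(algorithm_spec, algorithm))
  }
  abort("config key `algorithm`: unrecognised value")
}

#' @export
print.ckd_report <- function(x, ...) {
  cat(sprintf("<ckd_report> %d patients, %d included, algorithm \"%s\"\n",
              x$manifest$n_patients, x$manifest$n_included,
              x$manifest$algorithm))
  overall <- filter(x$performance, .data$stratum_var == "overall")
  for (i in seq_len(nrow(overall))) {
    cat(sprintf("  eGFR <%d: sens %s%%, spec %s%%, PPV %s%%, NPV %s%%\n",
                overall$threshold[i], fmt_pct(overall$sensitivity[i]),
                fmt_pct(overall$specificity[i]), fmt_pct(overall$ppv[i]),
                fmt_pct(overall$npv[i])))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `cohort.csv`, `reference.csv`, `flags.csv`, `exclusion_tally.csv`,
#' machine-readable `validity_report.json` (stratified performance,
#' contrasts, stability), `performance.tsv`, and `manifest.json`. Outputs
#' are deterministic: rerunning the same configuration and seed reproduces
#' the files byte for byte.
#'
#' @param report A `ckd_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ckd_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(report$cohort), file.path(dir, "cohort.csv"), na = "")
  readr::write_csv(tibble::as_tibble(report$reference), file.path(dir, "reference.csv"), na = "")
  readr::write_csv(report$flags, file.path(dir, "flags.csv"), na = "")
  readr::write_csv(report$tally, file.path(dir, "exclusion_tally.csv"), na = "")
  readr::write_tsv(tibble::as_tibble(report$performance),
                   file.path(dir, "performance.tsv"), na = "")
  jsonlite::write_json(
    list(performance = tibble::as_tibble(report$performance),
         contrasts = report$contrasts,
         stability = report$stability,
         exclusions = report$tally),
    file.path(dir, "validity_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
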