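#' Stratified algorithm performance
#'
#' Evaluates the algorithm flags against each eGFR threshold overall and
#' within strata (age band 66-80 vs >80; women vs men), with Wilson
#' intervals for every metric, mirroring how validation studies tabulate
#' threshold-specific and subgroup performance. Within each stratifying
#' variable and threshold, a two-proportion chi-square p-value compares
#' each stratum's sensitivity to the first stratum's.
#'
#' @param cohort A `ckd_cohort`.
#' @param reference A `ckd_reference`.
#' @param flags Output of [flag_patients()].
#' @param strata Character subset of `c("overall", "age", "sex")`.
#' @param thresholds eGFR thresholds to evaluate (subset of 60, 45, 30).
#' @param age_break Boundary between the two age bands (default 80:
#'   66-80 vs >80, completed years).
#' @param level Confidence level for Wilson intervals.
#' @return A tibble of class `ckd_strat_report`: one row per stratum x
#'   threshold with counts, the four accuracy metrics with intervals,
#'   prevalence, and `p_vs_first` (sensitivity comparison).
#' @examples
#' b <- simulate_cohort(sim_params(2000, seed = 11))
#' ch <- accrue(b$patients, b$prescriptions, b$labs, b$events)
#' ref <- reference_standard(ch, b$labs)
#' fl <- flag_patients(ch, b$codes, algorithm_spec("ckd", ckd_final_codes()))
#' stratified_report(ch, ref, fl, strata = c("overall", "sex"))
#' @export
stratified_report <- function(cohort, reference, flags,
                              strata = c("overall", "age", "sex"),
                              thresholds = c(60, 45, 30),
                              age_break = 80, level = 0.95) {
  strata <- match.arg(strata, several.ok = TRUE)
  stopifnot(all(thresholds %in% c(60, 45, 30)))
  sf <- strata_frame(cohort, strata, age_break) |>
    semi_join(flags, by = "patient_id")

  out <- purrr::pmap_dfr(
    distinct(sf[c("stratum_var", "stratum")]),
    function(stratum_var, stratum) {
      ids <- sf$patient_id[sf$stratum_var == stratum_var &
                             sf$stratum == stratum]
      purrr::map_dfr(thresholds, function(th) {
        label <- paste0("lt", th)
        if (length(ids) == 0) {
          warn(sprintf("empty stratum %s = %s", stratum_var, stratum))
          return(tibble::tibble(stratum_var, stratum, threshold = th))
        }
        t2 <- contingency(filter(flags, .data$patient_id %in% ids),
                          filter(reference, .data$patient_id %in% ids),
                          label)
        m <- metrics(t2, level, warn_null = FALSE)
        s <- m$summary
        wide <- purrr::list_flatten(purrr::pmap(
          s[c("metric", "estimate", "conf.low", "conf.high")],
          function(metric, estimate, conf.low, conf.high) {
            stats::setNames(list(estimate, conf.low, conf.high),
                            paste0(metric, c("", "_low", "_high")))
          }))
        tibble::tibble(stratum_var, stratum, threshold = th,
                       n = m$n, tp = t2$tp, fp = t2$fp, fn = t2$fn, tn = t2$tn,
                       !!!wide)
      })
    })

  # sensitivity comparison against the first stratum of each variable
  out <- out |>
    group_by(.data$stratum_var, .data$threshold) |>
    mutate(p_vs_first = {
      tp_ <- .data$tp; fp_ <- .data$fp; fn_ <- .data$fn; tn_ <- .data$tn
      purrr::map_dbl(seq_along(tp_), function(i) {
        if (i == 1 || length(tp_) < 2 || is.na(tp_[i]) || is.na(tp_[1])) {
          return(NA_real_)
        }
        compare_sensitivities(two_by_two(tp_[1], fp_[1], fn_[1], tn_[1]),
                              two_by_two(tp_[i], fp_[i], fn_[i], tn_[i]))
      })
    }) |>
    ungroup()
  class(out) <- c("ckd_strat_report", class(out))
  attr(out, "level") <- level
  out
}

strata_frame <- function(cohort, strata, age_break = 80) {
  inc <- filter(cohort, .data$included)
  pieces <- list()
  if ("overall" %in% strata) {
    pieces$overall <- tibble::tibble(patient_id = inc$patient_id,
                                     stratum_var = "overall", stratum = "all")
  }
  if ("age" %in% strata) {
    pieces$age <- tibble::tibble(
      patient_id = inc$patient_id, stratum_var = "age",
      stratum = ifelse(inc$age_at_index <= age_break,
                       sprintf("66-%d", age_break),
                       sprintf(">%d", age_break))
    )
  }
  if ("sex" %in% strata) {
    pieces$sex <- tibble::tibble(
      patient_id = inc$patient_id, stratum_var = "sex",
      stratum = ifelse(inc$sex == "M", "men", "women")
    )
  }
  bind_rows(pieces) |>
    arrange(factor(.data$stratum_var, levels = c("overall", "age", "sex")),
            .data$stratum, .data$patient_id)
}

#' Creatinine and eGFR distributions by algorithm flag
#'
#' Median and interquartile range (25th/75th percentiles, linear
#' interpolation) of baseline serum creatinine and eGFR, split by algorithm
#' flag and optionally by stratum — the continuous-value contrast showing
#' that flagged patients sit at distinctly worse kidney function.
#'
#' @inheritParams stratified_report
#' @return Tibble: `stratum_var`, `stratum`, `positive`, `n`, and
#'   median/q25/q75 of `egfr` and `creatinine`.
#' @export
flag_contrasts <- function(cohort, reference, flags,
                           strata = "overall", age_break = 80) {
  strata <- match.arg(strata, c("overall", "age", "sex"), several.ok = TRUE)
  sf <- strata_frame(cohort, strata, age_break)
  sf |>
    inner_join(flags[c("patient_id", "positive")], by = "patient_id") |>
    inner_join(reference[c("patient_id", "egfr", "baseline_creatinine_umol_l")],
               by = "patient_id") |>
    group_by(.data$stratum_var, .data$stratum, .data$positive) |>
    summarise(
      n = dplyr::n(),
      egfr_median = median(.data$egfr),
      egfr_q25 = unname(quantile(.data$egfr, 0.25)),
      egfr_q75 = unname(quantile(.data$egfr, 0.75)),
      creatinine_median = median(.data$baseline_creatinine_umol_l),
      creatinine_q25 = unname(quantile(.data$baseline_creatinine_umol_l, 0.25)),
      creatinine_q75 = unname(quantile(.data$baseline_creatinine_umol_l, 0.75)),
      .groups = "drop"
    )
}
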