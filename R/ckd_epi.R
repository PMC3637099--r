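#' Estimate GFR from serum creatinine (CKD-EPI 2009)
#'
#' Computes the estimated glomerular filtration rate from serum creatinine,
#' age, and sex using the 2009 CKD-EPI creatinine equation:
#' \deqn{eGFR = 141 \times \min(S/\kappa, 1)^{\alpha} \times
#'   \max(S/\kappa, 1)^{-1.209} \times 0.993^{age} \times 1.018[\mathrm{female}]}
#' where \eqn{S} is creatinine in mg/dL (input is micromol/L, divided by 88.4),
#' \eqn{\kappa} = 0.7 (female) / 0.9 (male), and \eqn{\alpha} = -0.329 (female)
#' / -0.411 (male). The result is strictly decreasing in creatinine and in age.
#'
#' The optional race multiplier (1.159) of the original publication is off by
#' default: the administrative data this package models carry no race field.
#'
#' @param creatinine_umol_l Serum creatinine, micromol/L; must be positive.
#' @param age Age in years.
#' @param sex Character vector, `"F"` or `"M"`.
#' @param race_coefficient Apply the 1.159 multiplier? Default `FALSE`.
#' @return eGFR in mL/min per 1.73 m^2 (unrounded).
#' @examples
#' ckd_epi_egfr(84, 75, "F")    # ~58.6
#' ckd_epi_egfr(79.56, 66, "M") # ~88.7 (creatinine/kappa exactly 1)
#' @seealso [invert_ckd_epi()], [classify_egfr()]
#' @export
ckd_epi_egfr <- function(creatinine_umol_l, age, sex, race_coefficient = FALSE) {
  if (any(!is.finite(creatinine_umol_l) | creatinine_umol_l <= 0)) {
    abort("`creatinine_umol_l` must be positive and finite")
  }
  if (any(age < 0)) abort("`age` must be non-negative")
  sex <- check_sex(sex)
  female <- sex == "F"
  scr <- creatinine_umol_l / 88.4
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  s <- scr / kappa
  out <- 141 * pmin(s, 1)^alpha * pmax(s, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1)
  if (race_coefficient) out <- out * 1.159
  out
}

#' Serum creatinine that yields a given eGFR
#'
#' Closed-form inverse of [ckd_epi_egfr()] at fixed age and sex. The equation
#' is strictly decreasing in creatinine, so the inverse is unique: with
#' \eqn{b = eGFR / (141 \times 0.993^{age} \times 1.018[\mathrm{F}])},
#' the normalised creatinine is \eqn{b^{1/\alpha}} when \eqn{b > 1}
#' (creatinine below \eqn{\kappa}) and \eqn{b^{-1/1.209}} otherwise.
#' Round-tripping through [ckd_epi_egfr()] recovers the input to well under
#' 1e-6 mL/min per 1.73 m^2.
#'
#' @inheritParams ckd_epi_egfr
#' @param egfr Target eGFR, mL/min per 1.73 m^2; must be positive.
#' @return Serum creatinine in micromol/L.
#' @examples
#' ckd_epi_egfr(invert_ckd_epi(45, 80, "M"), 80, "M")  # 45
#' @export
invert_ckd_epi <- function(egfr, age, sex, race_coefficient = FALSE) {
  if (any(!is.finite(egfr) | egfr <= 0)) abort("`egfr` must be positive and finite")
  sex <- check_sex(sex)
  female <- sex == "F"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  base <- egfr / (141 * 0.993^age * ifelse(female, 1.018, 1))
  if (race_coefficient) base <- base / 1.159
  s <- ifelse(base > 1, base^(1 / alpha), base^(-1 / 1.209))
  s * kappa * 88.4
}

#' Classify eGFR into categories and threshold labels
#'
#' Assigns each eGFR to one of the five categories `">=60"`, `"45-59"`,
#' `"30-44"`, `"15-29"`, `"<15"` (lower bound inclusive, upper exclusive:
#' eGFR = 45 is `"45-59"`) and to the three nested disease labels
#' eGFR < 60, < 45, < 30 used as reference-standard thresholds.
#'
#' @param egfr Numeric vector of eGFR values, mL/min per 1.73 m^2.
#' @return A tibble with columns `egfr`, `category` (factor), and logicals
#'   `lt60`, `lt45`, `lt30`. The labels are nested: `lt30` implies `lt45`
#'   implies `lt60`.
#' @examples
#' classify_egfr(c(45, 44.999, 14))
#' @export
classify_egfr <- function(egfr) {
  if (any(!is.finite(egfr) | egfr <= 0)) abort("`egfr` must be positive and finite")
  tibble::tibble(
    egfr = egfr,
    category = egfr_category(egfr),
    lt60 = egfr < 60,
    lt45 = egfr < 45,
    lt30 = egfr < 30
  )
}

egfr_category <- function(egfr) {
  cut(egfr, breaks = rev(EGFR_BREAKS), labels = rev(EGFR_CATEGORIES),
      right = FALSE) |>
    factor(levels = EGFR_CATEGORIES)
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  if (any(!sex %in% c("F", "M"))) abort('`sex` must be "F" or "M"')
  sex
}
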