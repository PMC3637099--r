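#' Construct a 2x2 contingency table
#'
#' @param tp,fp,fn,tn Non-negative integer counts: true positives, false
#'   positives, false negatives, true negatives (algorithm flag vs
#'   reference-standard label).
#' @return A list of class `ckd_2x2`.
#' @examples
#' two_by_two(tp = 6214, fp = 3287, fn = 12797, tn = 101201)
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts) | counts < 0 | counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(as.list(counts), class = "ckd_2x2")
}

#' @export
print.ckd_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(`algorithm` = c("positive", "negative"),
                              `reference` = c("diseased", "not diseased")))
  print(m)
  invisible(x)
}

#' Cross-tabulate algorithm flags against reference labels
#'
#' Joins per-patient flags to reference labels and counts the 2x2 table.
#' The two tables must cover exactly the same patients.
#'
#' @param flags Tibble with `patient_id` and logical `positive` (output of
#'   [flag_patients()]).
#' @param reference Tibble with `patient_id` and the label column — a
#'   `ckd_reference`, or any frame with a logical label.
#' @param label Name of the logical label column in `reference`
#'   (default `"lt45"`).
#' @return A `ckd_2x2`.
#' @export
contingency <- function(flags, reference, label = "lt45") {
  assert_columns(flags, c("patient_id", "positive"), "flags")
  assert_columns(reference, c("patient_id", label), "reference")
  if (!setequal(flags$patient_id, reference$patient_id) ||
      nrow(flags) != nrow(reference)) {
    abort("`flags` and `reference` must cover the same patients exactly once")
  }
  df <- inner_join(flags[c("patient_id", "positive")],
                   reference[c("patient_id", label)], by = "patient_id")
  lab <- df[[label]]
  if (anyNA(df$positive) || anyNA(lab)) abort("flags and labels must be non-missing")
  two_by_two(
    tp = sum(df$positive & lab),
    fp = sum(df$positive & !lab),
    fn = sum(!df$positive & lab),
    tn = sum(!df$positive & !lab)
  )
}

#' Diagnostic-accuracy metrics with Wilson intervals
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive
#' predictive value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)`,
#' prevalence `(tp+fn)/N`, and the algorithm-positive proportion
#' `(tp+fp)/N`, each with a Wilson score confidence interval. A zero
#' denominator yields `NA` (with a warning unless `warn_null = FALSE`).
#'
#' @param x A `ckd_2x2`.
#' @param level Confidence level (default 0.95).
#' @param warn_null Warn when a denominator is zero?
#' @return An object of class `ckd_validity`; see [tidy.ckd_validity()] and
#'   [glance.ckd_validity()].
#' @examples
#' m <- metrics(two_by_two(tp = 30, fp = 10, fn = 70, tn = 890))
#' tidy(m)
#' @export
metrics <- function(x, level = 0.95, warn_null = TRUE) {
  stopifnot(inherits(x, "ckd_2x2"))
  n <- x$tp + x$fp + x$fn + x$tn
  parts <- tibble::tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv",
               "prevalence", "positives"),
    successes = c(x$tp, x$tn, x$tp, x$tn, x$tp + x$fn, x$tp + x$fp),
    n = c(x$tp + x$fn, x$tn + x$fp, x$tp + x$fp, x$tn + x$fn, n, n)
  )
  if (warn_null && any(parts$n == 0)) {
    warn(sprintf("zero denominator for %s; reporting NA",
                 paste(parts$metric[parts$n == 0], collapse = ", ")))
  }
  est <- ifelse(parts$n > 0, parts$successes / parts$n, NA_real_)
  ci <- wilson_ci(parts$successes, parts$n, level)
  structure(
    list(
      table = x, level = level, n = n,
      estimates = stats::setNames(as.list(est), parts$metric),
      summary = mutate(parts, estimate = est,
                       conf.low = ci$conf.low, conf.high = ci$conf.high)
    ),
    class = "ckd_validity"
  )
}

#' @export
print.ckd_validity <- function(x, digits = 1, ...) {
  cat(sprintf("<ckd_validity> n = %d (tp %d, fp %d, fn %d, tn %d)\n",
              x$n, x$table$tp, x$table$fp, x$table$fn, x$table$tn))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %5s%% (%g%% CI: %s to %s)\n", s$metric[i],
                fmt_pct(s$estimate[i], digits), 100 * x$level,
                fmt_pct(s$conf.low[i], digits), fmt_pct(s$conf.high[i], digits)))
  }
  invisible(x)
}

fmt_pct <- function(p, digits = 1) {
  ifelse(is.na(p), "NA", formatC(100 * p, format = "f", digits = digits))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form score interval: with \eqn{\hat p = x/n} and \eqn{z} the
#' standard-normal quantile for the requested level, the centre is
#' \eqn{(\hat p + z^2/2n) / (1 + z^2/n)} and the half-width
#' \eqn{z \sqrt{\hat p (1-\hat p)/n + z^2/4n^2} / (1 + z^2/n)}. The
#' interval always lies in \[0, 1\] and contains \eqn{\hat p}; unlike the
#' Wald interval it behaves sensibly at the boundaries (for 0 successes the
#' lower bound is exactly 0 but the upper bound is positive).
#'
#' @param successes,n Integer vectors (recycled); `0 <= successes <= n`.
#' @param level Confidence level.
#' @return Tibble with columns `conf.low`, `conf.high`; rows with `n = 0`
#'   are `NA`.
#' @examples
#' wilson_ci(6214, 19011)  # ~ (0.320, 0.334)
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  len <- max(length(successes), length(n))
  successes <- rep_len(successes, len)
  n <- rep_len(n, len)
  if (any(n > 0 & (successes < 0 | successes > n), na.rm = TRUE)) {
    abort("`successes` must lie in [0, n]")
  }
  z <- qnorm(1 - (1 - level) / 2)
  p <- ifelse(n > 0, successes / n, NA_real_)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(
    conf.low = ifelse(n > 0, pmax(centre - half, 0), NA_real_),
    conf.high = ifelse(n > 0, pmin(centre + half, 1), NA_real_)
  )
}

#' Compare sensitivities between two strata
#'
#' Two-proportion Pearson chi-square test (no continuity correction) on the
#' diseased rows (tp, fn) of two 2x2 tables — e.g. men vs women, or the two
#' age bands. Fisher's exact test is available for small strata.
#'
#' @param a,b `ckd_2x2` tables for the two strata.
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return Two-sided p-value (`NA` if a stratum has no diseased patients).
#' @export
compare_sensitivities <- function(a, b, method = c("chisq", "fisher")) {
  stopifnot(inherits(a, "ckd_2x2"), inherits(b, "ckd_2x2"))
  method <- match.arg(method)
  if (a$tp + a$fn == 0 || b$tp + b$fn == 0) return(NA_real_)
  m <- matrix(c(a$tp, a$fn, b$tp, b$fn), 2, 2)
  if (method == "chisq") {
    if (a$tp + b$tp == 0 || a$fn + b$fn == 0) return(1)
    suppressWarnings(
      prop.test(c(a$tp, b$tp), c(a$tp + a$fn, b$tp + b$fn),
                correct = FALSE)$p.value
    )
  } else {
    stats::fisher.test(m)$p.value
  }
}
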