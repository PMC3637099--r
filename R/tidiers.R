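#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy diagnostic-accuracy metrics
#'
#' @param x A `ckd_validity` from [metrics()].
#' @param ... Unused.
#' @return A tibble with one row per metric: `metric`, `estimate`,
#'   `conf.low`, `conf.high`, `successes`, `n`.
#' @export
tidy.ckd_validity <- function(x, ...) {
  x$summary[c("metric", "estimate", "conf.low", "conf.high", "successes", "n")]
}

#' One-row summary of diagnostic accuracy
#'
#' @param x A `ckd_validity` from [metrics()].
#' @param ... Unused.
#' @return A one-row tibble with the four accuracy metrics, prevalence,
#'   positives proportion, counts, and the confidence level.
#' @export
glance.ckd_validity <- function(x, ...) {
  tibble::tibble(
    sensitivity = x$estimates$sensitivity,
    specificity = x$estimates$specificity,
    ppv = x$estimates$ppv,
    npv = x$estimates$npv,
    prevalence = x$estimates$prevalence,
    positives = x$estimates$positives,
    tp = x$table$tp, fp = x$table$fp, fn = x$table$fn, tn = x$table$tn,
    n = x$n, conf.level = x$level
  )
}

#' @export
tidy.ckd_2x2 <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fp", "fn", "tn"),
                 count = c(x$tp, x$fp, x$fn, x$tn))
}
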