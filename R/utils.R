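#' Age in completed years at a given date
#'
#' Whole years elapsed between birth and a reference date, the convention
#' used for eligibility (minimum age 66) and for the age term of the
#' CKD-EPI equation.
#'
#' @param birth_date,at `Date` vectors (recycled to common length).
#' @return Integer vector of completed years.
#' @examples
#' age_completed_years(as.Date("1940-06-15"), as.Date("2008-06-14"))  # 67
#' @export
age_completed_years <- function(birth_date, at) {
  as.integer(lubridate::interval(birth_date, at) %/% lubridate::years(1))
}

# Subtract whole years from a date, rolling back month-end (Feb 29 safe).
years_before <- function(date, n) {
  date %m-% lubridate::years(n)
}

#' @importFrom lubridate %m-%
NULL

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

parse_date_strict <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("unparseable date in `%s` at row %d: \"%s\"",
                  what, bad[1], as.character(x[bad[1]])))
  }
  out
}
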