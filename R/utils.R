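#' Round half away from zero
#'
#' Percentages are reported to one decimal with ties rounded away from zero
#' (so 44.85 -> 44.9), matching conventional clinical-audit reporting rather
#' than IEEE banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Completion percentage from counts
#'
#' `100 * n_with_form / n_eligible`, rounded half away from zero to one
#' decimal.  Undefined (NA) when the denominator is zero: an empty team has
#' no completion rate, which is reported as absent rather than 0.
#'
#' @param n_with numerator count.
#' @param n_eligible denominator count.
#' @return percentage (one decimal) or NA_real_.
#' @export
completion_pct <- function(n_with, n_eligible) {
  ifelse(n_eligible > 0, round_half_up(100 * n_with / n_eligible, 1), NA_real_)
}

#' Monthly census dates (28th of each month)
#'
#' @param from,to "YYYY-MM" strings (inclusive).
#' @return Date vector, one 28th per month.
#' @export
monthly_censuses <- function(from = "2017-10", to = "2019-01") {
  f <- as.Date(paste0(from, "-28"))
  t <- as.Date(paste0(to, "-28"))
  if (is.na(f) || is.na(t)) stop("census bounds must be 'YYYY-MM'", call. = FALSE)
  if (f > t) stop("census start is after census end", call. = FALSE)
  out <- seq(f, t, by = "1 month")
  # seq() by month from a day-28 anchor always lands on the 28th
  out
}

as_iso_date <- function(x, field = "date") {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(d) && !all(is.na(x))) {
    stop(sprintf("field '%s' contains unparseable dates", field), call. = FALSE)
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
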