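#' Parse FAERS compact dates
#'
#' FAERS date fields are compact strings with variable precision:
#' `YYYYMMDD`, `YYYYMM` or `YYYY`. A partial date is kept at its stated
#' precision: it participates in ordering comparisons (via
#' [faers_date_num()]) but counts as absent for day-level arithmetic
#' ([faers_date_day()] returns `NA`).
#'
#' @param x character vector of raw date strings.
#' @return `faers_date_prec()`: integer vector of precision in digits
#'   (8, 6, 4) or `NA` for unparseable/empty values.
#' @keywords internal
#' @name faers-dates
NULL

#' @rdname faers-dates
#' @export
faers_date_prec <- function(x) {
  x <- trimws(as.character(x))
  n <- nchar(x)
  ok <- !is.na(x) & grepl("^[0-9]+$", x) & n %in% c(4L, 6L, 8L)
  out <- rep(NA_integer_, length(x))
  out[ok] <- n[ok]
  out
}

#' @rdname faers-dates
#' @return `faers_date_num()`: numeric sort key on a common `YYYYMMDD`
#'   scale (year and month precision padded with zeros), `NA` when
#'   unparseable. Comparable across precisions for keep-latest rules.
#' @export
faers_date_num <- function(x) {
  x <- trimws(as.character(x))
  p <- faers_date_prec(x)
  v <- suppressWarnings(as.numeric(x))
  out <- rep(NA_real_, length(x))
  out[!is.na(p) & p == 8L] <- v[!is.na(p) & p == 8L]
  out[!is.na(p) & p == 6L] <- v[!is.na(p) & p == 6L] * 100
  out[!is.na(p) & p == 4L] <- v[!is.na(p) & p == 4L] * 10000
  out
}

#' @rdname faers-dates
#' @return `faers_date_day()`: a `Date` vector; `NA` unless the value is
#'   a valid full `YYYYMMDD` date.
#' @export
faers_date_day <- function(x) {
  x <- trimws(as.character(x))
  p <- faers_date_prec(x)
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(p) & p == 8L
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    out[full] <- d
  }
  out
}

#' @rdname faers-dates
#' @return `faers_date_year()`: integer calendar year or `NA`.
#' @export
faers_date_year <- function(x) {
  p <- faers_date_prec(x)
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(p)
  out[ok] <- as.integer(substr(trimws(as.character(x[ok])), 1L, 4L))
  out
}

# FAERS age unit codes, in years per unit
.age_unit_years <- c(
  YR = 1, YEAR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
  DY = 1 / 365.25, HR = 1 / 8766
)

#' Normalize FAERS age to years
#'
#' Converts an age value plus FAERS unit code (`YR`, `DEC`, `MON`, `WK`,
#' `DY`, `HR`) to years. A missing or unrecognized unit code is treated
#' as years, the FAERS convention for unqualified ages.
#'
#' @param value numeric age values.
#' @param unit character unit codes.
#' @return numeric vector of ages in years (`NA` where value missing or
#'   negative).
#' @export
age_in_years <- function(value, unit) {
  value <- suppressWarnings(as.numeric(value))
  unit <- toupper(trimws(as.character(unit)))
  mult <- .age_unit_years[unit]
  mult[is.na(mult)] <- 1
  out <- value * as.numeric(mult)
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Round half away from zero
#'
#' Presentation rounding used for reported percentages: exact halves go
#' up (`round_half_up(0.125, 2)` is `0.13`), unlike base `round()`'s
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage of a count over a denominator
#'
#' `100 * count / denom`, rounded half-up to two decimals — the
#' presentation convention used throughout the descriptive summaries.
#' Returns `NA` for a zero denominator.
#'
#' @param count numeric counts.
#' @param denom denominator (single value or vector).
#' @param digits decimal places (default 2).
#' @return numeric percentages.
#' @export
pct <- function(count, denom, digits = 2) {
  out <- round_half_up(100 * count / denom, digits)
  out[denom == 0] <- NA_real_
  out
}
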