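#' @keywords internal
"_PACKAGE"

# Length of one reporting month in days. Administrative extracts carry
# day-level dates; month-level quantities (timing-agreement bins, RFS
# summaries) divide day counts by this fixed constant so results do not
# depend on which calendar months a difference happens to span.
DAYS_PER_MONTH <- 30.4375

#' Add calendar months to a date, clamping to month end
#'
#' Calendar-month addition used for landmark dates: the day-of-month is kept
#' where it exists in the target month and clamped to the last day otherwise
#' (2008-08-31 plus 6 months is 2009-02-28).
#'
#' @param date a `Date` (vectorised).
#' @param months integer number of months to add.
#' @return a `Date` vector.
#' @export
#' @examples
#' add_months(as.Date("2008-03-15"), 6)  # 2008-09-15
#' add_months(as.Date("2008-08-31"), 6)  # 2009-02-28
add_months <- function(date, months) {
  stopifnot(inherits(date, "Date"))
  lt <- as.POSIXlt(date)
  day <- lt$mday
  m0 <- lt$year * 12L + lt$mon + as.integer(months)
  yr <- m0 %/% 12L + 1900L
  mo <- m0 %% 12L + 1L
  last <- days_in_month(yr, mo)
  out <- as.Date(sprintf("%04d-%02d-%02d", yr, mo, pmin(day, last)))
  out
}

days_in_month <- function(year, month) {
  n <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(month == 2L & leap, 29L, n)
}

# Integer day difference a - b.
days_between <- function(a, b) as.integer(round(as.numeric(a) - as.numeric(b)))

# Round half away from zero (the paper-style 1-decimal percentage rule;
# base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct1 <- function(num, den) {
  if (den == 0) return(NA_real_)
  round_half_up(100 * num / den, 1)
}

parse_iso_date <- function(x, what, file) {
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  nonblank <- !is.na(x) & nzchar(trimws(x))
  parsed <- as.Date(trimws(x[nonblank]), format = "%Y-%m-%d", optional = TRUE)
  bad <- is.na(parsed)
  if (any(bad)) {
    row <- which(nonblank)[which(bad)[1]]
    stop(sprintf("%s: unparseable date '%s' in column '%s' (data row %d)",
                 file, x[nonblank][which(bad)[1]], what, row), call. = FALSE)
  }
  out[nonblank] <- parsed
  out
}

parse_yesno <- function(x, what, file) {
  v <- tolower(trimws(x))
  blank <- is.na(x) | !nzchar(v)
  bad <- !blank & !v %in% c("yes", "no")
  if (any(bad)) {
    stop(sprintf("%s: column '%s' must be 'yes'/'no', found '%s' (data row %d)",
                 file, what, x[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  out <- rep(NA, length(x))
  out[!blank] <- v[!blank] == "yes"
  out
}

format_yesno <- function(x) ifelse(is.na(x), "", ifelse(x, "yes", "no"))

format_date_col <- function(x) ifelse(is.na(x), "", format(x, "%Y-%m-%d"))

`%||%` <- function(a, b) if (is.null(a)) b else a
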