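#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Monday = 1 ... Sunday = 7, independent of locale
wday1 <- function(date) {
  lubridate::wday(date, week_start = 1)
}

is_weekday <- function(date) {
  wday1(date) <= 5
}

# weekdays in [from, to], inclusive; zero-length when to < from
weekdays_between <- function(from, to) {
  if (is.na(from) || is.na(to) || to < from) return(as.Date(character()))
  days <- seq(as.Date(from), as.Date(to), by = "day")
  days[is_weekday(days)]
}

n_weekdays_between <- function(from, to) length(weekdays_between(from, to))

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

round1 <- function(x) round(x, 1)

# percentage helpers used across the summary tables; safe at zero denominator
pct <- function(num, den, digits = 1) {
  ifelse(den > 0, round(100 * num / den, digits), 0)
}
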