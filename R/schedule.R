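#' Daily epoch schedule of the smartwatch
#'
#' The watch divides the monitored day (08:00--17:00) into five consecutive
#' periods: four of 2 h and a final 1-h period matched to the remaining
#' battery life. `epoch_schedule()` builds the configuration object and
#' validates that the periods tile the day without gaps or overlaps;
#' `build_epochs()` instantiates the five half-open windows for a calendar
#' date.
#'
#' @param start Clock time the first period opens, `"HH:MM"`. Default 08:00.
#' @param durations_min Integer vector of period lengths in minutes, one per
#'   period. Default `c(120, 120, 120, 120, 60)`.
#' @return A `swaft_schedule` list with elements `start` (seconds after
#'   midnight) and `durations` (seconds).
#' @examples
#' build_epochs(as.Date("2015-11-16"))
#' @export
epoch_schedule <- function(start = "08:00", durations_min = c(120, 120, 120, 120, 60)) {
  start_sec <- as.numeric(hms::as_hms(paste0(start, ":00")))
  if (is.na(start_sec)) abort("`start` must be a clock time like \"08:00\"")
  if (length(durations_min) < 1 || any(!is.finite(durations_min)) || any(durations_min <= 0)) {
    abort("`durations_min` must be positive period lengths")
  }
  end_sec <- start_sec + sum(durations_min) * 60
  if (end_sec > 24 * 3600) abort("schedule runs past midnight; periods must fit one day")
  structure(
    list(start = start_sec, durations = as.numeric(durations_min) * 60),
    class = "swaft_schedule"
  )
}

#' @rdname epoch_schedule
#' @param date Calendar date (`Date` or coercible).
#' @param schedule A schedule from [epoch_schedule()].
#' @return `build_epochs()` returns a tibble with one row per period:
#'   `date`, `period`, `start`, `end` (clock times, `hms`); windows are
#'   half-open `[start, end)`, pairwise disjoint and jointly cover the
#'   scheduled day.
#' @export
build_epochs <- function(date, schedule = epoch_schedule()) {
  if (!inherits(schedule, "swaft_schedule")) abort("`schedule` must come from epoch_schedule()")
  date <- as.Date(date)
  if (length(date) != 1 || is.na(date)) abort("`date` must be a single valid date")
  bounds <- schedule$start + c(0, cumsum(schedule$durations))
  tibble(
    date = date,
    period = seq_along(schedule$durations),
    start = hms::as_hms(bounds[-length(bounds)]),
    end = hms::as_hms(bounds[-1])
  )
}

# seconds-after-midnight bounds for one window row (or list with start/end)
window_bounds <- function(window) {
  if (is.data.frame(window)) {
    if (nrow(window) != 1) abort("`window` must be a single epoch window row")
    c(as.numeric(window$start), as.numeric(window$end))
  } else {
    c(as.numeric(window[["start"]]), as.numeric(window[["end"]]))
  }
}
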