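#' Configuration for activity scoring and wear detection
#'
#' The activity score (AS) summarises overall body movement in a window: the
#' per-sample vector magnitude of tri-axial acceleration has the 1 g gravity
#' magnitude subtracted, is rectified, passed through a small dead-band to
#' suppress sensor noise, then integrated over the window (sum scaled by the
#' sampling interval). The score is an arbitrary movement unit intended for
#' relative, day-to-day comparison, not for calibrated energy expenditure;
#' it is non-negative, additive over partitions of a window, and zero for a
#' stationary wrist.
#'
#' Wear detection is movement-based: the window is tiled into sub-windows and
#' a sub-window counts as active when the variance of the vector magnitude
#' meets the threshold; the watch is deemed worn when at least
#' `min_fraction` of sub-windows are active. Movement-based wear inference
#' is deliberately conservative and will under-estimate wear for a patient
#' lying still.
#'
#' @param deadband_g Dead-band on the rectified magnitude deviation, in g.
#' @param subwindow_sec Sub-window width for wear detection, seconds.
#' @param var_threshold_g2 Active-sub-window variance threshold, in g^2.
#' @param min_fraction Minimum active fraction for `worn = TRUE`.
#' @return A configuration list.
#' @export
scoring_config <- function(deadband_g = 0.05) {
  if (!is.numeric(deadband_g) || deadband_g < 0) abort("`deadband_g` must be >= 0")
  structure(list(deadband_g = deadband_g), class = "swaft_scoring_config")
}

#' @rdname scoring_config
#' @export
wear_config <- function(subwindow_sec = 60, var_threshold_g2 = 1e-4, min_fraction = 0.25) {
  if (subwindow_sec <= 0) abort("`subwindow_sec` must be positive")
  if (var_threshold_g2 < 0) abort("`var_threshold_g2` must be >= 0")
  if (min_fraction < 0 || min_fraction > 1) abort("`min_fraction` must be in [0, 1]")
  structure(
    list(
      subwindow_sec = subwindow_sec,
      var_threshold_g2 = var_threshold_g2,
      min_fraction = min_fraction
    ),
    class = "swaft_wear_config"
  )
}

validate_trace <- function(trace) {
  assert_columns(trace, c("t", "ax", "ay", "az"), "trace")
  t <- as.numeric(trace$t)
  acc <- cbind(trace$ax, trace$ay, trace$az)
  if (anyNA(t) || any(!is.finite(t))) abort("trace timestamps must be finite")
  if (nrow(trace) > 0 && (anyNA(acc) || any(!is.finite(acc)))) {
    abort("trace accelerations must be finite")
  }
  if (is.unsorted(t, strictly = TRUE)) abort("trace timestamps must be strictly increasing")
  invisible(trace)
}

# samples with t (seconds after midnight) in [start, end)
clip_to_window <- function(trace, window) {
  b <- window_bounds(window)
  t <- as.numeric(trace$t)
  trace[t >= b[1] & t < b[2], , drop = FALSE]
}

vector_magnitude <- function(trace) {
  sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
}

#' Activity score of a trace over one epoch window
#'
#' @param trace Data frame with columns `t` (seconds after midnight, strictly
#'   increasing), `ax`, `ay`, `az` (acceleration in g).
#' @param window One row of [build_epochs()] (or a list with `start`/`end`
#'   in seconds); samples are clipped to the half-open window.
#' @param scoring A [scoring_config()].
#' @return A one-row tibble: `activity_score` (AS, arbitrary movement
#'   units), `n_samples` used, and `no_data` (`TRUE` when no sample fell in
#'   the window, in which case the score is 0).
#' @seealso [detect_worn()], [score_traces()]
#' @export
compute_activity_score <- function(trace, window, scoring = scoring_config()) {
  validate_trace(trace)
  inwin <- clip_to_window(trace, window)
  n <- nrow(inwin)
  if (n == 0) {
    return(tibble(activity_score = 0, n_samples = 0L, no_data = TRUE))
  }
  if (n == 1) {
    # a single sample carries no sampling interval, hence no movement measure
    return(tibble(activity_score = 0, n_samples = 1L, no_data = FALSE))
  }
  dt <- stats::median(diff(as.numeric(inwin$t)))
  dev <- pmax(abs(vector_magnitude(inwin) - 1) - scoring$deadband_g, 0)
  tibble(activity_score = sum(dev) * dt, n_samples = n, no_data = FALSE)
}

#' Movement-based wear detection over one epoch window
#'
#' @inheritParams compute_activity_score
#' @param wear A [wear_config()].
#' @return A one-row tibble: `worn` (logical), `worn_fraction` (fraction of
#'   sub-windows whose vector-magnitude variance meets the threshold) and
#'   `n_subwindows`. An empty trace yields `(FALSE, 0)`.
#' @export
detect_worn <- function(trace, window, wear = wear_config()) {
  validate_trace(trace)
  b <- window_bounds(window)
  inwin <- clip_to_window(trace, window)
  breaks <- seq(b[1], b[2], by = wear$subwindow_sec)
  if (breaks[length(breaks)] < b[2]) breaks <- c(breaks, b[2])
  n_sub <- length(breaks) - 1
  if (nrow(inwin) == 0) {
    return(tibble(worn = FALSE, worn_fraction = 0, n_subwindows = n_sub))
  }
  vm <- vector_magnitude(inwin)
  idx <- findInterval(as.numeric(inwin$t), breaks, rightmost.closed = FALSE)
  active <- vapply(seq_len(n_sub), function(i) {
    v <- vm[idx == i]
    length(v) >= 2 && stats::var(v) >= wear$var_threshold_g2
  }, logical(1))
  frac <- mean(active)
  tibble(worn = frac >= wear$min_fraction, worn_fraction = frac, n_subwindows = n_sub)
}

#' Score raw traces into per-epoch activity records
#'
#' Applies [compute_activity_score()] and [detect_worn()] to every
#' (patient, date, period) window on the daily schedule, producing the
#' atomic analytic unit of the trial: one activity score and wear estimate
#' per patient-day-period.
#'
#' @param traces Data frame with `patient_id`, `t` (`POSIXct` timestamps or
#'   numeric epoch seconds) and `ax`, `ay`, `az` in g.
#' @param schedule An [epoch_schedule()].
#' @param scoring A [scoring_config()].
#' @param wear A [wear_config()].
#' @return A tibble of epoch records: `patient_id`, `date`, `period`,
#'   `activity_score`, `worn`, `worn_fraction`. Windows without any sample
#'   are omitted (missing data, not zeros).
#' @export
score_traces <- function(traces, schedule = epoch_schedule(),
                         scoring = scoring_config(), wear = wear_config()) {
  assert_columns(traces, c("patient_id", "t", "ax", "ay", "az"), "traces")
  tt <- traces$t
  if (inherits(tt, "POSIXct")) {
    date <- as.Date(tt, tz = lubridate::tz(tt))
    sod <- as.numeric(tt) - as.numeric(lubridate::force_tz(as.POSIXct(date), lubridate::tz(tt)))
  } else {
    date <- as.Date(as.POSIXct(as.numeric(tt), origin = "1970-01-01", tz = "UTC"))
    sod <- as.numeric(tt) %% 86400
  }
  work <- traces |>
    mutate(.date = date, .sod = sod) |>
    group_by(.data$patient_id, .data$.date) |>
    group_split()
  out <- purrr::map_dfr(work, function(day) {
    wins <- build_epochs(day$.date[1], schedule)
    trace <- tibble(t = day$.sod, ax = day$ax, ay = day$ay, az = day$az)
    purrr::map_dfr(seq_len(nrow(wins)), function(i) {
      w <- wins[i, ]
      sc <- compute_activity_score(trace, w, scoring)
      if (sc$no_data) return(NULL)
      wn <- detect_worn(trace, w, wear)
      tibble(
        patient_id = day$patient_id[1],
        date = day$.date[1],
        period = w$period,
        activity_score = sc$activity_score,
        worn = wn$worn,
        worn_fraction = wn$worn_fraction
      )
    })
  })
  if (nrow(out) == 0) {
    out <- tibble(
      patient_id = character(), date = as.Date(character()), period = integer(),
      activity_score = double(), worn = logical(), worn_fraction = double()
    )
  }
  out
}
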