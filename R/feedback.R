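#' Comparable previous watch day
#'
#' Goals are set from the same period on the preceding watch weekday: for
#' Tuesday--Friday that is the previous calendar day, and Friday's scores
#' carry over the weekend to set Monday's goals. The intervention runs
#' Monday to Friday, so weekend dates are rejected.
#'
#' @param date A weekday `Date` (vectorised).
#' @return The preceding comparable watch day as a `Date`.
#' @examples
#' comparable_previous_day(as.Date("2015-11-16")) # Monday -> preceding Friday
#' @export
comparable_previous_day <- function(date) {
  date <- as.Date(date)
  wd <- wday1(date)
  if (any(wd > 5)) abort("weekend dates have no comparable previous watch day")
  date - ifelse(wd == 1, 3, 1)
}

#' Adaptive activity goal: 5% above the comparable previous-day score
#'
#' @param prev_epoch_score Activity score of the comparable epoch on the
#'   preceding watch day (non-negative, vectorised).
#' @param rate Goal multiplier; default 1.05 (a 5% increase).
#' @return The goal in AS units.
#' @examples
#' set_goal(100) # 105
#' @export
set_goal <- function(prev_epoch_score, rate = 1.05) {
  if (any(is.na(prev_epoch_score)) || any(prev_epoch_score < 0)) {
    abort("`prev_epoch_score` must be non-negative")
  }
  rate * prev_epoch_score
}

#' Four-bar feedback level for progress towards a goal
#'
#' The watch face shows four progressive bars: bar 1 (red) is the default
#' for little or no activity, and bars 2, 3 and 4 light at completion of
#' 1/3 (orange), 2/3 (yellow) and the whole (green) of the activity goal.
#' Thresholds are inclusive, and a zero goal is treated as already met
#' (level 4).
#'
#' @param cumulative_score Cumulative within-period AS (non-negative,
#'   vectorised).
#' @param goal Period goal in AS units (non-negative, recycled).
#' @return Integer bar level 1--4.
#' @examples
#' bar_state(c(0, 100, 200, 300), 300) # 1 2 3 4
#' @export
bar_state <- function(cumulative_score, goal) {
  if (any(is.na(cumulative_score)) || any(cumulative_score < 0)) {
    abort("`cumulative_score` must be non-negative")
  }
  if (any(is.na(goal)) || any(goal < 0)) abort("`goal` must be non-negative")
  n <- max(length(cumulative_score), length(goal))
  s <- rep_len(cumulative_score, n)
  g <- rep_len(goal, n)
  lvl <- ifelse(
    g == 0, 4L,
    1L + (s >= g / 3) + (s >= 2 * g / 3) + (s >= g)
  )
  as.integer(lvl)
}

#' @rdname bar_state
#' @details `replay_bar_levels()` replays the display over a cumulative
#'   within-period score series (as the watch recomputes the state at every
#'   ingested sample) and returns the bar level at each point; levels never
#'   decrease within a period.
#' @export
replay_bar_levels <- function(cumulative_score, goal) {
  bar_state(cummax(cumulative_score), goal)
}

#' Goal-fallback configuration
#'
#' When the comparable previous-day epoch is missing (watch not worn, data
#' file lost), the goal falls back to the most recent recorded same-period
#' score, then to the baseline (day 1) score, then to `default_goal`.
#'
#' @param rate Daily goal multiplier (default 1.05).
#' @param default_goal Goal used when a patient has no recorded score at all
#'   for a period, in AS units.
#' @return A configuration list.
#' @export
goal_config <- function(rate = 1.05, default_goal = 0) {
  if (rate <= 0) abort("`rate` must be positive")
  if (default_goal < 0) abort("`default_goal` must be >= 0")
  structure(list(rate = rate, default_goal = default_goal), class = "swaft_goal_config")
}

# goal + provenance for one (patient, period) on `date`, given that
# patient's epoch records strictly before `date`
resolve_goal <- function(history, period, date, config) {
  h <- history[history$period == period & history$date < date, , drop = FALSE]
  if (nrow(h) == 0) {
    return(list(goal = config$default_goal, source = "default"))
  }
  comp <- comparable_previous_day(date)
  hit <- h[h$date == comp, , drop = FALSE]
  if (nrow(hit) == 1) {
    return(list(goal = config$rate * hit$activity_score, source = "comparable_day"))
  }
  # most recent recorded same-period score, falling back to baseline
  last <- h[which.max(h$date), , drop = FALSE]
  src <- if (last$date == min(h$date)) "baseline" else "last_recorded"
  list(goal = config$rate * last$activity_score, source = src)
}

#' Run one intervention day for one patient
#'
#' Emits the feedback timeline for each scheduled period and the goals that
#' today's recorded scores set for the next watch day. On the first
#' intervention day no patient in any arm receives feedback (the day is the
#' baseline measure per period); in control mode the display carries the
#' clock icon only and never a bar level.
#'
#' @param epochs Epoch records for one patient (columns `patient_id`,
#'   `date`, `period`, `activity_score`), covering days up to and including
#'   `date`.
#' @param date The intervention day to run (weekday).
#' @param mode `"feedback"` or `"control"`.
#' @param intervention_start The patient's first watch day (baseline day).
#' @param config A [goal_config()].
#' @return A list with `timeline` (one row per period: `patient_id`, `date`,
#'   `period`, `period_icon`, `mode`, `bar_level` (`NA` whenever no feedback
#'   is shown), `goal`, `goal_source`, `score`) and `next_goals` (per-period
#'   goals for the following watch day with provenance).
#' @export
run_intervention_day <- function(epochs, date, mode = c("feedback", "control"),
                                 intervention_start, config = goal_config()) {
  mode <- match.arg(mode)
  assert_columns(epochs, c("patient_id", "date", "period", "activity_score"), "epochs")
  date <- as.Date(date)
  intervention_start <- as.Date(intervention_start)
  if (date < intervention_start) abort("`date` precedes the intervention start")
  if (!is_weekday(date)) abort("intervention days run Monday to Friday")
  pid <- if (nrow(epochs) > 0) epochs$patient_id[1] else NA_character_
  periods <- seq_along(epoch_schedule()$durations)
  today <- epochs[epochs$date == date, , drop = FALSE]
  baseline_day <- date == intervention_start

  timeline <- purrr::map_dfr(periods, function(p) {
    res <- resolve_goal(epochs, p, date, config)
    score <- today$activity_score[today$period == p]
    score <- if (length(score) == 1) score else NA_real_
    show_bar <- mode == "feedback" && !baseline_day
    tibble(
      patient_id = pid, date = date, period = p, period_icon = p, mode = mode,
      bar_level = if (show_bar && !is.na(score)) bar_state(score, res$goal) else NA_integer_,
      goal = if (baseline_day) NA_real_ else res$goal,
      goal_source = if (baseline_day) NA_character_ else res$source,
      score = score
    )
  })

  next_day <- date + if (wday1(date) == 5) 3 else 1
  next_goals <- purrr::map_dfr(periods, function(p) {
    res <- resolve_goal(epochs, p, next_day, config)
    tibble(
      patient_id = pid, date = next_day, period = p,
      goal = res$goal, goal_source = res$source
    )
  })
  list(timeline = timeline, next_goals = next_goals)
}

#' Feedback timeline across a cohort
#'
#' Replays [run_intervention_day()] over every recorded watch weekday of
#' every patient in the registry, in the patient's allocated mode
#' (feedback arm shows bars from day 2; observation and no-feedback arms
#' are control displays).
#'
#' @param epochs Epoch records (`patient_id`, `date`, `period`,
#'   `activity_score`).
#' @param registry Registry tibble with `id`, `group`, `intervention_start`.
#' @param config A [goal_config()].
#' @return Timeline tibble, one row per patient-day-period.
#' @export
feedback_timeline <- function(epochs, registry, config = goal_config()) {
  assert_columns(registry, c("id", "group", "intervention_start"), "registry")
  assert_columns(epochs, c("patient_id", "date", "period", "activity_score"), "epochs")
  purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    pid <- registry$id[i]
    mode <- if (registry$group[i] == "feedback") "feedback" else "control"
    pe <- epochs[epochs$patient_id == pid, , drop = FALSE]
    days <- sort(unique(pe$date[is_weekday(pe$date)]))
    purrr::map_dfr(days, function(d) {
      run_intervention_day(
        pe[pe$date <= d, , drop = FALSE], d, mode,
        registry$intervention_start[i], config
      )$timeline
    })
  })
}
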