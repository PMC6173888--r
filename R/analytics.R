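ANALYSIS_PERIODS <- 1:4 # period 5 varies with battery life and is excluded

# per-patient trial window: first watch day to discharge when recorded,
# otherwise to the last day with smartwatch data (length of stay estimated
# from the watch when discharge dates are missing)
trial_windows <- function(registry, epochs) {
  assert_columns(registry, c("id", "group", "intervention_start"), "registry")
  last_rec <- if (nrow(epochs) > 0) {
    epochs |>
      group_by(id = .data$patient_id) |>
      summarise(last_recorded = max(.data$date), .groups = "drop")
  } else {
    tibble(id = character(), last_recorded = as.Date(character()))
  }
  registry |>
    left_join(last_rec, by = "id") |>
    mutate(
      trial_start = as.Date(.data$intervention_start),
      trial_end = as.Date(if ("discharge_date" %in% names(registry)) {
        coalesce(as.Date(.data$discharge_date), .data$last_recorded)
      } else {
        .data$last_recorded
      }),
      trial_end = pmax(.data$trial_end, .data$trial_start, na.rm = TRUE)
    ) |>
    select("id", "group", "trial_start", "trial_end")
}

#' Daily total activity score (periods 1--4)
#'
#' Sums the activity score over periods 1 to 4 (08:00--16:00) for every
#' recorded patient-day; period 5 is excluded from analysis because its
#' duration varies with battery life. Days where only period 5 was
#' recorded carry an `NA` total and are flagged missing; days with some of
#' periods 1--4 missing are flagged partial.
#'
#' @param epochs Epoch records (`patient_id`, `date`, `period`,
#'   `activity_score`).
#' @return Tibble: `patient_id`, `date`, `daily_as`, `n_periods` (of
#'   periods 1--4 present), `partial`, `missing_day`.
#' @export
daily_total <- function(epochs) {
  assert_columns(epochs, c("patient_id", "date", "period", "activity_score"), "epochs")
  epochs |>
    group_by(.data$patient_id, .data$date) |>
    summarise(
      daily_as = if (any(.data$period %in% ANALYSIS_PERIODS)) {
        sum(.data$activity_score[.data$period %in% ANALYSIS_PERIODS])
      } else {
        NA_real_
      },
      n_periods = sum(.data$period %in% ANALYSIS_PERIODS),
      .groups = "drop"
    ) |>
    mutate(
      partial = .data$n_periods > 0 & .data$n_periods < length(ANALYSIS_PERIODS),
      missing_day = .data$n_periods == 0
    )
}

#' Baseline exceedance for one patient
#'
#' A day exceeds baseline when its daily total AS is strictly greater than
#' the total recorded on the baseline day (day 1 of the intervention). The
#' baseline day itself can therefore never count as exceeding.
#'
#' @param daily Daily totals for one patient (from [daily_total()]).
#' @param baseline_date The patient's first intervention day; defaults to
#'   the earliest recorded day.
#' @return One-row tibble `n_exceeding`, `n_days` (post-baseline recorded
#'   days). Both `NA`, with a warning, when the baseline day is missing.
#' @export
exceedance <- function(daily, baseline_date = NULL) {
  assert_columns(daily, c("date", "daily_as"), "daily")
  rec <- daily[!is.na(daily$daily_as), , drop = FALSE]
  baseline_date <- as.Date(baseline_date %||% suppressWarnings(min(rec$date)))
  base <- rec$daily_as[rec$date == baseline_date]
  if (length(base) != 1) {
    warn("baseline day missing; patient excluded from exceedance")
    return(tibble(n_exceeding = NA_integer_, n_days = NA_integer_))
  }
  post <- rec[rec$date > baseline_date, , drop = FALSE]
  tibble(
    n_exceeding = sum(post$daily_as > base),
    n_days = nrow(post)
  )
}

#' Percentage columns for exceedance counts
#'
#' Adds the two printed rates to a per-group count table: days exceeding
#' baseline as a percentage of expected days (weekdays spanned by each
#' patient's intervention) and of actual days (days with recorded data;
#' weekend recording can push actual above expected).
#'
#' @param counts Tibble with `expected_days`, `actual_days`,
#'   `days_exceeding` (and any id columns, carried through).
#' @return The input with `rate_vs_expected` and `rate_vs_actual` (percent,
#'   1 decimal).
#' @export
exceedance_rates <- function(counts) {
  assert_columns(counts, c("expected_days", "actual_days", "days_exceeding"), "counts")
  counts |>
    mutate(
      rate_vs_expected = pct(.data$days_exceeding, .data$expected_days),
      rate_vs_actual = pct(.data$days_exceeding, .data$actual_days)
    )
}

#' Per-group baseline-exceedance table
#'
#' @param epochs Epoch records.
#' @param registry Registry with `id`, `group`, `intervention_start` (and
#'   optionally `discharge_date`).
#' @return One row per group: `expected_days`, `actual_days`,
#'   `days_exceeding`, `rate_vs_expected`, `rate_vs_actual`.
#' @export
exceedance_table <- function(epochs, registry) {
  daily <- daily_total(epochs)
  wins <- trial_windows(registry, epochs)
  per_patient <- purrr::map_dfr(seq_len(nrow(wins)), function(i) {
    w <- wins[i, ]
    d <- daily[daily$patient_id == w$id & !is.na(daily$daily_as), , drop = FALSE]
    ex <- if (nrow(d) > 0) {
      suppressWarnings(exceedance(d, baseline_date = w$trial_start))
    } else {
      tibble(n_exceeding = NA_integer_, n_days = NA_integer_)
    }
    tibble(
      id = w$id, group = w$group, no_baseline = is.na(ex$n_exceeding),
      expected_days = n_weekdays_between(w$trial_start, w$trial_end),
      actual_days = nrow(d),
      days_exceeding = coalesce(ex$n_exceeding, 0L)
    )
  })
  if (any(per_patient$no_baseline)) {
    warn(sprintf(
      "%d patient(s) without a recorded baseline day excluded from the exceedance numerator",
      sum(per_patient$no_baseline)
    ))
  }
  per_patient$no_baseline <- NULL
  per_patient |>
    group_by(.data$group) |>
    summarise(across(c("expected_days", "actual_days", "days_exceeding"), sum), .groups = "drop") |>
    exceedance_rates()
}

#' Percentage columns for adherence counts
#'
#' The printed adherence table mixes two percentage bases; both are
#' computed: days in each worn-period category divided by the expected
#' weekday count (`*_pct_weekday`) and by the recorded-day count
#' (`*_pct_recorded`). Because weekends add recorded days beyond the
#' weekday denominator, the >= 1 period rate on the weekday base can exceed
#' 100%.
#'
#' @param counts Tibble with `weekdays`, `recorded_days` and `days_4` ..
#'   `days_1` (days worn for exactly that many of periods 1--4).
#' @return The input plus `days_ge1` and percentage columns on both bases
#'   (1 decimal).
#' @export
adherence_percentages <- function(counts) {
  assert_columns(
    counts,
    c("weekdays", "recorded_days", "days_4", "days_3", "days_2", "days_1"),
    "counts"
  )
  out <- counts |> mutate(days_ge1 = .data$days_4 + .data$days_3 + .data$days_2 + .data$days_1)
  for (cat in c("4", "3", "2", "1", "ge1")) {
    col <- paste0("days_", cat)
    out[[paste0("pct_", cat, "_weekday")]] <- pct(out[[col]], out$weekdays)
    out[[paste0("pct_", cat, "_recorded")]] <- pct(out[[col]], out$recorded_days)
  }
  out
}

#' Per-group smartwatch wear adherence table
#'
#' Classifies every recorded day by the number of periods 1--4 in which the
#' watch was worn and tabulates per group the total elapsed trial days, the
#' expected weekdays, the recorded days, and the counts and percentages per
#' worn-period category.
#'
#' @inheritParams exceedance_table
#' @return One row per group with counts and both percentage bases (see
#'   [adherence_percentages()]).
#' @export
adherence_table <- function(epochs, registry) {
  assert_columns(epochs, c("patient_id", "date", "period", "worn"), "epochs")
  wins <- trial_windows(registry, epochs)
  day_cat <- epochs |>
    filter(.data$period %in% ANALYSIS_PERIODS) |>
    group_by(id = .data$patient_id, .data$date) |>
    summarise(worn_periods = sum(.data$worn), .groups = "drop")
  recorded <- epochs |>
    distinct(id = .data$patient_id, .data$date)
  per_patient <- purrr::map_dfr(seq_len(nrow(wins)), function(i) {
    w <- wins[i, ]
    cats <- day_cat$worn_periods[day_cat$id == w$id]
    tibble(
      group = w$group,
      total_days = as.integer(w$trial_end - w$trial_start) + 1L,
      weekdays = n_weekdays_between(w$trial_start, w$trial_end),
      recorded_days = sum(recorded$id == w$id),
      days_4 = sum(cats == 4), days_3 = sum(cats == 3),
      days_2 = sum(cats == 2), days_1 = sum(cats == 1)
    )
  })
  if (nrow(per_patient) == 0 || nrow(epochs) == 0) {
    per_patient <- tibble(
      group = unique(registry$group), total_days = 0L, weekdays = 0L,
      recorded_days = 0L, days_4 = 0L, days_3 = 0L, days_2 = 0L, days_1 = 0L
    )
  }
  per_patient |>
    group_by(.data$group) |>
    summarise(across(everything(), sum), .groups = "drop") |>
    adherence_percentages()
}

#' Trial flow rates
#'
#' Recruitment, retention and follow-up percentages from the participant
#' flow counts, rounded to integer percent. Zero denominators yield 0
#' rather than an error.
#'
#' @param counts Named list, one-row data frame or named vector with
#'   `admitted`, `recruited`, `valid`, `completed_discharge`,
#'   `completed_followup`.
#' @return One-row tibble: `recruitment_pct` (recruited / admitted),
#'   `retention_discharge_pct` (completed discharge / valid),
#'   `retention_followup_pct` (completed follow-up / valid),
#'   `followup_among_discharged_pct` (completed follow-up / completed
#'   discharge).
#' @examples
#' flow_rates(list(
#'   admitted = 470, recruited = 51, valid = 50,
#'   completed_discharge = 39, completed_followup = 24
#' ))
#' @export
flow_rates <- function(counts) {
  counts <- as.list(counts)
  need <- c("admitted", "recruited", "valid", "completed_discharge", "completed_followup")
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0) {
    abort(paste0("counts is missing: ", paste(missing, collapse = ", ")))
  }
  with(counts, {
    if (recruited > admitted || valid > recruited ||
        completed_discharge > valid || completed_followup > completed_discharge) {
      abort("flow counts violate admitted >= recruited >= valid >= discharge >= follow-up")
    }
    tibble(
      recruitment_pct = pct(recruited, admitted, 0),
      retention_discharge_pct = pct(completed_discharge, valid, 0),
      retention_followup_pct = pct(completed_followup, valid, 0),
      followup_among_discharged_pct = pct(completed_followup, completed_discharge, 0)
    )
  })
}

#' Outcome-measure sets assessed at each timepoint
#'
#' Five performance-based measures and five self-report measures are
#' assessed at baseline and discharge; three self-report measures are
#' re-assessed by telephone at 3 months post-discharge.
#'
#' @return Tibble `set`, `measure`, `timepoint`.
#' @export
measure_sets <- function() {
  bind_rows(
    tidyr::expand_grid(
      set = "performance",
      measure = c("grip_left", "grip_right", "walk_10m", "moca", "barthel"),
      timepoint = c("baseline", "discharge")
    ),
    tidyr::expand_grid(
      set = "self_report",
      measure = c("fss", "vaf_s", "eq5d5l", "rmi", "whodas"),
      timepoint = c("baseline", "discharge")
    ),
    tidyr::expand_grid(
      set = "followup",
      measure = c("rmi", "whodas", "eq5d5l"),
      timepoint = "followup_3m"
    )
  )
}

#' Assessment completion table
#'
#' For each group, timepoint and measure set: the number of patients who
#' completed every measure in the set, and the range (min--max percent of
#' the group) of per-measure completion. A patient with no record for a
#' measure counts as not having completed it.
#'
#' @param assessments Tibble `patient_id`, `timepoint`, `measure`,
#'   `completed` (logical).
#' @param registry Registry with `id`, `group`.
#' @param sets Measure-set definition, default [measure_sets()].
#' @return Tibble `group`, `timepoint`, `set`, `n_group`, `n_full`,
#'   `completion_min_pct`, `completion_max_pct`.
#' @export
completion_table <- function(assessments, registry, sets = measure_sets()) {
  assert_columns(assessments, c("patient_id", "timepoint", "measure", "completed"), "assessments")
  assert_columns(registry, c("id", "group"), "registry")
  grid <- tidyr::expand_grid(
    registry |> select(patient_id = "id", "group"),
    sets
  )
  full <- grid |>
    left_join(assessments, by = c("patient_id", "timepoint", "measure")) |>
    mutate(completed = coalesce(.data$completed, FALSE))
  per_measure <- full |>
    group_by(.data$group, .data$timepoint, .data$set, .data$measure) |>
    summarise(pct_complete = pct(sum(.data$completed), n()), .groups = "drop")
  per_patient <- full |>
    group_by(.data$group, .data$timepoint, .data$set, .data$patient_id) |>
    summarise(all_complete = all(.data$completed), .groups = "drop")
  per_patient |>
    group_by(.data$group, .data$timepoint, .data$set) |>
    summarise(
      n_group = n(), n_full = sum(.data$all_complete),
      .groups = "drop"
    ) |>
    left_join(
      per_measure |>
        group_by(.data$group, .data$timepoint, .data$set) |>
        summarise(
          completion_min_pct = min(.data$pct_complete),
          completion_max_pct = max(.data$pct_complete),
          .groups = "drop"
        ),
      by = c("group", "timepoint", "set")
    )
}

#' Activity summary per group and intervention day
#'
#' Median and quartiles (inclusive linear-interpolation rule) of the daily
#' total AS at selected weekday indices of the intervention (day 1 = first
#' watch day; weekends excluded from indexing).
#'
#' @inheritParams exceedance_table
#' @param day_indices Weekday indices to summarise.
#' @return Tibble `group`, `day_index`, `median`, `q1`, `q3`, `n`.
#' @export
activity_summary <- function(epochs, registry, day_indices = c(1, 5, 10, 15)) {
  daily <- daily_total(epochs)
  wins <- trial_windows(registry, epochs)
  indexed <- purrr::map_dfr(seq_len(nrow(wins)), function(i) {
    w <- wins[i, ]
    wd <- weekdays_between(w$trial_start, w$trial_end + 28) # index beyond window is never requested
    d <- daily[daily$patient_id == w$id & !is.na(daily$daily_as), , drop = FALSE]
    d$day_index <- match(d$date, wd)
    d$group <- w$group
    d[!is.na(d$day_index), , drop = FALSE]
  })
  tidyr::expand_grid(group = unique(registry$group), day_index = day_indices) |>
    left_join(indexed, by = c("group", "day_index")) |>
    group_by(.data$group, .data$day_index) |>
    summarise(
      median = if (all(is.na(.data$daily_as))) NA_real_ else stats::median(.data$daily_as, na.rm = TRUE),
      q1 = if (all(is.na(.data$daily_as))) NA_real_ else unname(stats::quantile(.data$daily_as, 0.25, na.rm = TRUE, type = 7)),
      q3 = if (all(is.na(.data$daily_as))) NA_real_ else unname(stats::quantile(.data$daily_as, 0.75, na.rm = TRUE, type = 7)),
      n = sum(!is.na(.data$daily_as)),
      .groups = "drop"
    )
}

#' Per-period activity deltas from baseline and from the previous day
#'
#' For each patient and period 1--4, the difference between the day's AS
#' and the baseline (day 1) AS, and between the day's AS and the comparable
#' previous watch day's AS (Friday precedes Monday). Missing days propagate
#' as `NA`.
#'
#' @inheritParams exceedance_table
#' @return Tibble `patient_id`, `group`, `period`, `date`, `day_index`,
#'   `as`, `delta_bas`, `delta_prev`.
#' @export
delta_metrics <- function(epochs, registry) {
  assert_columns(epochs, c("patient_id", "date", "period", "activity_score"), "epochs")
  wins <- trial_windows(registry, epochs)
  purrr::map_dfr(seq_len(nrow(wins)), function(i) {
    w <- wins[i, ]
    wd <- weekdays_between(w$trial_start, w$trial_end)
    if (length(wd) == 0) return(NULL)
    pe <- epochs[epochs$patient_id == w$id & epochs$period %in% ANALYSIS_PERIODS, , drop = FALSE]
    tidyr::expand_grid(date = wd, period = ANALYSIS_PERIODS) |>
      left_join(
        pe |> select("date", "period", as = "activity_score"),
        by = c("date", "period")
      ) |>
      group_by(.data$period) |>
      arrange(.data$date, .by_group = TRUE) |>
      mutate(
        patient_id = w$id, group = w$group,
        day_index = match(.data$date, wd),
        delta_bas = .data$as - .data$as[1],
        delta_prev = .data$as - lag(.data$as)
      ) |>
      ungroup() |>
      select(
        "patient_id", "group", "period", "date", "day_index",
        "as", "delta_bas", "delta_prev"
      )
  })
}

#' Combined feasibility report
#'
#' Bundles every feasibility metric the trial design calls for: participant
#' flow and rates, wear adherence, baseline exceedance, assessment
#' completion and activity summaries.
#'
#' @param epochs Epoch records.
#' @param registry Registry tibble.
#' @param assessments Assessment completion records.
#' @param n_admitted Total ward admissions over the recruitment window
#'   (denominator of the recruitment rate).
#' @param day_indices Day indices for the activity summary.
#' @return A `swaft_feasibility` object (list of tibbles) with [print()],
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()]
#'   methods.
#' @export
feasibility_report <- function(epochs, registry, assessments, n_admitted,
                               day_indices = c(1, 5, 10, 15)) {
  assert_columns(registry, c("id", "group", "valid"), "registry")
  discharge_done <- assessments |>
    filter(.data$timepoint == "discharge", .data$completed) |>
    distinct(.data$patient_id)
  followup_done <- assessments |>
    filter(.data$timepoint == "followup_3m", .data$completed) |>
    distinct(.data$patient_id)
  valid_ids <- registry$id[registry$valid]
  counts <- list(
    admitted = n_admitted,
    recruited = nrow(registry),
    valid = length(valid_ids),
    completed_discharge = sum(discharge_done$patient_id %in% valid_ids),
    completed_followup = sum(followup_done$patient_id %in% valid_ids)
  )
  counts$dropouts_post_baseline <- counts$valid - counts$completed_discharge
  structure(
    list(
      flow_counts = as_tibble(counts),
      flow_rates = flow_rates(counts[1:5]),
      adherence = adherence_table(epochs, registry),
      exceedance = exceedance_table(epochs, registry),
      completion = completion_table(assessments, registry),
      activity = activity_summary(epochs, registry, day_indices)
    ),
    class = "swaft_feasibility"
  )
}
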