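#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
print.swaft_feasibility <- function(x, ...) {
  cat("Trial feasibility report\n\n")
  cat("Participant flow:\n")
  print(x$flow_counts)
  cat("\nFlow rates (%):\n")
  print(x$flow_rates)
  cat("\nSmartwatch wear adherence:\n")
  print(x$adherence |> select("group", "weekdays", "recorded_days",
                              "days_4", "pct_4_weekday", "pct_4_recorded"))
  cat("\nBaseline exceedance:\n")
  print(x$exceedance)
  cat("\nActivity summary (daily AS, periods 1-4):\n")
  print(x$activity)
  invisible(x)
}

#' Tidy a feasibility report into one long metric table
#'
#' @param x A `swaft_feasibility` object.
#' @param ... Unused.
#' @return Tibble `metric`, `group`, `value` covering flow rates, per-group
#'   all-period adherence (both bases) and exceedance rates.
#' @export
tidy.swaft_feasibility <- function(x, ...) {
  bind_rows(
    x$flow_rates |>
      tidyr::pivot_longer(everything(), names_to = "metric") |>
      mutate(group = "all"),
    x$adherence |>
      select("group", pct_4_weekday = "pct_4_weekday", pct_4_recorded = "pct_4_recorded",
             pct_ge1_weekday = "pct_ge1_weekday") |>
      tidyr::pivot_longer(-"group", names_to = "metric"),
    x$exceedance |>
      select("group", "rate_vs_expected", "rate_vs_actual") |>
      tidyr::pivot_longer(-"group", names_to = "metric")
  ) |>
    select("metric", "group", "value")
}

#' One-row summary of a feasibility report
#'
#' @inheritParams tidy.swaft_feasibility
#' @return One-row tibble with the headline rates: recruitment, retention
#'   at discharge and follow-up, pooled all-period adherence (%), and the
#'   exceedance-rate difference between feedback and no-feedback arms
#'   (percentage points, `NA` when either arm is absent).
#' @export
glance.swaft_feasibility <- function(x, ...) {
  adh <- x$adherence
  rct <- adh[adh$group %in% c("feedback", "no_feedback"), , drop = FALSE]
  pooled_adherence <- if (nrow(rct) > 0) {
    pct(sum(rct$days_4), sum(rct$weekdays), 0)
  } else {
    NA_real_
  }
  exc <- x$exceedance
  fb <- exc$rate_vs_expected[exc$group == "feedback"]
  nf <- exc$rate_vs_expected[exc$group == "no_feedback"]
  bind_cols(
    x$flow_rates,
    tibble(
      rct_adherence_pct = pooled_adherence,
      exceedance_arm_diff_pp = if (length(fb) == 1 && length(nf) == 1) fb - nf else NA_real_
    )
  )
}

#' Plot the per-group activity summary
#'
#' Median daily AS with an interquartile ribbon per group across
#' intervention day indices.
#'
#' @param summary Output of [activity_summary()].
#' @return A ggplot object.
#' @export
plot_activity_summary <- function(summary) {
  assert_columns(summary, c("group", "day_index", "median", "q1", "q3"), "summary")
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$day_index, y = .data$median,
                                        colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Intervention day (weekdays)", y = "Daily activity score (P1-P4)",
                  colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}

#' Plot per-period activity deltas for one patient
#'
#' Differences of AS from the baseline day and from the comparable previous
#' day, per 2-h period, across the intervention.
#'
#' @param deltas Output of [delta_metrics()].
#' @param patient Patient id to plot.
#' @return A ggplot object.
#' @export
plot_delta_metrics <- function(deltas, patient) {
  d <- deltas |>
    filter(.data$patient_id == patient) |>
    tidyr::pivot_longer(c("delta_bas", "delta_prev"),
                        names_to = "reference", values_to = "delta") |>
    mutate(reference = dplyr::recode(.data$reference,
                                     delta_bas = "vs baseline",
                                     delta_prev = "vs previous day"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day_index, y = .data$delta,
                                  colour = factor(.data$period))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::facet_wrap(~reference, scales = "free_y") +
    ggplot2::labs(x = "Intervention day (weekdays)", y = "AS difference",
                  colour = "Period") +
    ggplot2::theme_minimal()
}

#' @rdname plot_activity_summary
#' @param object A `swaft_feasibility` object.
#' @param ... Unused.
#' @export
autoplot.swaft_feasibility <- function(object, ...) {
  plot_activity_summary(object$activity)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
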