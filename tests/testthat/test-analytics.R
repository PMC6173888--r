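mon <- as.Date("2015-11-16")

test_that("daily totals sum periods 1-4 only and flag partial/missing days", {
  ep <- tibble::tibble(
    patient_id = "P1", date = mon, period = 1:5,
    activity_score = c(10, 20, 30, 40, 99), worn = TRUE, worn_fraction = 1
  )
  d <- daily_total(ep)
  expect_equal(d$daily_as, 100)
  expect_false(d$partial)
  partial <- daily_total(ep[ep$period %in% 1:2, ])
  expect_equal(partial$daily_as, 30)
  expect_true(partial$partial)
  p5only <- daily_total(ep[ep$period == 5, ])
  expect_true(is.na(p5only$daily_as))
  expect_true(p5only$missing_day)
})

test_that("exceedance counts strictly-greater post-baseline days", {
  d <- tibble::tibble(
    patient_id = "P1", date = mon + 0:3,
    daily_as = c(100, 120, 90, 101)
  )
  ex <- exceedance(d)
  expect_equal(ex$n_exceeding, 2)
  expect_equal(ex$n_days, 3)
  flat <- d |> dplyr::mutate(daily_as = 100)
  expect_equal(exceedance(flat)$n_exceeding, 0)
  expect_warning(
    out <- exceedance(d[-1, ], baseline_date = mon),
    "baseline"
  )
  expect_true(is.na(out$n_exceeding))
})

test_that("group exceedance rates use both expected and actual denominators", {
  reg <- make_registry("P1", "feedback", start = mon, discharge = mon + 4)
  # weekdays Mon-Fri (5 expected); record Mon-Thu plus Saturday (5 actual)
  ep <- make_epochs("P1", c(mon + 0:3, mon + 5), c(25, 25, 25, 25))
  ep$activity_score <- rep(c(25, 30, 20, 30, 30), each = 4) # totals 100,120,80,120,120
  tab <- exceedance_table(ep, reg)
  expect_equal(tab$expected_days, 5)
  expect_equal(tab$actual_days, 5)
  expect_equal(tab$days_exceeding, 3)
  expect_equal(tab$rate_vs_expected, 60)
  expect_equal(tab$rate_vs_actual, 60)
  expect_true(tab$days_exceeding <= tab$actual_days)
})

test_that("adherence classifies each recorded day into exactly one category", {
  reg <- make_registry("P1", "observation", start = mon, discharge = mon + 4)
  worn_by_day <- list(c(T, T, T, T), c(T, T, T, F), c(F, F, T, T), c(T, F, F, F), c(F, F, F, F))
  ep <- purrr::map_dfr(seq_along(worn_by_day), function(i) {
    e <- make_epochs("P1", mon + i - 1, c(10, 10, 10, 10))
    e$worn <- worn_by_day[[i]]
    e
  })
  tab <- adherence_table(ep, reg)
  expect_equal(tab$weekdays, 5)
  expect_equal(tab$recorded_days, 5)
  expect_equal(c(tab$days_4, tab$days_3, tab$days_2, tab$days_1), c(1, 1, 1, 1))
  expect_equal(tab$days_ge1, 4) # the zero-worn day is recorded but uncategorised
  expect_equal(tab$pct_4_weekday, 20)
  # category counts sum to the >=1 count; each day lands in exactly one category
  orc <- oracle_adherence_categories(ep)
  expect_equal(sum(orc[c("4", "3", "2", "1")]), tab$days_ge1)
  expect_equal(sum(orc), tab$recorded_days)
})

test_that("empty record sets produce an all-zero adherence table", {
  reg <- make_registry("P1", "observation", start = mon)
  ep <- make_epochs("P1", mon, c(1, 1, 1, 1))[0, ]
  tab <- adherence_table(ep, reg)
  expect_equal(tab$recorded_days, 0)
  expect_equal(tab$days_4 + tab$days_3 + tab$days_2 + tab$days_1, 0)
  expect_equal(tab$pct_ge1_weekday, 0)
})

test_that("weekend recording can push >=1-period rates above 100%", {
  reg <- make_registry("P1", "feedback", start = mon, discharge = mon + 4)
  days <- c(mon + 0:4, mon + 5, mon + 6) # five weekdays + both weekend days
  ep <- make_epochs("P1", days, c(10, 10, 10, 10))
  tab <- adherence_table(ep, reg)
  expect_equal(tab$weekdays, 5)
  expect_equal(tab$recorded_days, 7)
  expect_gt(tab$pct_ge1_weekday, 100)
  expect_equal(tab$pct_ge1_recorded, 100)
  # only the weekday-based >=1 ratio may exceed 100
  expect_true(all(c(tab$pct_4_recorded, tab$pct_3_recorded,
                    tab$pct_2_recorded, tab$pct_1_recorded) <= 100))
})

test_that("flow rates divide the documented numerators and denominators", {
  fr <- flow_rates(list(
    admitted = 470, recruited = 51, valid = 50,
    completed_discharge = 39, completed_followup = 24
  ))
  expect_equal(fr$recruitment_pct, 11)
  expect_equal(fr$retention_discharge_pct, 78)
  expect_equal(fr$retention_followup_pct, 48)
  expect_equal(fr$followup_among_discharged_pct, 62)
  zero <- flow_rates(list(
    admitted = 100, recruited = 0, valid = 0,
    completed_discharge = 0, completed_followup = 0
  ))
  expect_equal(zero$recruitment_pct, 0)
  expect_equal(zero$retention_discharge_pct, 0)
  expect_error(
    flow_rates(list(admitted = 10, recruited = 20, valid = 10,
                    completed_discharge = 5, completed_followup = 2)),
    "violate"
  )
})

test_that("completion table counts full completers and per-measure ranges", {
  reg <- make_registry(c("P1", "P2"), c("feedback", "feedback"), start = mon)
  sets <- measure_sets()
  full <- tidyr::expand_grid(
    patient_id = c("P1", "P2"),
    sets |> dplyr::distinct(timepoint, measure)
  ) |>
    dplyr::mutate(completed = TRUE)
  tab <- completion_table(full, reg)
  expect_true(all(tab$n_full == 2))
  expect_true(all(tab$completion_min_pct == 100 & tab$completion_max_pct == 100))
  # one patient missing one measure decrements that set's full count by one
  miss <- full |>
    dplyr::mutate(completed = !(patient_id == "P2" & timepoint == "baseline" & measure == "moca"))
  tab2 <- completion_table(miss, reg)
  perf_base <- tab2[tab2$set == "performance" & tab2$timepoint == "baseline", ]
  expect_equal(perf_base$n_full, 1)
  expect_equal(perf_base$completion_min_pct, 50)
  expect_equal(perf_base$completion_max_pct, 100)
  # untouched sets unaffected
  expect_equal(tab2$n_full[tab2$set == "followup"], 2)
})

test_that("activity summaries follow the inclusive quantile rule", {
  reg <- make_registry(c("P1", "P2", "P3"), rep("observation", 3), start = mon)
  ep <- purrr::map_dfr(c("P1", "P2", "P3"), function(id) {
    make_epochs(id, mon, rep(c(P1 = 10, P2 = 20, P3 = 40)[[id]] / 4, 4) * c(1, 1, 1, 1))
  })
  s <- activity_summary(ep, reg, day_indices = 1)
  expect_equal(s$n, 3)
  expect_equal(s$median, 20)
  expect_equal(s$q1, oracle_quantile(c(10, 20, 40), 0.25))
  expect_equal(s$q3, oracle_quantile(c(10, 20, 40), 0.75))
  # constant totals collapse all quartiles; single patient reports itself
  solo <- activity_summary(make_epochs("P1", mon, rep(12.5, 4)),
                           make_registry("P1", "observation", start = mon),
                           day_indices = 1)
  expect_equal(c(solo$median, solo$q1, solo$q3, solo$n), c(50, 50, 50, 1))
})

test_that("delta metrics subtract baseline and the comparable previous day", {
  reg <- make_registry("P1", "feedback", start = mon, discharge = mon + 8)
  days <- c(mon + 0:4, mon + 7) # Mon-Fri then next Monday
  scores <- c(100, 110, 105, 120, 130, 125)
  ep <- purrr::map_dfr(seq_along(days), function(i) {
    make_epochs("P1", days[i], rep(scores[i], 4))
  })
  d <- delta_metrics(ep, reg)
  p1 <- d[d$period == 1 & !is.na(d$as), ]
  expect_equal(p1$delta_bas, scores - 100)
  # next Monday's previous day is Friday (weekday indexing skips the weekend)
  expect_equal(p1$delta_prev, c(NA, diff(scores)))
  expect_equal(p1$day_index, 1:6)
  # flat scores give all-zero deltas from day 2
  flat <- purrr::map_dfr(days, function(dd) make_epochs("P2", dd, rep(50, 4)))
  reg2 <- make_registry("P2", "feedback", start = mon, discharge = mon + 8)
  d2 <- delta_metrics(flat, reg2)
  expect_true(all(d2$delta_bas[!is.na(d2$delta_bas)] == 0))
  expect_true(all(d2$delta_prev[!is.na(d2$delta_prev)] == 0))
  # unrecorded weekdays propagate as missing, not zero
  expect_true(anyNA(d2$as))
})

test_that("feasibility report bundles consistent flow counts and rates", {
  sim <- simulate_cohort(sim_config(seed = 5, n_admitted = 120))
  rep <- suppressWarnings(feasibility_report(sim$epochs, sim$registry, sim$assessments,
                                           n_admitted = sim$n_admitted))
  fc <- rep$flow_counts
  expect_true(fc$recruited <= fc$admitted)
  expect_true(fc$completed_followup <= fc$completed_discharge)
  expect_true(fc$completed_discharge <= fc$valid)
  expect_true(fc$valid <= fc$recruited)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(glance(rep)), 1)
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  expect_s3_class(plot_delta_metrics(delta_metrics(sim$epochs, sim$registry),
                                     sim$registry$id[1]), "ggplot")
})
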