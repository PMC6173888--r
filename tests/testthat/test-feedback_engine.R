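test_that("comparable previous day walks back one weekday, Friday before Monday", {
  expect_equal(comparable_previous_day(as.Date("2015-11-16")), as.Date("2015-11-13")) # Mon -> Fri
  expect_equal(comparable_previous_day(as.Date("2015-11-18")), as.Date("2015-11-17")) # Wed -> Tue
  expect_equal(comparable_previous_day(as.Date("2015-11-17")), as.Date("2015-11-16")) # Tue -> Mon
  expect_error(comparable_previous_day(as.Date("2015-11-15")), "weekend")
})

test_that("the goal is a 5% increase on the comparable epoch score", {
  expect_equal(set_goal(100), 105)
  expect_equal(set_goal(0), 0)
  expect_equal(set_goal(172), 180.6)
  expect_error(set_goal(-1), "non-negative")
})

test_that("bar levels sit at thirds of the goal with inclusive thresholds", {
  expect_equal(bar_state(0, 300), 1L)
  expect_equal(bar_state(c(100, 200, 300), 300), c(2L, 3L, 4L))
  expect_equal(bar_state(299.9, 300), 3L)
  expect_equal(bar_state(0, 0), 4L) # zero goal counts as met
  expect_error(bar_state(-1, 10), "non-negative")
  expect_error(bar_state(1, -10), "non-negative")
})

test_that("bar_state is monotone and replay never lets the display drop", {
  withr::with_seed(21, {
    for (i in 1:25) {
      goal <- stats::runif(1, 0, 400)
      s <- sort(stats::runif(50, 0, 500))
      lv <- bar_state(s, goal)
      expect_true(all(diff(lv) >= 0))
      # replay over an arbitrary (non-monotone) cumulative stream
      stream <- cumsum(stats::runif(50, 0, 20))
      expect_true(all(diff(replay_bar_levels(stream, goal)) >= 0))
    }
  })
  # documented transition placement on a cumulative trace vs previous score 200
  goal <- set_goal(200) # 210
  stream <- c(0, 69, 70, 139, 140, 209, 210, 400)
  expect_equal(replay_bar_levels(stream, goal), c(1, 1, 2, 2, 3, 3, 4, 4))
})

test_that("day 1 emits no feedback in any mode and control mode never shows bars", {
  d1 <- as.Date("2015-11-16")
  ep <- make_epochs("P1", d1, c(100, 90, 80, 70))
  for (mode in c("feedback", "control")) {
    out <- run_intervention_day(ep, d1, mode, intervention_start = d1)
    expect_true(all(is.na(out$timeline$bar_level)))
    expect_equal(out$timeline$period_icon, 1:5)
    # goals for day 2 initialised to 1.05 x day-1 scores
    expect_equal(out$next_goals$goal[1:4], 1.05 * c(100, 90, 80, 70))
    expect_equal(unique(out$next_goals$date), d1 + 1)
  }
  # control mode on a later day still shows the clock only
  ep2 <- dplyr::bind_rows(ep, make_epochs("P1", d1 + 1, c(120, 95, 85, 60)))
  out2 <- run_intervention_day(ep2, d1 + 1, "control", intervention_start = d1)
  expect_true(all(is.na(out2$timeline$bar_level)))
})

test_that("feedback-mode bars follow the 5% goal against the previous day", {
  d1 <- as.Date("2015-11-16")
  ep <- dplyr::bind_rows(
    make_epochs("P1", d1, c(100, 100, 100, 100)),
    make_epochs("P1", d1 + 1, c(104, 105, 36, 0)) # goal 105 each period
  )
  out <- run_intervention_day(ep, d1 + 1, "feedback", intervention_start = d1)
  tl <- out$timeline[out$timeline$period %in% 1:4, ]
  expect_equal(tl$goal, rep(105, 4))
  expect_equal(tl$goal_source, rep("comparable_day", 4))
  expect_equal(tl$bar_level, c(3L, 4L, 2L, 1L)) # 104<105, 105>=105, 36>=35, 0<35
})

test_that("missing comparable epochs fall back with provenance flags", {
  mon <- as.Date("2015-11-16")
  ep <- dplyr::bind_rows(
    make_epochs("P1", mon, c(100, 100, 100, 100)), # baseline Monday
    make_epochs("P1", mon + 1, c(200, 200, 200, 200)) # Tuesday
  )
  # Thursday: Wednesday missing -> most recent recorded (Tuesday)
  out <- run_intervention_day(ep, mon + 3, "feedback", intervention_start = mon)
  expect_equal(out$timeline$goal_source[1], "last_recorded")
  expect_equal(out$timeline$goal[1], 1.05 * 200)
  # patient with only the baseline recorded -> baseline fallback
  ep_b <- make_epochs("P2", mon, c(50, 50, 50, 50))
  out_b <- run_intervention_day(ep_b, mon + 3, "feedback", intervention_start = mon)
  expect_equal(out_b$timeline$goal_source[1], "baseline")
  expect_equal(out_b$timeline$goal[1], 1.05 * 50)
  # no history at all -> configured default goal
  none <- ep_b[0, ]
  out_n <- run_intervention_day(none, mon + 1, "feedback", mon,
                                config = goal_config(default_goal = 42))
  expect_equal(out_n$timeline$goal_source[1], "default")
  expect_equal(out_n$timeline$goal[1], 42)
  # weekend runs are rejected
  expect_error(run_intervention_day(ep, mon + 5, "feedback", mon), "Monday to Friday")
})

test_that("goal ratchet: exact 5% daily growth ends every period at bar 4", {
  d1 <- as.Date("2015-11-16")
  days <- d1 + 0:4 # Mon-Fri
  grow <- purrr::map_dfr(seq_along(days), function(i) {
    make_epochs("P1", days[i], rep(100 * 1.05^(i - 1), 4))
  })
  slow <- purrr::map_dfr(seq_along(days), function(i) {
    make_epochs("P2", days[i], rep(100 * 1.03^(i - 1), 4))
  })
  for (d in days[-1]) {
    tl <- run_intervention_day(grow, as.Date(d, origin = "1970-01-01"), "feedback", d1)$timeline
    expect_true(all(tl$bar_level[tl$period %in% 1:4] == 4L))
    tl2 <- run_intervention_day(slow, as.Date(d, origin = "1970-01-01"), "feedback", d1)$timeline
    expect_true(all(tl2$bar_level[tl2$period %in% 1:4] < 4L))
  }
})

test_that("cohort timelines keep modes separated in serialised output", {
  d1 <- as.Date("2015-11-16")
  reg <- make_registry(c("F1", "C1"), c("feedback", "no_feedback"), start = d1)
  ep <- dplyr::bind_rows(
    make_epochs("F1", d1 + 0:2, c(100, 100, 100, 100)),
    make_epochs("C1", d1 + 0:2, c(100, 100, 100, 100))
  )
  tl <- feedback_timeline(ep, reg)
  expect_true(all(is.na(tl$bar_level[tl$mode == "control"])))
  expect_true(any(!is.na(tl$bar_level[tl$mode == "feedback"])))
  # Friday's scores set Monday's goals
  fri <- as.Date("2015-11-20")
  ep_w <- make_epochs("F1", c(d1 + 0:4), c(100, 100, 100, 100))
  mon2 <- run_intervention_day(ep_w, fri + 3, "feedback", d1)
  expect_equal(mon2$timeline$goal_source[1], "comparable_day")
  expect_equal(mon2$timeline$goal[1], 105)
})
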