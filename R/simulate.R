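#' Simulation configuration for a synthetic trial cohort
#'
#' Defaults emulate the conditions of a single-site inpatient feasibility
#' deployment: roughly one admission in nine recruited (eligibility 0.20 x
#' consent 0.55), a 40/60 observation/RCT phase mix, a length of stay
#' around two and a half weeks, heavily right-skewed inter-patient activity
#' levels (lognormal), high weekday recording with occasional weekend
#' records, a 22% post-baseline dropout before the discharge assessment and
#' telephone contact with 62% of discharged patients at 3 months.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_admitted Ward admissions to simulate.
#' @param eligibility_prob,consent_prob Probability an admission is
#'   eligible, and that an eligible patient consents.
#' @param phase_mix Named fractions of recruits entering each phase
#'   (`observation`, `rct`); assigned in registration order.
#' @param mean_los_days,los_dispersion Mean and lognormal sigma of days
#'   from intervention start to discharge.
#' @param baseline_activity_log_mean,baseline_activity_log_sd Lognormal
#'   parameters of the per-patient per-period activity level (AS units).
#' @param epoch_noise_log_sd Lognormal sigma of per-epoch noise.
#' @param daily_trend Multiplicative day-on-day drift of activity
#'   (1 = flat).
#' @param feedback_effect Multiplicative uplift of post-baseline activity
#'   in the feedback arm (0 = null).
#' @param wear_prob Probability each scheduled period of a recorded day is
#'   worn.
#' @param record_prob,weekend_record_prob Probability a watch weekday /
#'   weekend day yields a data file.
#' @param dropout_prob_discharge Probability a valid patient drops out
#'   after the baseline assessment (no discharge assessment).
#' @param contact_prob_followup Probability a discharged-assessed patient
#'   is reached at the 3-month telephone follow-up.
#' @param measure_completion_prob Probability an assessed patient completes
#'   any given measure at an attended timepoint.
#' @param max_watch_days,max_elapsed_days Intervention cap: watch days
#'   (weekdays) and elapsed calendar days.
#' @param start_date First possible admission date (a trial calendar
#'   anchor); admissions spread over `recruitment_weeks` weeks.
#' @param recruitment_weeks Length of the recruitment window.
#' @return A `swaft_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_admitted = 470,
                       eligibility_prob = 0.20,
                       consent_prob = 0.55,
                       phase_mix = c(observation = 0.4, rct = 0.6),
                       mean_los_days = 17.5,
                       los_dispersion = 0.45,
                       baseline_activity_log_mean = log(120),
                       baseline_activity_log_sd = 0.6,
                       epoch_noise_log_sd = 0.3,
                       daily_trend = 1.0,
                       feedback_effect = 0.1,
                       wear_prob = 0.85,
                       record_prob = 0.97,
                       weekend_record_prob = 0.3,
                       dropout_prob_discharge = 0.22,
                       contact_prob_followup = 0.62,
                       measure_completion_prob = 0.9,
                       max_watch_days = 15,
                       max_elapsed_days = 21,
                       start_date = as.Date("2015-09-21"),
                       recruitment_weeks = 30) {
  probs <- c(
    eligibility_prob, consent_prob, wear_prob, record_prob, weekend_record_prob,
    dropout_prob_discharge, contact_prob_followup, measure_completion_prob, phase_mix
  )
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (abs(sum(phase_mix) - 1) > 1e-8) abort("`phase_mix` must sum to 1")
  if (los_dispersion <= 0 || baseline_activity_log_sd < 0 || epoch_noise_log_sd < 0) {
    abort("dispersion parameters must be positive")
  }
  if (feedback_effect < 0) abort("`feedback_effect` must be >= 0")
  structure(as.list(environment()), class = "swaft_sim_config")
}

# next weekday on or after a date
next_weekday <- function(date) {
  add <- c(0, 0, 0, 0, 0, 2, 1)[wday1(date)]
  date + add
}

#' Simulate a synthetic trial cohort
#'
#' Generates a full synthetic trial: screened admissions, registration with
#' phase assignment and concealed 1:1 randomisation in the RCT phase,
#' per-patient per-day per-period activity scores with wear gaps, weekend
#' recording and dropout, assessment-completion records and a watch
#' distribution/download log. The intervention runs Monday--Friday for up
#' to `max_watch_days` watch days within `max_elapsed_days` elapsed days,
#' or until discharge if sooner. Output is byte-reproducible given the
#' seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional override of `cfg$seed`.
#' @return A list of tibbles: `registry`, `epochs`, `assessments`,
#'   `watch_log`, plus `n_admitted` (scalar) for the recruitment
#'   denominator.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = NULL) {
  if (!inherits(cfg, "swaft_sim_config")) abort("`cfg` must come from sim_config()")
  seed <- as.integer(seed %||% cfg$seed)
  withr::with_seed(seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_admitted
  admission_date <- cfg$start_date + sort(sample.int(cfg$recruitment_weeks * 7, n, replace = TRUE)) - 1

  eligible <- stats::rbinom(n, 1, cfg$eligibility_prob) == 1
  consented <- eligible & stats::rbinom(n, 1, cfg$consent_prob) == 1
  recruited_idx <- which(consented)
  n_rec <- length(recruited_idx)

  ids <- sprintf("P%04d", seq_len(n_rec))
  n_obs <- round(cfg$phase_mix[["observation"]] * n_rec)
  phase <- c(rep("observation", n_obs), rep("rct", n_rec - n_obs))
  group <- rep("observation", n_rec)
  if (n_rec > n_obs) {
    rct_ids <- ids[phase == "rct"]
    group[phase == "rct"] <- randomise(rct_ids, seed = sample.int(.Machine$integer.max, 1))$group
  }

  adm <- admission_date[recruited_idx]
  registration_date <- adm + pmax(0, round(stats::rgamma(n_rec, shape = 2, scale = 3)))
  intervention_start <- next_weekday(registration_date + 1)
  los <- pmax(2, round(stats::rlnorm(n_rec, log(cfg$mean_los_days), cfg$los_dispersion)))
  discharge_date <- intervention_start + los

  registry <- tibble(
    id = ids, phase = phase, group = group, valid = TRUE,
    age = round(pmin(75, pmax(40, stats::rnorm(n_rec, 58, 10)))),
    sex = sample(c("male", "female"), n_rec, replace = TRUE, prob = c(0.7, 0.3)),
    affected_side = sample(c("left", "right"), n_rec, replace = TRUE),
    stroke_date = adm - pmax(1, round(stats::rnorm(n_rec, 55, 30))),
    admission_date = adm,
    registration_date = registration_date,
    intervention_start = intervention_start,
    discharge_date = discharge_date
  )

  level <- stats::rlnorm(n_rec, cfg$baseline_activity_log_mean, cfg$baseline_activity_log_sd)

  epochs <- purrr::map_dfr(seq_len(n_rec), function(i) {
    start <- intervention_start[i]
    end <- min(discharge_date[i], start + cfg$max_elapsed_days - 1)
    days <- seq(start, end, by = "day")
    weekday <- is_weekday(days)
    watch_index <- cumsum(weekday)
    days <- days[watch_index <= cfg$max_watch_days]
    weekday <- weekday[seq_along(days)]
    rec_p <- ifelse(weekday, cfg$record_prob, cfg$weekend_record_prob)
    recorded <- stats::rbinom(length(days), 1, rec_p) == 1
    days <- days[recorded]
    if (length(days) == 0) return(NULL)
    wd_index <- cumsum(is_weekday(seq(start, end, by = "day")))[match(days, seq(start, end, by = "day"))]
    grid <- tidyr::expand_grid(date = days, period = 1:5)
    grid$day_index <- wd_index[match(grid$date, days)]
    uplift <- if (group[i] == "feedback") 1 + cfg$feedback_effect else 1
    grid |>
      mutate(
        worn = stats::rbinom(n(), 1, cfg$wear_prob) == 1,
        worn_fraction = ifelse(.data$worn, stats::runif(n(), 0.6, 1), stats::runif(n(), 0, 0.2)),
        eff = ifelse(.data$date > start, uplift, 1),
        period_scale = ifelse(.data$period == 5, 0.5, 1),
        activity_score = ifelse(
          .data$worn,
          level[i] * cfg$daily_trend^(.data$day_index - 1) * .data$eff * .data$period_scale *
            stats::rlnorm(n(), 0, cfg$epoch_noise_log_sd),
          0
        ),
        patient_id = ids[i]
      ) |>
      select("patient_id", "date", "period", "activity_score", "worn", "worn_fraction")
  })
  if (is.null(epochs) || nrow(epochs) == 0) {
    epochs <- tibble(
      patient_id = character(), date = as.Date(character()), period = integer(),
      activity_score = double(), worn = logical(), worn_fraction = double()
    )
  }

  # assessment attendance: baseline always attempted; discharge unless the
  # patient drops out post-baseline; follow-up only among discharge-assessed
  attended_discharge <- stats::rbinom(n_rec, 1, 1 - cfg$dropout_prob_discharge) == 1
  attended_followup <- attended_discharge & stats::rbinom(n_rec, 1, cfg$contact_prob_followup) == 1
  sets <- measure_sets()
  assessments <- purrr::map_dfr(seq_len(n_rec), function(i) {
    att <- c(
      baseline = TRUE,
      discharge = attended_discharge[i],
      followup_3m = attended_followup[i]
    )
    sets |>
      distinct(.data$timepoint, .data$measure) |>
      mutate(
        patient_id = ids[i],
        completed = unname(att[.data$timepoint]) &
          stats::rbinom(n(), 1, cfg$measure_completion_prob) == 1
      ) |>
      select("patient_id", "timepoint", "measure", "completed")
  })

  watch_log <- epochs |>
    distinct(.data$patient_id, .data$date) |>
    mutate(
      watch_id = paste0("W", match(.data$patient_id, ids)),
      action = "distributed", file_name = NA_character_
    ) |>
    bind_rows(
      epochs |>
        distinct(.data$patient_id, .data$date) |>
        mutate(
          watch_id = paste0("W", match(.data$patient_id, ids)),
          action = "downloaded",
          file_name = paste0(.data$patient_id, "_", format(.data$date, "%Y%m%d"), ".csv")
        )
    ) |>
    arrange(.data$patient_id, .data$date, .data$action) |>
    select("watch_id", "patient_id", "date", "action", "file_name")

  list(
    registry = registry, epochs = epochs, assessments = assessments,
    watch_log = watch_log, n_admitted = n
  )
}

#' Simulate an accelerometer trace achieving a target activity score
#'
#' Builds a uniformly sampled tri-axial trace over one epoch window whose
#' [compute_activity_score()] equals `level` (to well within 5%) and whose
#' non-worn stretches are zero-variance pure gravity. Movement is encoded
#' as alternating high/rest vector magnitudes around 1 g pointing in
#' seeded random 3-D directions, so wear detection always sees
#' super-threshold variance in worn stretches.
#'
#' @param level Target activity score (>= 0); 0 yields a stationary trace.
#' @param window One row of [build_epochs()].
#' @param worn_pattern `NULL` (worn throughout) or a data frame of
#'   `start`/`end` offsets in seconds from the window start during which
#'   the watch is worn.
#' @param seed Integer seed (movement directions).
#' @param fs Sampling rate, Hz.
#' @param scoring The [scoring_config()] the trace is built against.
#' @return Trace tibble `t` (seconds after midnight), `ax`, `ay`, `az`.
#' @export
simulate_accel_trace <- function(level, window, worn_pattern = NULL, seed = 1L,
                                 fs = 10, scoring = scoring_config()) {
  if (length(level) != 1 || is.na(level) || level < 0) abort("`level` must be a single value >= 0")
  b <- window_bounds(window)
  dur <- b[2] - b[1]
  n <- as.integer(dur * fs)
  t <- b[1] + (seq_len(n) - 1) / fs
  off <- t - b[1]

  worn <- rep(TRUE, n)
  if (!is.null(worn_pattern)) {
    assert_columns(worn_pattern, c("start", "end"), "worn_pattern")
    worn <- rep(FALSE, n)
    for (j in seq_len(nrow(worn_pattern))) {
      worn <- worn | (off >= worn_pattern$start[j] & off < worn_pattern$end[j])
    }
  }

  vm <- rep(1, n)
  if (level > 0 && any(worn)) {
    widx <- which(worn)
    hi <- widx[seq_along(widx) %% 2 == 1] # alternate movement / rest samples
    c_dev <- level * fs / length(hi)
    vm[hi] <- 1 + scoring$deadband_g + c_dev
  }

  withr::with_seed(as.integer(seed), {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
  })
  moving <- vm != 1
  ax <- ifelse(moving, vm * u[, 1], 0)
  ay <- ifelse(moving, vm * u[, 2], 0)
  az <- ifelse(moving, vm * u[, 3], 1)
  tibble(t = t, ax = ax, ay = ay, az = az)
}
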