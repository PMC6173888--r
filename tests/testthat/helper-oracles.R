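# Independent brute-force oracles: plain loops applying the documented
# definitions sample by sample / day by day, kept free of package internals.

oracle_score <- function(trace, start, end, deadband = 0.05) {
  keep <- trace$t >= start & trace$t < end
  t <- trace$t[keep]
  if (length(t) < 2) return(0)
  d <- sort(diff(t)) # median sampling interval, by sorting
  m <- length(d)
  dt <- if (m %% 2 == 1) d[(m + 1) / 2] else (d[m / 2] + d[m / 2 + 1]) / 2
  total <- 0
  for (i in seq_along(t)) {
    vm <- sqrt(trace$ax[keep][i]^2 + trace$ay[keep][i]^2 + trace$az[keep][i]^2)
    dev <- abs(vm - 1) - deadband
    if (dev > 0) total <- total + dev * dt
  }
  total
}

oracle_worn <- function(trace, start, end, sub = 60, threshold = 1e-4, min_frac = 0.25) {
  edges <- seq(start, end, by = sub)
  if (edges[length(edges)] < end) edges <- c(edges, end)
  n_active <- 0
  n_sub <- length(edges) - 1
  for (k in seq_len(n_sub)) {
    keep <- trace$t >= edges[k] & trace$t < edges[k + 1] & trace$t >= start & trace$t < end
    vm <- sqrt(trace$ax[keep]^2 + trace$ay[keep]^2 + trace$az[keep]^2)
    if (length(vm) >= 2) {
      mu <- sum(vm) / length(vm)
      v <- sum((vm - mu)^2) / (length(vm) - 1)
      if (v >= threshold) n_active <- n_active + 1
    }
  }
  frac <- n_active / n_sub
  list(worn = frac >= min_frac, worn_fraction = frac)
}

# day-by-day worn-period category count (periods 1-4)
oracle_adherence_categories <- function(epochs) {
  days <- unique(epochs[c("patient_id", "date")])
  out <- c("4" = 0, "3" = 0, "2" = 0, "1" = 0, "0" = 0)
  for (i in seq_len(nrow(days))) {
    rows <- epochs$patient_id == days$patient_id[i] & epochs$date == days$date[i] &
      epochs$period %in% 1:4
    k <- sum(epochs$worn[rows])
    out[as.character(k)] <- out[as.character(k)] + 1
  }
  out
}

# per-measure percentage scan and all-complete count for one group
oracle_completion <- function(assessments, ids, timepoint, measures) {
  per_measure <- numeric(length(measures))
  names(per_measure) <- measures
  for (m in measures) {
    done <- 0
    for (id in ids) {
      row <- assessments$patient_id == id & assessments$timepoint == timepoint &
        assessments$measure == m
      if (any(row) && any(assessments$completed[row])) done <- done + 1
    }
    per_measure[m] <- round(100 * done / length(ids), 1)
  }
  full <- 0
  for (id in ids) {
    ok <- TRUE
    for (m in measures) {
      row <- assessments$patient_id == id & assessments$timepoint == timepoint &
        assessments$measure == m
      if (!any(row) || !any(assessments$completed[row])) ok <- FALSE
    }
    if (ok) full <- full + 1
  }
  list(n_full = full, min_pct = min(per_measure), max_pct = max(per_measure))
}

# inclusive linear-interpolation quantile on a sorted list (closed form)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small random trace on a uniform grid with bursts of movement
random_trace <- function(start, end, fs = 5) {
  t <- start + seq(0, end - start - 1 / fs, by = 1 / fs)
  n <- length(t)
  burst <- stats::rbinom(n, 1, 0.3) == 1
  amp <- stats::runif(n, 0, 0.6) * burst
  tibble::tibble(
    t = t,
    ax = amp * stats::rnorm(n, 0, 0.5),
    ay = amp * stats::rnorm(n, 0, 0.5),
    az = 1 + amp * stats::rnorm(n, 0, 0.5)
  )
}

# compact registry + epoch-record fixture with fully known structure
make_registry <- function(ids, group, start = as.Date("2015-11-16"), discharge = start + 11) {
  tibble::tibble(
    id = ids, phase = ifelse(group == "observation", "observation", "rct"),
    group = group, valid = TRUE,
    intervention_start = start, discharge_date = discharge
  )
}

make_epochs <- function(id, dates, scores_by_period, worn = TRUE) {
  tidyr::expand_grid(date = dates, period = 1:4) |>
    dplyr::mutate(
      patient_id = id,
      activity_score = rep(scores_by_period, length.out = dplyr::n()),
      worn = worn, worn_fraction = ifelse(worn, 1, 0)
    ) |>
    dplyr::select(patient_id, date, period, activity_score, worn, worn_fraction)
}
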