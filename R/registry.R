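eligibility_fields <- c(
  "age", "days_since_stroke", "first_rehab_admission", "could_walk_10m_prestroke",
  "two_stage_command", "sufficient_cognition", "sufficient_vision", "can_consent"
)

#' Screen candidates against the trial inclusion criteria
#'
#' Inclusion is a pure conjunction of demographic criteria (aged 40--75,
#' stroke onset under 4 months, first rehabilitation admission, able to
#' walk 10 m unaided before the stroke) and performance-based criteria
#' (sufficient cognition, can follow a two-stage command, sufficient vision,
#' capacity to consent). A candidate failing only the two-stage command is
#' scheduled for a 3-day recheck rather than excluded. An optional logical
#' `override` column admits protocol deviations (recorded in
#' `deviation_reasons`) for the demographic criteria, mirroring deviation
#' reporting in deployed trials.
#'
#' @param candidates Data frame with an `id` column plus the screening
#'   fields `age`, `days_since_stroke`, `first_rehab_admission`,
#'   `could_walk_10m_prestroke`, `two_stage_command`,
#'   `sufficient_cognition`, `sufficient_vision`, `can_consent`.
#' @param max_days_since_stroke Operationalisation of "under 4 months", in
#'   days (default 122).
#' @return Tibble: `id`, `status` (`"eligible"`, `"ineligible"`,
#'   `"recheck_day3"`), `reasons` (failed criteria, `;`-separated, `""`
#'   when none) and `deviation_reasons` (criteria admitted via override).
#' @export
screen_eligibility <- function(candidates, max_days_since_stroke = 122) {
  assert_columns(candidates, c("id", eligibility_fields), "candidates")
  has_override <- "override" %in% names(candidates)
  purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    c_ <- candidates[i, ]
    fields <- unlist(c_[eligibility_fields])
    if (anyNA(fields)) {
      return(tibble(
        id = c_$id, status = "ineligible",
        reasons = "incomplete screen", deviation_reasons = ""
      ))
    }
    fails <- character()
    if (c_$age < 40 || c_$age > 75) fails <- c(fails, "age")
    if (c_$days_since_stroke >= max_days_since_stroke) fails <- c(fails, "stroke_onset")
    if (!c_$first_rehab_admission) fails <- c(fails, "first_admission")
    if (!c_$could_walk_10m_prestroke) fails <- c(fails, "prestroke_walking")
    if (!c_$sufficient_cognition) fails <- c(fails, "cognition")
    if (!c_$two_stage_command) fails <- c(fails, "two_stage_command")
    if (!c_$sufficient_vision) fails <- c(fails, "vision")
    if (!c_$can_consent) fails <- c(fails, "consent_capacity")

    deviations <- character()
    if (has_override && isTRUE(c_$override)) {
      deviations <- intersect(fails, c("age", "stroke_onset"))
      fails <- setdiff(fails, deviations)
    }
    status <- if (length(fails) == 0) {
      "eligible"
    } else if (identical(fails, "two_stage_command")) {
      "recheck_day3"
    } else {
      "ineligible"
    }
    tibble(
      id = c_$id, status = status,
      reasons = paste(fails, collapse = ";"),
      deviation_reasons = paste(deviations, collapse = ";")
    )
  })
}

#' Concealed 1:1 randomisation
#'
#' Generates the concealed allocation sequence from the seed and consumes it
#' in registration order, so the allocation of the k-th patient is fixed
#' before any patient is seen and independent of later registrations
#' (regenerating a longer sequence from the same seed leaves earlier
#' assignments unchanged). Simple randomisation is the default; permuted
#' blocks guarantee balance within each block.
#'
#' @param ids Unique patient identifiers, in registration order.
#' @param seed Integer seed fixing the concealed sequence.
#' @param method `"simple"` (independent fair draws) or `"block"`
#'   (permuted blocks).
#' @param block_size Even block size for `method = "block"`.
#' @return Tibble `id`, `group` (`"feedback"`/`"no_feedback"`).
#' @export
randomise <- function(ids, seed, method = c("simple", "block"), block_size = 2) {
  method <- match.arg(method)
  if (anyDuplicated(ids)) abort("`ids` must be unique")
  n <- length(ids)
  if (n == 0) return(tibble(id = character(), group = character()))
  seq_groups <- allocation_sequence(seed, n, method, block_size)
  tibble(id = ids, group = seq_groups[seq_len(n)])
}

# concealed sequence of length >= n, deterministic in seed; prefixes are
# stable as n grows (sequential RNG stream / whole blocks)
allocation_sequence <- function(seed, n, method = "simple", block_size = 2) {
  arms <- c("feedback", "no_feedback")
  withr::with_seed(seed, {
    if (method == "simple") {
      arms[stats::rbinom(n, 1, 0.5) + 1]
    } else {
      if (block_size %% 2 != 0 || block_size < 2) abort("`block_size` must be even")
      n_blocks <- ceiling(n / block_size)
      unlist(lapply(seq_len(n_blocks), function(b) {
        sample(rep(arms, each = block_size / 2))
      }))
    }
  })
}

#' Register screened candidates onto the trial
#'
#' Observation-phase patients are assigned `group = "observation"` without
#' randomisation; pilot-RCT patients draw the next concealed allocation in
#' registration order. Registering an ineligible candidate is an error
#' unless `force = TRUE`, in which case the record is created but flagged
#' `valid = FALSE` (an accidental registration that must be excludable from
#' the valid cohort post hoc).
#'
#' @param candidates Data frame of screening fields (see
#'   [screen_eligibility()]); date columns (`stroke_date`,
#'   `admission_date`, `registration_date`, `intervention_start`,
#'   `discharge_date`) and demographics (`sex`, `affected_side`) are carried
#'   through when present.
#' @param phase `"observation"` or `"rct"`.
#' @param seed Seed for the concealed allocation sequence (RCT phase).
#' @param method,block_size Passed to [randomise()].
#' @param force Register despite failed screening, flagging the record
#'   invalid.
#' @return Registry tibble: `id`, `phase`, `group`, `valid`, screening
#'   status, and any carried demographic/date columns.
#' @export
register_patients <- function(candidates, phase = c("observation", "rct"),
                              seed = 1L, method = "simple", block_size = 2,
                              force = FALSE) {
  phase <- match.arg(phase)
  screen <- screen_eligibility(candidates)
  registrable <- screen$status == "eligible"
  if (!force && any(!registrable)) {
    abort(sprintf(
      "cannot register ineligible candidate(s): %s",
      paste(screen$id[!registrable], collapse = ", ")
    ))
  }
  groups <- if (phase == "observation") {
    rep("observation", nrow(screen))
  } else {
    randomise(screen$id, seed, method, block_size)$group
  }
  extra <- intersect(
    c("sex", "affected_side", "age", "stroke_date", "admission_date",
      "registration_date", "intervention_start", "discharge_date"),
    names(candidates)
  )
  out <- tibble(
    id = screen$id, phase = phase, group = groups,
    valid = registrable, screen_status = screen$status,
    deviation_reasons = screen$deviation_reasons
  )
  bind_cols(out, as_tibble(candidates)[extra])
}
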