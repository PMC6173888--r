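dialects <- list(
  epochs = list(
    cols = c("patient_id", "date", "period", "activity_score", "worn", "worn_fraction"),
    types = readr::cols(
      patient_id = readr::col_character(), date = readr::col_date(),
      period = readr::col_integer(), activity_score = readr::col_double(),
      worn = readr::col_logical(), worn_fraction = readr::col_double(),
      .default = readr::col_guess()
    )
  ),
  trace = list(
    cols = c("t", "ax", "ay", "az"),
    types = readr::cols(
      t = readr::col_guess(), ax = readr::col_double(),
      ay = readr::col_double(), az = readr::col_double(),
      .default = readr::col_guess()
    )
  ),
  registry = list(
    cols = c("id", "phase", "group", "age", "sex", "affected_side", "stroke_date",
             "admission_date", "registration_date", "intervention_start", "discharge_date"),
    types = readr::cols(
      id = readr::col_character(), phase = readr::col_character(),
      group = readr::col_character(), age = readr::col_double(),
      sex = readr::col_character(), affected_side = readr::col_character(),
      stroke_date = readr::col_date(), admission_date = readr::col_date(),
      registration_date = readr::col_date(), intervention_start = readr::col_date(),
      discharge_date = readr::col_date(), .default = readr::col_guess()
    )
  ),
  assessments = list(
    cols = c("patient_id", "timepoint", "measure", "completed"),
    types = readr::cols(
      patient_id = readr::col_character(), timepoint = readr::col_character(),
      measure = readr::col_character(), completed = readr::col_logical(),
      .default = readr::col_guess()
    )
  ),
  watch_log = list(
    cols = c("watch_id", "patient_id", "date", "action", "file_name"),
    types = readr::cols(
      watch_id = readr::col_character(), patient_id = readr::col_character(),
      date = readr::col_date(), action = readr::col_character(),
      file_name = readr::col_character(), .default = readr::col_guess()
    )
  )
)

# bookkeeping columns written by in-package builders; accepted silently
known_extra <- list(
  registry = c("valid", "screen_status", "deviation_reasons"),
  epochs = character(), trace = "patient_id",
  assessments = character(), watch_log = character()
)

read_dialect <- function(path, dialect) {
  d <- dialects[[dialect]]
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(d$cols, header)
  if (length(missing) > 0) {
    abort(sprintf("%s file %s is missing column(s): %s",
                  dialect, path, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(header, c(d$cols, known_extra[[dialect]]))
  if (length(extra) > 0) {
    warn(sprintf("%s file %s has extra column(s), preserved: %s",
                 dialect, path, paste(extra, collapse = ", ")))
  }
  readr::read_csv(path, col_types = d$types, show_col_types = FALSE)
}

write_dialect <- function(x, path, dialect) {
  d <- dialects[[dialect]]
  assert_columns(x, d$cols, dialect)
  readr::write_csv(x, path)
  invisible(path)
}

#' Read and write the trial's CSV dialects
#'
#' One reader/writer pair per interchange format: per-epoch activity
#' records, raw accelerometer traces, the patient registry, assessment
#' completion records and the watch distribution log. Readers validate the
#' documented header (a missing column is an error naming the column),
#' tolerate and preserve extra columns with a warning, and round-trip all
#' fields losslessly with the writers. Dates are ISO-8601; trace
#' timestamps may be ISO-8601 datetimes or numeric epoch seconds.
#'
#' @param path File path.
#' @param x Tibble to write (must carry the dialect's columns).
#' @return Readers return a tibble; writers return the path invisibly.
#' @name swaft_io
NULL

#' @rdname swaft_io
#' @export
read_epochs <- function(path) read_dialect(path, "epochs")
#' @rdname swaft_io
#' @export
write_epochs <- function(x, path) write_dialect(x, path, "epochs")

#' @rdname swaft_io
#' @param patient_id Optional patient identifier attached to the trace.
#' @export
read_trace <- function(path, patient_id = NULL) {
  out <- read_dialect(path, "trace")
  if (!is.null(patient_id)) out$patient_id <- patient_id
  out
}
#' @rdname swaft_io
#' @export
write_trace <- function(x, path) write_dialect(x, path, "trace")

#' @rdname swaft_io
#' @export
read_registry <- function(path) read_dialect(path, "registry")
#' @rdname swaft_io
#' @export
write_registry <- function(x, path) {
  d <- dialects$registry
  # registries built in-package carry extra bookkeeping columns; dialect
  # columns are required, the rest are preserved
  assert_columns(x, intersect(d$cols, c("id", "phase", "group")), "registry")
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname swaft_io
#' @export
read_assessments <- function(path) read_dialect(path, "assessments")
#' @rdname swaft_io
#' @export
write_assessments <- function(x, path) write_dialect(x, path, "assessments")

#' @rdname swaft_io
#' @export
read_watch_log <- function(path) read_dialect(path, "watch_log")
#' @rdname swaft_io
#' @export
write_watch_log <- function(x, path) write_dialect(x, path, "watch_log")

#' File-level quality control of downloaded smartwatch data
#'
#' Reproduces the data-management checks of a daily-download deployment:
#' duplicate files (identical per patient-day payloads, a common artefact
#' of repeated daily downloads), mislabelled files (embedded patient id not
#' present in the registry) and unconsolidated patients (no single final
#' file spanning the whole intervention from start to last recorded day).
#' Unparseable files are listed in the report, never fatal.
#'
#' @param files Character vector of epoch-record CSV paths.
#' @param registry Registry tibble with `id` and `intervention_start`.
#' @return A `swaft_qc` list: `duplicate_groups` (tibble `payload_hash`,
#'   `files`), `mislabelled` (tibble `file`, `patient_id`),
#'   `unconsolidated` (tibble `patient_id`), `unparseable` (tibble `file`,
#'   `error`).
#' @export
qc_files <- function(files, registry) {
  assert_columns(registry, c("id", "intervention_start"), "registry")
  parsed <- purrr::map(files, function(f) {
    tryCatch(
      suppressWarnings(read_epochs(f)),
      error = function(e) conditionMessage(e)
    )
  })
  ok <- vapply(parsed, is.data.frame, logical(1))
  unparseable <- tibble(
    file = files[!ok],
    error = unlist(parsed[!ok], use.names = FALSE) %||% character()
  )

  payloads <- purrr::map2_dfr(files[ok], parsed[ok], function(f, df) {
    df <- df |> arrange(.data$patient_id, .data$date, .data$period)
    tibble(
      file = f,
      payload_hash = rlang::hash(df[dialects$epochs$cols]),
      patient_ids = list(unique(df$patient_id)),
      date_min = suppressWarnings(min(df$date)),
      date_max = suppressWarnings(max(df$date))
    )
  })

  duplicate_groups <- if (nrow(payloads) > 0) {
    payloads |>
      group_by(.data$payload_hash) |>
      filter(n() > 1) |>
      summarise(files = list(sort(.data$file)), .groups = "drop")
  } else {
    tibble(payload_hash = character(), files = list())
  }

  mislabelled <- if (nrow(payloads) > 0) {
    payloads |>
      select("file", "patient_ids") |>
      tidyr::unnest(cols = "patient_ids") |>
      rename(patient_id = "patient_ids") |>
      filter(!.data$patient_id %in% registry$id)
  } else {
    tibble(file = character(), patient_id = character())
  }

  # a patient is consolidated when one file alone spans start -> last day
  last_day <- payloads |>
    tidyr::unnest(cols = "patient_ids") |>
      rename(patient_id = "patient_ids") |>
    group_by(.data$patient_id) |>
    summarise(last = max(.data$date_max), .groups = "drop")
  unconsolidated <- purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    pid <- registry$id[i]
    span <- last_day$last[last_day$patient_id == pid]
    if (length(span) == 0) return(tibble(patient_id = pid)) # no data at all
    has_final <- payloads |>
      tidyr::unnest(cols = "patient_ids") |>
      rename(patient_id = "patient_ids") |>
      filter(
        .data$patient_id == pid,
        .data$date_min <= as.Date(registry$intervention_start[i]),
        .data$date_max >= span
      )
    if (nrow(has_final) == 0) tibble(patient_id = pid) else NULL
  })
  if (nrow(unconsolidated) == 0) unconsolidated <- tibble(patient_id = character())

  structure(
    list(
      duplicate_groups = duplicate_groups, mislabelled = mislabelled,
      unconsolidated = unconsolidated, unparseable = unparseable
    ),
    class = "swaft_qc"
  )
}

#' @export
print.swaft_qc <- function(x, ...) {
  cat("Smartwatch file QC report\n")
  cat(sprintf("  duplicate groups : %d\n", nrow(x$duplicate_groups)))
  cat(sprintf("  mislabelled files: %d\n", nrow(x$mislabelled)))
  cat(sprintf("  unconsolidated   : %d patient(s)\n", nrow(x$unconsolidated)))
  cat(sprintf("  unparseable files: %d\n", nrow(x$unparseable)))
  invisible(x)
}
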