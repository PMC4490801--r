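#' Default activity vocabulary
#'
#' The four interface activities logged by the game-like touch interface the
#' package was built around: `Sel` (select a tile), `S` (swap, a scoring
#' move), `R` (reswap, a failed move) and `W` (wiggle, the drag gesture that
#' reveals same-colored tiles). The order of this vector fixes the activity
#' block order of the symbol alphabet built by [fit_codebook()].
#'
#' @param select_code Code used for the bare selection activity.
#' @param wiggle_code Code for the wiggle activity, absent in static-interface
#'   sessions.
#' @return Character vector of activity codes with attributes `select` and
#'   `wiggle` naming the two special codes.
#' @export
#' @examples
#' wiggle_vocabulary()
wiggle_vocabulary <- function(select_code = "Sel", wiggle_code = "W") {
  out <- c(select_code, "S", "R", wiggle_code)
  attr(out, "select") <- select_code
  attr(out, "wiggle") <- wiggle_code
  out
}

select_code_of <- function(vocabulary) {
  attr(vocabulary, "select") %||% vocabulary[[1]]
}

wiggle_code_of <- function(vocabulary) {
  attr(vocabulary, "wiggle") %||% vocabulary[[length(vocabulary)]]
}

log_columns <- c("session_id", "subject_id", "interface", "instruction",
                 "timestamp", "activity")

#' Read a time-stamped activity log
#'
#' Reads a delimited text log with one interface event per row and validates
#' it as a set of sessions. Events are kept in file order; timestamps must be
#' non-decreasing within a session (no silent sorting), every activity code
#' must belong to `vocabulary`, and sessions recorded under a static
#' interface must not contain the wiggle code.
#'
#' @param path Path to a delimited text file with a header row and columns
#'   `session_id`, `subject_id`, `interface`, `instruction`, `timestamp`,
#'   `activity`.
#' @param delim Field delimiter (default comma).
#' @param timestamp_unit `"seconds"` (default) or `"milliseconds"`;
#'   millisecond inputs are converted to seconds.
#' @param vocabulary Allowed activity codes, see [wiggle_vocabulary()].
#' @return A tibble of events, one row per event, timestamps in seconds.
#' @export
read_activity_log <- function(path, delim = ",",
                              timestamp_unit = c("seconds", "milliseconds"),
                              vocabulary = wiggle_vocabulary()) {
  timestamp_unit <- match.arg(timestamp_unit)
  events <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      session_id = readr::col_character(),
      subject_id = readr::col_character(),
      interface = readr::col_character(),
      instruction = readr::col_character(),
      timestamp = readr::col_double(),
      activity = readr::col_character()
    )
  )
  missing_cols <- setdiff(log_columns, names(events))
  if (length(missing_cols) > 0) {
    cli::cli_abort("log file {.path {path}} is missing column{?s} {.field {missing_cols}}")
  }
  if (timestamp_unit == "milliseconds") {
    events$timestamp <- events$timestamp / 1000
  }
  validate_activity_log(events, vocabulary = vocabulary)
}

#' Validate an in-memory activity-log table
#'
#' Checks the session invariants used throughout the pipeline: known activity
#' codes, non-negative and within-session non-decreasing timestamps, and no
#' wiggle events in static-interface sessions. Useful when events were built
#' in code (e.g. by [simulate_ensemble()]) rather than read from disk.
#'
#' @param events Event tibble with the columns of [read_activity_log()].
#' @param vocabulary Allowed activity codes.
#' @return The validated events, invisibly unchanged, as a tibble.
#' @export
validate_activity_log <- function(events, vocabulary = wiggle_vocabulary()) {
  events <- tibble::as_tibble(events)
  bad <- which(!(events$activity %in% vocabulary))
  if (length(bad) > 0) {
    cli::cli_abort(c(
      "unknown activity code {.val {events$activity[bad[1]]}} at row {bad[1]}",
      "i" = "vocabulary is {.val {as.character(vocabulary)}}"
    ))
  }
  if (any(events$timestamp < 0)) {
    cli::cli_abort("timestamps must be non-negative")
  }
  decreasing <- events |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$session_id) |>
    dplyr::filter(.data$timestamp < dplyr::lag(.data$timestamp,
                                               default = -Inf)) |>
    dplyr::ungroup()
  if (nrow(decreasing) > 0) {
    cli::cli_abort(paste0(
      "timestamps decrease within session ",
      "{.val {decreasing$session_id[1]}} at row {decreasing$.row[1]}"
    ))
  }
  wiggle <- wiggle_code_of(vocabulary)
  offending <- events |>
    dplyr::filter(.data$interface == "static", .data$activity == wiggle)
  if (nrow(offending) > 0) {
    cli::cli_abort(paste0(
      "static-interface session {.val {offending$session_id[1]}} contains ",
      "{.val {wiggle}} events"
    ))
  }
  events
}

#' Collapse rapid select-then-act pairs
#'
#' A move in the logged interface is implemented as a selection followed by
#' the act itself, so a select event immediately followed by a swap, reswap
#' or wiggle within the recode window records intent, not a separate action.
#' This recode drops every select event whose immediate successor (within the
#' same session) is a non-select activity occurring within `window` seconds
#' (boundary inclusive), keeping the follower. The pass is left-to-right and
#' a consumed select cannot chain; a select followed by another select is
#' never collapsed.
#'
#' @param events Event tibble (see [read_activity_log()]).
#' @param window Collapse window in seconds, default 0.050.
#' @param vocabulary Activity codes; the select code is taken from its
#'   `select` attribute.
#' @return The events tibble with collapsed select events removed.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   session_id = "a", subject_id = "a", interface = "wiggle",
#'   instruction = "none", timestamp = c(0, 0.03, 0.2), activity = c("Sel", "W", "R")
#' )
#' recode_selections(ev)$activity
recode_selections <- function(events, window = 0.050,
                              vocabulary = wiggle_vocabulary()) {
  if (window < 0) {
    cli::cli_abort("recode window must be non-negative, got {window}")
  }
  sel <- select_code_of(vocabulary)
  followers <- setdiff(as.character(vocabulary), sel)
  events |>
    dplyr::group_by(.data$session_id) |>
    dplyr::mutate(
      .collapse = .data$activity == sel &
        dplyr::lead(.data$activity, default = "") %in% followers &
        (dplyr::lead(.data$timestamp, default = Inf) - .data$timestamp) <= window
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!.data$.collapse) |>
    dplyr::select(-".collapse")
}

#' Derive inter-event intervals
#'
#' Adds the continuous temporal feature used by the quantizer: for each
#' event, the time elapsed since the previous retained event of the same
#' session. The first event's interval is its own timestamp, i.e. the time
#' since the session start at zero.
#'
#' @param events Event tibble, normally after [recode_selections()].
#' @return The events tibble with a `delta` column (seconds).
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   session_id = "a", subject_id = "a", interface = "static",
#'   instruction = "none", timestamp = c(1, 1.5, 4), activity = c("Sel", "R", "S")
#' )
#' compute_intervals(ev)$delta
compute_intervals <- function(events) {
  if (nrow(events) == 0) {
    cli::cli_abort("cannot compute intervals for an empty event table")
  }
  events |>
    dplyr::group_by(.data$session_id) |>
    dplyr::mutate(delta = .data$timestamp -
                    dplyr::lag(.data$timestamp, default = 0)) |>
    dplyr::ungroup()
}

#' Per-session activity rate
#'
#' Number of retained events per minute of session time, where session time
#' is the span between the first and last event (making the rate invariant
#' to a constant timestamp offset).
#'
#' @param events Event tibble, normally after [recode_selections()].
#' @return Tibble with one row per session: `session_id`, `subject_id`,
#'   `n_events`, `duration_min`, `rate` (events per minute).
#' @export
activity_rate <- function(events) {
  if (nrow(events) == 0) {
    cli::cli_abort("cannot compute an activity rate for an empty event table")
  }
  out <- events |>
    dplyr::group_by(.data$session_id) |>
    dplyr::summarise(
      subject_id = dplyr::first(.data$subject_id),
      n_events = dplyr::n(),
      duration_min = (max(.data$timestamp) - min(.data$timestamp)) / 60,
      .groups = "drop"
    )
  if (any(out$duration_min <= 0)) {
    bad <- out$session_id[out$duration_min <= 0][1]
    cli::cli_abort("session {.val {bad}} has zero duration")
  }
  dplyr::mutate(out, rate = .data$n_events / .data$duration_min)
}
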