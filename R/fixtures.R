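#' Packaged reference tables
#'
#' Three small tables shipped with the package for fixture-based checks of
#' the derivative metrics, transcribed from the study the package's defaults
#' emulate:
#'
#' * `"table3"` — per-subject correctness of the self-reported game rule
#'   after session 2 (`correct` is `"Yes"`, `"No"`, or `NA` when the subject
#'   gave no report).
#' * `"table4"` — proportion of session time each of 20 subjects spent in
#'   each of 10 states, per session (wide; unvisited states are `NA`).
#' * `"table5"` — per-state excess kurtosis and max-average peakedness
#'   values of the activity-collapsed emission profiles; the classification
#'   thresholds are -1.2 (kurtosis) and the across-state mean of the
#'   max-average column.
#'
#' @param name One of `"table3"`, `"table4"`, `"table5"`.
#' @return A tibble.
#' @export
#' @examples
#' load_fixture("table5")
load_fixture <- function(name) {
  if (!name %in% c("table3", "table4", "table5")) {
    cli::cli_abort("unknown fixture {.val {name}}; available: table3, table4, table5")
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "bphmm",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Occupancy fixture in long form
#'
#' Reshapes the `"table4"` fixture into the long layout produced by
#' [state_occupancy()] (`NA` proportions become 0), ready for
#' [success_flags()] and [session_peakedness()].
#'
#' @return Tibble with `subject_id`, `session_id`, `interface`, `hint`,
#'   `state`, `proportion`.
#' @export
occupancy_fixture <- function() {
  load_fixture("table4") |>
    tidyr::pivot_longer(dplyr::starts_with("state_"), names_to = "state",
                        names_prefix = "state_", values_to = "proportion") |>
    dplyr::mutate(
      subject_id = as.character(.data$subject),
      session_id = paste0(.data$subject, "_s", .data$session),
      state = as.integer(.data$state),
      proportion = dplyr::coalesce(.data$proportion, 0)
    ) |>
    dplyr::select("subject_id", "session_id", "session", "interface",
                  "hint", "state", "proportion")
}
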