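#' Group fitted solutions by feature count
#'
#' Partitions a collection of fitted solutions (e.g. the output of a
#' hyperparameter grid) by the number of states each discovered.
#'
#' @param solutions A list of `bphmm_solution` objects or a [run_grid()]
#'   tibble with a `solution` list-column.
#' @return A tibble with one row per distinct feature count, ascending:
#'   `feature_count`, `n_models`, and the member solutions in the
#'   `solutions` list-column.
#' @export
group_by_feature_count <- function(solutions) {
  sols <- extract_solutions(solutions)
  if (length(sols) == 0) cli::cli_abort("no solutions to group")
  counts <- vapply(sols, n_states, integer(1))
  tibble::tibble(feature_count = counts, solution = sols) |>
    dplyr::group_by(.data$feature_count) |>
    dplyr::summarise(n_models = dplyr::n(),
                     solutions = list(.data$solution),
                     .groups = "drop") |>
    dplyr::arrange(.data$feature_count)
}

#' Pick the representative solution of a same-size group
#'
#' Pools the emission rows (M-dimensional categorical vectors) of every
#' group member, clusters them into `s` clusters by K-means with Euclidean
#' distance (where `s` is the shared feature count), and scores each member
#' by the summed distance of its rows to their assigned cluster centroids.
#' The member with the minimum total distance — the one whose emission
#' library sits closest to the group consensus — is the representative.
#' Ties go to the earlier member in input order.
#'
#' @param group_solutions List of `bphmm_solution` objects, all with the
#'   same number of states.
#' @param seed Integer seed for the K-means restarts.
#' @return A list: `index` of the chosen member, the chosen `solution`, and
#'   the numeric `total_distance` per member.
#' @export
select_representative <- function(group_solutions, seed = 1L) {
  sols <- extract_solutions(group_solutions)
  if (length(sols) == 0) cli::cli_abort("the group is empty")
  s <- n_states(sols[[1]])
  if (!all(vapply(sols, n_states, integer(1)) == s)) {
    cli::cli_abort("group members disagree on the number of states")
  }
  if (length(sols) == 1) {
    return(list(index = 1L, solution = sols[[1]], total_distance = 0))
  }

  rows <- do.call(rbind, lapply(sols, function(x) x$theta))
  member <- rep(seq_along(sols), each = s)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  n_distinct <- nrow(unique(rows))
  centers <- if (n_distinct <= s) {
    unique(rows)
  } else {
    stats::kmeans(rows, centers = s, nstart = 10, iter.max = 100)$centers
  }

  d2 <- outer(rowSums(rows^2), rep(1, nrow(centers))) -
    2 * rows %*% t(centers) +
    outer(rep(1, nrow(rows)), rowSums(centers^2))
  nearest <- sqrt(pmax(apply(d2, 1, min), 0))
  totals <- as.numeric(tapply(nearest, member, sum))
  list(index = which.min(totals), solution = sols[[which.min(totals)]],
       total_distance = totals)
}

#' Representatives for every feature-count group
#'
#' Convenience wrapper running [group_by_feature_count()] and
#' [select_representative()] over a grid of fitted solutions.
#'
#' @inheritParams group_by_feature_count
#' @param seed Integer seed passed to each group's K-means.
#' @return Tibble with `feature_count`, `n_models`, `representative_index`,
#'   per-member `total_distance` (list-column) and the chosen
#'   `representative` solution (list-column).
#' @export
select_representatives <- function(solutions, seed = 1L) {
  groups <- group_by_feature_count(solutions)
  picks <- purrr::map(groups$solutions, select_representative, seed = seed)
  groups |>
    dplyr::mutate(
      representative_index = purrr::map_int(picks, "index"),
      total_distance = purrr::map(picks, "total_distance"),
      representative = purrr::map(picks, "solution")
    ) |>
    dplyr::select(-"solutions")
}

extract_solutions <- function(solutions) {
  if (is.data.frame(solutions) && "solution" %in% names(solutions)) {
    return(solutions$solution)
  }
  if (inherits(solutions, "bphmm_solution")) return(list(solutions))
  as.list(solutions)
}
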