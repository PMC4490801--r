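#' Viterbi decoding of one sequence
#'
#' Most probable joint hidden path of sequence `i` under the fitted
#' parameters, restricted to the sequence's active features. Ties are broken
#' toward the lower state index.
#'
#' @param solution A `bphmm_solution`.
#' @param i Sequence index (position in `solution$sequence_ids`).
#' @return Integer vector of global state labels, one per event.
#' @export
viterbi_decode <- function(solution, i) {
  stopifnot(inherits(solution, "bphmm_solution"))
  act <- active_features(solution, i)
  E <- emission_probs(solution$seqs[[i]], solution$theta, act)
  act[viterbi_cpp(E, solution$trans[[i]], solution$pi0[[i]])]
}

#' Decode every sequence
#'
#' @param solution A `bphmm_solution`.
#' @return Tibble with `session_id`, `position`, `symbol` and the decoded
#'   `state` for every event of every sequence.
#' @export
decode_states <- function(solution) {
  stopifnot(inherits(solution, "bphmm_solution"))
  purrr::map2_dfr(seq_along(solution$seqs), solution$sequence_ids,
                  function(i, id) {
    tibble::tibble(
      session_id = id,
      position = seq_along(solution$seqs[[i]]),
      symbol = solution$seqs[[i]],
      state = viterbi_decode(solution, i)
    )
  })
}

#' Proportion of session time spent in each state
#'
#' Weights each decoded event by its inter-event interval, so the result is
#' the share of elapsed session time attributed to each state. States never
#' visited get 0.
#'
#' @param path Integer vector of decoded states.
#' @param deltas Inter-event intervals (seconds), same length as `path`.
#' @param n_states Number of global states (length of the output).
#' @param weight `"time"` (default) weights by `deltas`; `"events"` counts
#'   events instead.
#' @return Numeric proportions vector of length `n_states`, summing to 1.
#' @export
time_in_states <- function(path, deltas, n_states,
                           weight = c("time", "events")) {
  weight <- match.arg(weight)
  stopifnot(length(path) == length(deltas))
  w <- if (weight == "time") deltas else rep(1, length(path))
  total <- sum(w)
  if (total <= 0) cli::cli_abort("total session time is zero")
  out <- numeric(n_states)
  agg <- tapply(w, factor(path, levels = seq_len(n_states)), sum)
  out[as.integer(names(agg))] <- ifelse(is.na(agg), 0, agg)
  out / total
}

#' State occupancy table for a fitted ensemble
#'
#' Decodes every sequence and computes [time_in_states()] per session,
#' carrying subject and condition metadata when available in `data`.
#'
#' @param solution A `bphmm_solution`.
#' @param data Encoded event tibble (the same one passed to [run_mcmc()]),
#'   holding `session_id` and `delta` columns, and optionally `subject_id`,
#'   `interface`, `instruction`.
#' @param weight Passed to [time_in_states()].
#' @return Long tibble with one row per (session, state): `session_id`,
#'   metadata columns, `state`, `proportion`.
#' @export
state_occupancy <- function(solution, data, weight = c("time", "events")) {
  weight <- match.arg(weight)
  stopifnot(inherits(solution, "bphmm_solution"), "delta" %in% names(data))
  K <- n_states(solution)
  meta_cols <- intersect(c("subject_id", "interface", "instruction"),
                         names(data))
  meta <- dplyr::distinct(
    data[, c("session_id", meta_cols), drop = FALSE])
  rows <- purrr::map2_dfr(seq_along(solution$seqs), solution$sequence_ids,
                          function(i, id) {
    deltas <- data$delta[data$session_id == id]
    path <- viterbi_decode(solution, i)
    tibble::tibble(session_id = id, state = seq_len(K),
                   proportion = time_in_states(path, deltas, K,
                                               weight = weight))
  })
  dplyr::left_join(rows, meta, by = "session_id") |>
    dplyr::relocate("state", "proportion", .after = dplyr::last_col())
}

#' Count-normalized (categorical) emission distributions
#'
#' Converts a fitted solution's emission library from its sampled Dirichlet
#' parameterization to the categorical parameterization used for
#' interpretation: for each state, the symbols assigned to it by the
#' decoded state paths are tallied and normalized by the state's total
#' observation count, so each row reads as observed activity rates rather
#' than prior-smoothed probabilities. A state with no assigned observations
#' keeps its sampled row.
#'
#' @param solution A `bphmm_solution`.
#' @return K x M row-stochastic matrix.
#' @export
categorical_emissions <- function(solution) {
  stopifnot(inherits(solution, "bphmm_solution"))
  K <- n_states(solution); M <- solution$M
  counts <- matrix(0, K, M)
  for (i in seq_along(solution$seqs)) {
    path <- viterbi_decode(solution, i)
    x <- solution$seqs[[i]]
    for (t in seq_along(x)) counts[path[t], x[t]] <- counts[path[t], x[t]] + 1
  }
  tot <- rowSums(counts)
  out <- counts / ifelse(tot == 0, 1, tot)
  empty <- tot == 0
  if (any(empty)) out[empty, ] <- solution$theta[empty, , drop = FALSE]
  out
}

#' Collapse emission rows to activity-level profiles
#'
#' Sums each state's symbol probabilities within every activity block of the
#' alphabet, turning an M-dimensional emission row into one value per
#' activity (4 under the default vocabulary). The output rows sum to 1.
#'
#' @param theta An emission row (numeric vector of length M) or a K x M
#'   matrix of rows.
#' @param codebook The `bphmm_codebook` defining the activity blocks.
#' @return A named activity vector (for a single row) or a K x activities
#'   matrix.
#' @export
collapse_to_activities <- function(theta, codebook) {
  stopifnot(inherits(codebook, "bphmm_codebook"))
  acts <- symbol_activities(codebook)
  lv <- names(codebook$centroids)
  if (is.matrix(theta)) {
    stopifnot(ncol(theta) == length(acts))
    out <- t(apply(theta, 1, function(p) {
      tapply(p, factor(acts, levels = lv), sum, default = 0)
    }))
    colnames(out) <- lv
    out
  } else {
    stopifnot(length(theta) == length(acts))
    out <- tapply(theta, factor(acts, levels = lv), sum, default = 0)
    stats::setNames(as.numeric(out), lv)
  }
}

#' Sample excess kurtosis (Fisher-corrected)
#'
#' The bias-corrected sample excess kurtosis
#' `G2 = ((n-1)/((n-2)(n-3))) * ((n+1) g2 + 6)` with
#' `g2 = m4/m2^2 - 3` computed from central moments. At `n = 4` this is the
#' statistic whose benchmark for a discrete uniform profile is -1.2; unlike
#' the population form it can fall below -2, which is why peaked/diffuse
#' classification uses it.
#'
#' @param values Numeric vector, length >= 4, not all equal.
#' @return The excess kurtosis G2 (scalar).
#' @export
#' @examples
#' excess_kurtosis(c(0, 0, 0.5, 0.5))  # -6
#' excess_kurtosis(c(0, 0, 0, 1))      # 4
excess_kurtosis <- function(values) {
  n <- length(values)
  if (n < 4) cli::cli_abort("excess kurtosis needs at least 4 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) cli::cli_abort("undefined kurtosis: zero variance")
  g2 <- mean((values - m)^4) / m2^2 - 3
  ((n - 1) / ((n - 2) * (n - 3))) * ((n + 1) * g2 + 6)
}

#' Excess-kurtosis benchmark of a uniform distribution
#'
#' The excess kurtosis of a uniform profile, -6/5 = -1.2: the default
#' boundary between diffuse (platykurtic/uniform) and peaked (leptokurtic)
#' states.
#'
#' @return -1.2.
#' @export
uniform_excess_kurtosis <- function() -6 / 5

#' Classify states as peaked or diffuse
#'
#' Two classifiers over each state's activity-collapsed emission profile:
#'
#' * `"kurtosis"` — [excess_kurtosis()] of the activity masses; a state is
#'   peaked iff its value is strictly above the uniform benchmark
#'   ([uniform_excess_kurtosis()], -1.2). A zero-variance (uniform) profile
#'   is diffuse by definition.
#' * `"max_average"` — per state, the mean symbol probability within each
#'   activity block (activity mass divided by the block's centroid count);
#'   the maximum of these is the state's peakedness. The threshold is the
#'   across-state mean of the maxima; peaked iff strictly above it.
#'
#' @param solution A `bphmm_solution`, or a K x M emission matrix.
#' @param codebook The `bphmm_codebook` defining activity blocks; defaults
#'   to the one attached to the solution.
#' @param method `"kurtosis"` (default) or `"max_average"`.
#' @param kurtosis_threshold Peaked/diffuse boundary for the kurtosis
#'   method.
#' @param emissions For a solution, which emission parameterization to
#'   classify: `"empirical"` (default, the count-normalized categorical
#'   conversion of [categorical_emissions()]) or `"sampled"` (the raw
#'   Dirichlet draw).
#' @return Tibble with `state`, `method`, `statistic`, `threshold`, `label`
#'   (`"peaked"` or `"diffuse"`).
#' @export
classify_states <- function(solution, codebook = NULL,
                            method = c("kurtosis", "max_average"),
                            kurtosis_threshold = uniform_excess_kurtosis(),
                            emissions = c("empirical", "sampled")) {
  method <- match.arg(method)
  emissions <- match.arg(emissions)
  theta <- if (inherits(solution, "bphmm_solution")) {
    codebook <- codebook %||% solution$codebook
    if (emissions == "empirical") categorical_emissions(solution) else
      solution$theta
  } else {
    solution
  }
  if (is.null(codebook)) {
    cli::cli_abort("a codebook is required to collapse symbols to activities")
  }
  prof <- collapse_to_activities(theta, codebook)
  K <- nrow(prof)

  if (method == "kurtosis") {
    stat <- vapply(seq_len(K), function(k) {
      p <- prof[k, ]
      if (stats::var(p) == 0) NA_real_ else excess_kurtosis(p)
    }, numeric(1))
    label <- ifelse(!is.na(stat) & stat > kurtosis_threshold,
                    "peaked", "diffuse")
    threshold <- kurtosis_threshold
  } else {
    sizes <- lengths(codebook$centroids)
    sizes <- sizes[sizes > 0]
    stat <- apply(sweep(prof[, names(sizes), drop = FALSE], 2, sizes, "/"),
                  1, max)
    threshold <- mean(stat)
    label <- ifelse(stat > threshold, "peaked", "diffuse")
  }
  tibble::tibble(state = seq_len(K), method = method,
                 statistic = unname(stat), threshold = threshold,
                 label = unname(label))
}

#' Fraction of session time spent in peaked states
#'
#' @param proportions Per-state time proportions for one session (e.g. a row
#'   of [state_occupancy()] spread wide, or [time_in_states()] output).
#' @param peaked_states Integer indices of the peaked states.
#' @return Scalar fraction in \[0, 1\]; the diffuse fraction is its
#'   complement.
#' @export
peaked_time_fraction <- function(proportions, peaked_states) {
  stopifnot(all(peaked_states >= 1), all(peaked_states <= length(proportions)))
  sum(proportions[peaked_states])
}

#' Per-session peaked-time fractions
#'
#' @param occupancy Long occupancy tibble from [state_occupancy()] (columns
#'   `session_id`, `state`, `proportion`, plus any metadata).
#' @param peaked_states Integer indices of the peaked states (e.g. from
#'   [classify_states()]).
#' @return Tibble with one row per session: metadata, `peaked_fraction`,
#'   `diffuse_fraction`.
#' @export
session_peakedness <- function(occupancy, peaked_states) {
  meta_cols <- setdiff(names(occupancy), c("state", "proportion"))
  occupancy |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
    dplyr::summarise(
      peaked_fraction = sum(.data$proportion[.data$state %in% peaked_states]),
      .groups = "drop"
    ) |>
    dplyr::mutate(diffuse_fraction = 1 - .data$peaked_fraction)
}

#' Mean within- and between-category transition probabilities
#'
#' Over the off-diagonal entries of a transition matrix whose states carry
#' peaked/diffuse labels: the mean of entries whose source and destination
#' share a category (within) and the mean of the rest (between).
#' Self-transitions are excluded. A category with no qualifying entries is
#' reported as `NA`.
#'
#' @param trans L x L transition matrix.
#' @param labels Character vector of length L of state categories.
#' @return Named list with `within` and `between` means.
#' @export
transition_category_means <- function(trans, labels) {
  L <- nrow(trans)
  stopifnot(ncol(trans) == L, length(labels) == L)
  if (L < 2) return(list(within = NA_real_, between = NA_real_))
  same <- outer(labels, labels, "==")
  off <- !diag(TRUE, L)
  within_vals <- trans[off & same]
  between_vals <- trans[off & !same]
  list(
    within = if (length(within_vals) > 0) mean(within_vals) else NA_real_,
    between = if (length(between_vals) > 0) mean(between_vals) else NA_real_
  )
}

#' Transition-category statistics for every sequence
#'
#' Applies [transition_category_means()] to each sequence's fitted
#' transition matrix, using a state classification to label its active
#' features. Sequences with fewer than two active features are flagged
#' rather than erroring.
#'
#' @param solution A `bphmm_solution`.
#' @param classification Output of [classify_states()] covering all global
#'   states.
#' @return Tibble with `session_id`, `n_active`, `within_mean`,
#'   `between_mean` (`NA` where undefined).
#' @export
transition_category_stats <- function(solution, classification) {
  stopifnot(inherits(solution, "bphmm_solution"))
  labels <- classification$label[order(classification$state)]
  purrr::map2_dfr(seq_along(solution$seqs), solution$sequence_ids,
                  function(i, id) {
    act <- active_features(solution, i)
    mm <- transition_category_means(solution$trans[[i]], labels[act])
    tibble::tibble(session_id = id, n_active = length(act),
                   within_mean = mm$within, between_mean = mm$between)
  })
}

#' Flag participants who reached success states
#'
#' A participant is flagged successful if, in any session, they spent at
#' least `epsilon` of session time in any of the designated success states
#' (states whose emission profile shows high swap mass and low reswap mass).
#'
#' @param occupancy Long occupancy tibble with `subject_id`, `state`,
#'   `proportion` columns (session metadata may be present).
#' @param success_states Integer indices of the success states.
#' @param epsilon Non-negligible occupancy threshold (default 0.05).
#' @return Tibble with `subject_id` and logical `successful`.
#' @export
success_flags <- function(occupancy, success_states, epsilon = 0.05) {
  stopifnot("subject_id" %in% names(occupancy))
  occupancy |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      successful = any(.data$state %in% success_states &
                         .data$proportion >= epsilon, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Pearson correlation with validation
#'
#' Sample Pearson correlation of two equal-length vectors, erroring on
#' constant input or fewer than three observations.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) cli::cli_abort("x and y must have equal length")
  if (length(x) < 3) cli::cli_abort("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    cli::cli_abort("correlation undefined for constant input")
  }
  stats::cor(x, y)
}

#' Ordered feature activation map
#'
#' The ensemble's binary feature activations arranged for display: rows
#' (sessions) sorted static-interface first then wiggle (stable within
#' group), columns (states) sorted by ascending total emission mass on the
#' wiggle activity's symbols, ties by state index. On a two-condition
#' ensemble with condition-specific states this produces the characteristic
#' block-diagonal structure.
#'
#' @param solution A `bphmm_solution`.
#' @param sessions Tibble with `session_id` and `interface` columns covering
#'   every sequence.
#' @param codebook Codebook defining the wiggle symbol block; defaults to
#'   the solution's attached codebook.
#' @param emissions Emission parameterization used for the wiggle-mass
#'   ordering, as in [classify_states()].
#' @return A `bphmm_activation_map`: list with the permuted binary `map`
#'   (rownames = session ids, colnames = original state labels),
#'   `state_order`, `row_order` and the per-state `wiggle_mass`.
#' @export
activation_map <- function(solution, sessions, codebook = NULL,
                           emissions = c("empirical", "sampled")) {
  stopifnot(inherits(solution, "bphmm_solution"))
  emissions <- match.arg(emissions)
  codebook <- codebook %||% solution$codebook
  if (is.null(codebook)) cli::cli_abort("a codebook is required")
  theta <- if (emissions == "empirical") categorical_emissions(solution) else
    solution$theta
  prof <- collapse_to_activities(theta, codebook)
  wcode <- codebook$wiggle_code
  wiggle_mass <- if (wcode %in% colnames(prof)) prof[, wcode] else
    rep(0, nrow(prof))
  state_order <- order(wiggle_mass, seq_along(wiggle_mass))

  meta <- sessions[match(solution$sequence_ids, sessions$session_id), ]
  if (anyNA(meta$interface)) {
    cli::cli_abort("every sequence needs an {.field interface} label")
  }
  row_order <- order(meta$interface != "static", seq_along(solution$sequence_ids))

  map <- solution$F[row_order, state_order, drop = FALSE]
  rownames(map) <- solution$sequence_ids[row_order]
  colnames(map) <- paste0("state_", state_order)
  structure(list(map = map, state_order = state_order,
                 row_order = row_order, wiggle_mass = wiggle_mass,
                 interface = meta$interface[row_order]),
            class = "bphmm_activation_map")
}

#' @export
print.bphmm_activation_map <- function(x, ...) {
  cat("<bphmm_activation_map>", nrow(x$map), "sessions x", ncol(x$map),
      "states\n")
  print(x$map)
  invisible(x)
}
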