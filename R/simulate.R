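#' Default behavioral state templates
#'
#' Activity-level emission templates for the four canonical behavior modes
#' the generator emulates: random search (select + reswap heavy), success
#' (select + swap heavy, few reswaps), sequential search (reswap-dominated
#' with few selects), and wiggle-heavy exploration. Static-interface states
#' carry exactly zero wiggle mass.
#'
#' @param vocabulary Activity codes (columns of the template matrix).
#' @return K x 4 row-stochastic matrix with named rows.
#' @export
default_templates <- function(vocabulary = wiggle_vocabulary()) {
  tpl <- rbind(
    random_search     = c(0.45, 0.05, 0.50, 0.00),
    success           = c(0.50, 0.42, 0.08, 0.00),
    sequential_search = c(0.08, 0.02, 0.90, 0.00),
    wiggle_heavy      = c(0.15, 0.05, 0.10, 0.70)
  )
  colnames(tpl) <- as.character(vocabulary)
  tpl
}

#' Ground truth for the synthetic-log generator
#'
#' Describes a generating configuration: the state templates, per-state
#' temporal laws (log-normal inter-event intervals), the session roster with
#' its two interface conditions, the feature plan assigning states to
#' conditions, and sticky transition dynamics. The defaults emulate the
#' study design the package was built around: 20 subjects, two 10-minute
#' sessions each, half with the wiggle function enabled and half static
#' (static sessions never produce the wiggle code), half given the goal
#' hint, with rapid select precursors inserted before some acts to exercise
#' the 50 ms recode.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param sessions_per_subject Sessions per subject (default 2).
#' @param prop_wiggle Proportion of subjects with the wiggle interface.
#' @param prop_hint Proportion of subjects given the goal hint.
#' @param templates K x activities emission template matrix
#'   ([default_templates()]).
#' @param feature_plan Named list giving the state indices active under each
#'   interface condition.
#' @param delta_meanlog Per-state log-normal meanlog of inter-event
#'   intervals (seconds); defaults span sub-second to several seconds.
#' @param delta_sdlog Log-normal sdlog (shared).
#' @param self_transition Probability mass placed on self-transitions.
#' @param sel_precursor_prob Probability of inserting a select precursor
#'   within 50 ms before a non-select event.
#' @param min_delta Smallest natural inter-event interval (seconds); keeps
#'   natural pairs outside the recode window so inserted precursors are
#'   identifiable.
#' @return A `bphmm_ground_truth` list.
#' @export
ground_truth <- function(n_subjects = 20, sessions_per_subject = 2,
                         prop_wiggle = 0.5, prop_hint = 0.5,
                         templates = default_templates(),
                         feature_plan = list(
                           static = c(1, 2, 3),
                           wiggle = c(1, 3, 4)
                         ),
                         delta_meanlog = log(c(1.0, 2.5, 0.35, 3.5)),
                         delta_sdlog = 0.5,
                         self_transition = 0.9,
                         sel_precursor_prob = 0.3,
                         min_delta = 0.06) {
  K <- nrow(templates)
  stopifnot(length(delta_meanlog) == K,
            all(unlist(feature_plan) <= K),
            all(abs(rowSums(templates) - 1) < 1e-9),
            self_transition > 0, self_transition < 1)
  vocab <- colnames(templates)
  wcode <- vocab[length(vocab)]
  static_states <- feature_plan$static
  if (any(templates[static_states, wcode] > 0)) {
    cli::cli_abort("static-condition states must carry zero {.val {wcode}} mass")
  }
  n_wiggle <- round(n_subjects * prop_wiggle)
  n_hint <- round(n_subjects * prop_hint)
  subjects <- tibble::tibble(
    subject_id = sprintf("p%02d", seq_len(n_subjects)),
    interface = rep(c("wiggle", "static"),
                    c(n_wiggle, n_subjects - n_wiggle)),
    instruction = rep_len(c("hint", "none"), n_subjects)
  )
  sessions <- tidyr::expand_grid(subjects,
                                 session = seq_len(sessions_per_subject)) |>
    dplyr::mutate(session_id = paste0(.data$subject_id, "_s", .data$session))
  F <- matrix(0L, nrow(sessions), K)
  for (r in seq_len(nrow(sessions))) {
    F[r, feature_plan[[sessions$interface[r]]]] <- 1L
  }
  structure(
    list(templates = templates, vocabulary = vocab,
         feature_plan = feature_plan, F = F, sessions = sessions,
         delta_meanlog = delta_meanlog, delta_sdlog = delta_sdlog,
         self_transition = self_transition,
         sel_precursor_prob = sel_precursor_prob, min_delta = min_delta),
    class = "bphmm_ground_truth"
  )
}

#' @export
print.bphmm_ground_truth <- function(x, ...) {
  cat("<bphmm_ground_truth>", nrow(x$sessions), "sessions,",
      nrow(x$templates), "states\n")
  print(x$templates)
  invisible(x)
}

#' Simulate an ensemble of raw activity logs
#'
#' Draws, for every session in the ground truth's roster, a sticky hidden
#' state path over the session's active states, activities from the state
#' templates, and log-normal inter-event intervals (floored at
#' `truth$min_delta`). With probability `truth$sel_precursor_prob` a bare
#' select event is inserted 5-45 ms before a non-select event, mimicking
#' the select-then-act pairs the 50 ms recode is designed to collapse. The
#' insertion bookkeeping is returned so tests can verify the recode removes
#' exactly the inserted events.
#'
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed.
#' @param n_events Events per session before precursor insertion; when
#'   `NULL`, sessions run until `duration` seconds have elapsed.
#' @param duration Session length in seconds (default 600, i.e. 10 minutes),
#'   used when `n_events` is `NULL`.
#' @return A list: `events` (raw log tibble in [read_activity_log()] layout,
#'   including inserted precursors), `paths` (per-session hidden state
#'   vectors, pre-insertion), `n_precursors` (per-session insertion counts)
#'   and the `truth` object itself.
#' @export
simulate_ensemble <- function(truth, seed = 1L, n_events = NULL,
                              duration = 600) {
  stopifnot(inherits(truth, "bphmm_ground_truth"))
  if (is.null(n_events) && duration <= 0) {
    cli::cli_abort("duration must be positive")
  }
  if (!is.null(n_events) && n_events < 1) {
    cli::cli_abort("n_events must be positive")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  vocab <- truth$vocabulary
  sel <- vocab[1]
  K <- nrow(truth$templates)
  sessions <- truth$sessions
  paths <- vector("list", nrow(sessions))
  n_prec <- integer(nrow(sessions))
  out <- vector("list", nrow(sessions))

  for (r in seq_len(nrow(sessions))) {
    active <- which(truth$F[r, ] == 1)
    L <- length(active)
    P <- matrix((1 - truth$self_transition) / max(L - 1, 1), L, L)
    diag(P) <- if (L > 1) truth$self_transition else 1

    z <- integer(0)
    acts <- character(0)
    deltas <- numeric(0)
    t_now <- 0
    step <- 0L
    repeat {
      step <- step + 1L
      zi <- if (step == 1L) sample.int(L, 1) else
        sample.int(L, 1, prob = P[z[step - 1L], ])
      z[step] <- zi
      st <- active[zi]
      acts[step] <- sample(vocab, 1, prob = truth$templates[st, ])
      deltas[step] <- max(stats::rlnorm(1, truth$delta_meanlog[st],
                                        truth$delta_sdlog),
                          truth$min_delta)
      t_now <- t_now + deltas[step]
      if (!is.null(n_events)) {
        if (step >= n_events) break
      } else if (t_now >= duration) break
    }
    ts <- cumsum(deltas)
    paths[[r]] <- active[z]

    # insert select precursors within the recode window before non-select acts
    insert <- acts != sel & stats::runif(length(acts)) < truth$sel_precursor_prob
    n_prec[r] <- sum(insert)
    ev_t <- c(ts, ts[insert] - stats::runif(sum(insert), 0.005, 0.045))
    ev_a <- c(acts, rep(sel, sum(insert)))
    ord <- order(ev_t)
    out[[r]] <- tibble::tibble(
      session_id = sessions$session_id[r],
      subject_id = sessions$subject_id[r],
      interface = sessions$interface[r],
      instruction = sessions$instruction[r],
      timestamp = ev_t[ord],
      activity = ev_a[ord]
    )
  }
  events <- dplyr::bind_rows(out)
  names(paths) <- sessions$session_id
  names(n_prec) <- sessions$session_id
  list(events = events, paths = paths, n_precursors = n_prec, truth = truth)
}
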