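#' BP-HMM hyperparameters
#'
#' Bundles the hyperparameters of the sticky discrete-emission BP-HMM:
#'
#' * `gamma` — beta-process mass; the number of active states per sequence
#'   is marginally Poisson(`gamma`) when `beta = 1`.
#' * `beta` — beta-process concentration; larger values spread features more
#'   evenly across sequences.
#' * `kappa` — stickiness; extra Dirichlet mass on self-transitions,
#'   favoring temporally persistent states.
#' * `alpha` — base concentration of the transition Dirichlet rows.
#' * `lambda0` — symmetric Dirichlet concentration of the per-state
#'   emission distributions over the symbol alphabet.
#'
#' Defaults are the selected combination used throughout the package:
#' `gamma = 3`, `beta = 1`, `kappa = 200`, `lambda0 = 5`, with `alpha = 1`.
#'
#' @param gamma,beta,kappa,alpha,lambda0 Positive scalars (`kappa` may be 0).
#' @return A `bp_hyperparams` list.
#' @export
#' @examples
#' bp_hyperparams()
bp_hyperparams <- function(gamma = 3, beta = 1, kappa = 200, alpha = 1,
                           lambda0 = 5) {
  stopifnot(gamma > 0, beta > 0, kappa >= 0, alpha > 0, lambda0 > 0)
  structure(list(gamma = gamma, beta = beta, kappa = kappa, alpha = alpha,
                 lambda0 = lambda0),
            class = "bp_hyperparams")
}

#' @export
print.bp_hyperparams <- function(x, ...) {
  cat(sprintf(
    "<bp_hyperparams> gamma=%g beta=%g kappa=%g alpha=%g lambda0=%g\n",
    x$gamma, x$beta, x$kappa, x$alpha, x$lambda0))
  invisible(x)
}

# Internal constructor for a fitted (or simulated) BP-HMM solution.
# F: N x K binary matrix; theta: K x M emission rows; trans/pi0/z: per-
# sequence lists indexed like rows of F, each over the sequence's active
# features in ascending global order; seqs: per-sequence symbol vectors.
new_bphmm_solution <- function(hyper, F, theta, trans, pi0, z, seqs, M,
                               sequence_ids, seed, iteration = 0L,
                               trace = NULL, codebook = NULL) {
  structure(
    list(hyper = hyper, F = F, theta = theta, trans = trans, pi0 = pi0,
         z = z, seqs = seqs, M = M, sequence_ids = sequence_ids,
         seed = seed, iteration = iteration, trace = trace,
         codebook = codebook),
    class = "bphmm_solution"
  )
}

#' Number of states in a fitted solution
#' @param solution A `bphmm_solution`.
#' @return Integer count of global states (features).
#' @export
n_states <- function(solution) {
  stopifnot(inherits(solution, "bphmm_solution"))
  ncol(solution$F)
}

active_features <- function(solution, i) which(solution$F[i, ] == 1)

#' Check the structural invariants of a solution
#'
#' Verifies mutually consistent shapes (emission rows equal feature columns),
#' binary F with no featureless sequence and no unused state, simplex
#' emission and transition rows (tolerance 1e-9), and state paths confined
#' to each sequence's active features.
#'
#' @param solution A `bphmm_solution`.
#' @param tol Simplex tolerance.
#' @return The solution, invisibly; errors describe the first violation.
#' @export
validate_solution <- function(solution, tol = 1e-9) {
  F <- solution$F
  K <- ncol(F)
  if (!all(F %in% c(0, 1))) cli::cli_abort("feature matrix is not binary")
  if (any(rowSums(F) < 1)) cli::cli_abort("a sequence has no active features")
  if (K > 0 && any(colSums(F) < 1)) cli::cli_abort("an unused state column remains")
  if (nrow(solution$theta) != K) {
    cli::cli_abort("emission library has {nrow(solution$theta)} rows but F has {K} columns")
  }
  if (ncol(solution$theta) != solution$M) {
    cli::cli_abort("emission rows are not over the {solution$M}-symbol alphabet")
  }
  if (any(abs(rowSums(solution$theta) - 1) > tol)) {
    cli::cli_abort("an emission row is off the simplex")
  }
  for (i in seq_len(nrow(F))) {
    act <- which(F[i, ] == 1)
    P <- solution$trans[[i]]
    if (nrow(P) != length(act) || ncol(P) != length(act)) {
      cli::cli_abort("transition matrix of sequence {i} has the wrong size")
    }
    if (any(abs(rowSums(P) - 1) > tol) ||
        abs(sum(solution$pi0[[i]]) - 1) > tol) {
      cli::cli_abort("a transition row of sequence {i} is off the simplex")
    }
    if (!all(solution$z[[i]] %in% act)) {
      cli::cli_abort("state path of sequence {i} leaves its active features")
    }
  }
  invisible(solution)
}

#' @export
print.bphmm_solution <- function(x, ...) {
  cat("<bphmm_solution>\n")
  cat(sprintf("  %d sequences, %d states, %d-symbol alphabet\n",
              nrow(x$F), ncol(x$F), x$M))
  cat(sprintf("  hyperparameters: gamma=%g beta=%g kappa=%g alpha=%g lambda0=%g\n",
              x$hyper$gamma, x$hyper$beta, x$hyper$kappa, x$hyper$alpha,
              x$hyper$lambda0))
  cat(sprintf("  iteration %d, seed %d\n", x$iteration, x$seed))
  invisible(x)
}

#' Tidy a fitted BP-HMM solution
#'
#' Returns the emission library in long form: one row per (state, symbol)
#' with the emission probability, plus the symbol's activity and temporal
#' centroid when a codebook is attached to the solution.
#'
#' @param x A `bphmm_solution`.
#' @param ... Unused.
#' @return A tibble with columns `state`, `symbol`, `probability` and, when
#'   a codebook is available, `activity` and `centroid`.
#' @export
tidy.bphmm_solution <- function(x, ...) {
  K <- ncol(x$F)
  out <- tibble::tibble(
    state = rep(seq_len(K), each = x$M),
    symbol = rep(seq_len(x$M), times = K),
    probability = as.numeric(t(x$theta))
  )
  if (!is.null(x$codebook)) {
    info <- symbol_info(seq_len(x$M), x$codebook)
    out <- dplyr::left_join(out, info, by = "symbol")
  }
  out
}

#' One-row summary of a fitted BP-HMM solution
#'
#' @param x A `bphmm_solution`.
#' @param ... Unused.
#' @return A one-row tibble: sequence count, state count, alphabet size,
#'   joint log-likelihood of all sequences under the fitted parameters,
#'   iteration, seed and hyperparameters.
#' @export
glance.bphmm_solution <- function(x, ...) {
  tibble::tibble(
    n_sequences = nrow(x$F),
    n_states = ncol(x$F),
    alphabet_size = x$M,
    log_lik = joint_log_likelihood(x),
    iterations = x$iteration,
    seed = x$seed,
    gamma = x$hyper$gamma,
    beta = x$hyper$beta,
    kappa = x$hyper$kappa,
    alpha = x$hyper$alpha,
    lambda0 = x$hyper$lambda0
  )
}

#' Feature activations in long form
#'
#' @param solution A `bphmm_solution`.
#' @return Tibble with `session_id`, `state`, `active` (0/1) for every
#'   sequence-state pair.
#' @export
tidy_features <- function(solution) {
  stopifnot(inherits(solution, "bphmm_solution"))
  K <- ncol(solution$F)
  tibble::tibble(
    session_id = rep(solution$sequence_ids, times = K),
    state = rep(seq_len(K), each = nrow(solution$F)),
    active = as.integer(solution$F)
  )
}

#' Serialize / restore a solution as JSON
#'
#' Writes hyperparameters, the binary feature matrix, emission rows,
#' per-sequence transition matrices and initial distributions, state paths,
#' symbol sequences, seed and iteration index.
#'
#' @param solution A `bphmm_solution`.
#' @param path File path.
#' @return `write_solution()` returns `path` invisibly; `read_solution()`
#'   the restored solution.
#' @export
write_solution <- function(solution, path) {
  stopifnot(inherits(solution, "bphmm_solution"))
  payload <- list(
    hyper = unclass(solution$hyper),
    F = apply(solution$F, 1, as.integer, simplify = FALSE),
    theta = apply(solution$theta, 1, as.numeric, simplify = FALSE),
    trans = lapply(solution$trans, function(P) apply(P, 1, as.numeric,
                                                     simplify = FALSE)),
    pi0 = lapply(solution$pi0, as.numeric),
    z = lapply(solution$z, as.integer),
    seqs = lapply(solution$seqs, as.integer),
    M = solution$M,
    sequence_ids = solution$sequence_ids,
    seed = solution$seed,
    iteration = solution$iteration
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_solution
#' @export
read_solution <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  F <- do.call(rbind, lapply(p$F, function(r) as.integer(unlist(r))))
  theta <- do.call(rbind, lapply(p$theta, function(r) as.numeric(unlist(r))))
  trans <- lapply(p$trans, function(rows) {
    do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  })
  new_bphmm_solution(
    hyper = do.call(bp_hyperparams, p$hyper),
    F = F, theta = theta, trans = trans,
    pi0 = lapply(p$pi0, function(v) as.numeric(unlist(v))),
    z = lapply(p$z, function(v) as.integer(unlist(v))),
    seqs = lapply(p$seqs, function(v) as.integer(unlist(v))),
    M = p$M,
    sequence_ids = unlist(p$sequence_ids),
    seed = p$seed, iteration = p$iteration
  )
}
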