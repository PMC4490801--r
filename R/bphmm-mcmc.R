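#' MCMC configuration
#'
#' @param n_iterations Number of full sweeps (default 10,000, the setting
#'   used for production fits; tests and examples use far fewer).
#' @param seed Integer seed for the chain.
#' @param keep `"last"` keeps the final sweep's sample (the package-wide
#'   convention); `"max_loglik"` keeps the sweep with the highest joint
#'   log-likelihood instead.
#' @param progress_every Print a progress line every this many sweeps
#'   (0 = silent).
#' @return A `bp_mcmc_config` list.
#' @export
bp_mcmc_config <- function(n_iterations = 10000, seed = 1L,
                           keep = c("last", "max_loglik"),
                           progress_every = 0) {
  stopifnot(n_iterations >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 keep = match.arg(keep),
                 progress_every = progress_every),
            class = "bp_mcmc_config")
}

#' Conjugate posterior parameters for one emission row
#'
#' The symmetric Dirichlet(`lambda0`) prior over an emission row combined
#' with multinomial symbol counts gives a Dirichlet posterior with
#' parameters `lambda0 + counts`.
#'
#' @param counts Integer symbol counts assigned to the state (length M).
#' @param lambda0 Prior concentration.
#' @return Numeric vector of Dirichlet posterior parameters.
#' @export
emission_posterior <- function(counts, lambda0) {
  stopifnot(all(counts >= 0), lambda0 > 0)
  lambda0 + counts
}

#' Conjugate posterior parameters for one transition row
#'
#' The sticky Dirichlet(`alpha` + `kappa` on self) prior over a transition
#' row combined with observed transition counts gives a Dirichlet posterior
#' `alpha + kappa * delta(j, .) + counts`.
#'
#' @param counts Transition counts out of the row's state (length L).
#' @param alpha Base concentration.
#' @param kappa Stickiness mass.
#' @param self Index of the self-transition within the row.
#' @return Numeric vector of Dirichlet posterior parameters.
#' @export
transition_posterior <- function(counts, alpha, kappa, self) {
  stopifnot(all(counts >= 0), self >= 1, self <= length(counts))
  shape <- alpha + counts
  shape[self] <- shape[self] + kappa
  shape
}

# --- transition-weight augmentation ---------------------------------------
#
# Per sequence, unnormalized transition weights eta_jk ~ Gamma(alpha +
# kappa*delta(j,k), 1) are maintained for EVERY pair of global states, and
# the feature-constrained transition matrix is eta restricted to the active
# set and row-normalized (the normalized-Gamma construction, identical in
# distribution to sticky Dirichlet rows). Keeping weights for inactive
# states means a feature-activation flip only changes which entries are
# normalized, so its Metropolis-Hastings ratio needs no auxiliary draws.

prior_eta_matrix <- function(K, alpha, kappa) {
  shape <- matrix(alpha, K, K)
  diag(shape) <- alpha + kappa
  matrix(stats::rgamma(K * K, shape = shape, rate = 1), K, K)
}

# Sync the public transition matrix / initial distribution of sequence i
# with its weights over the current active set.
sync_trans_i <- function(solution, i) {
  act <- active_features(solution, i)
  E <- solution$eta[[i]][act, act, drop = FALSE]
  solution$trans[[i]] <- E / rowSums(E)
  e0 <- solution$eta0[[i]][act]
  solution$pi0[[i]] <- e0 / sum(e0)
  solution
}

# --- Gibbs blocks ----------------------------------------------------------

# Blocked draw of sequence i's hidden path from its exact conditional.
resample_states_i <- function(solution, i) {
  act <- active_features(solution, i)
  E <- emission_probs(solution$seqs[[i]], solution$theta, act)
  path_local <- ffbs_cpp(E, solution$trans[[i]], solution$pi0[[i]])
  solution$z[[i]] <- act[path_local]
  solution
}

#' Gibbs update of the emission library
#'
#' Pools, for each state, the symbols assigned to it across all sequences
#' and draws each emission row from Dirichlet([emission_posterior()]).
#' States currently emitting no observations are redrawn from the prior.
#'
#' @param solution A `bphmm_solution` with current state paths.
#' @return The solution with a fresh `theta`.
#' @export
resample_emissions <- function(solution) {
  K <- ncol(solution$F); M <- solution$M
  counts <- matrix(0, K, M)
  for (i in seq_along(solution$seqs)) {
    z <- solution$z[[i]]; x <- solution$seqs[[i]]
    for (t in seq_along(x)) counts[z[t], x[t]] <- counts[z[t], x[t]] + 1
  }
  lam <- solution$hyper$lambda0
  solution$theta <- t(vapply(seq_len(K), function(k) {
    rdirichlet_one(emission_posterior(counts[k, ], lam))
  }, numeric(M)))
  solution
}

#' Gibbs update of all transition parameters
#'
#' For each sequence, redraws its transition weights given the current
#' path: over the active set, each row's normalized weights come from
#' Dirichlet([transition_posterior()]) (scaled by an independent Gamma
#' total, which leaves the row distribution unchanged); weights involving
#' inactive states, which the likelihood never sees, are redrawn from the
#' prior. The initial distribution is treated the same way with a
#' Dirichlet(`alpha` + first-state indicator) posterior.
#'
#' @param solution A `bphmm_solution` with current state paths.
#' @return The solution with fresh transition weights and synced `trans`
#'   and `pi0`.
#' @export
resample_transitions <- function(solution) {
  hy <- solution$hyper
  K <- ncol(solution$F)
  for (i in seq_along(solution$seqs)) {
    act <- active_features(solution, i)
    L <- length(act)
    z <- match(solution$z[[i]], act)
    n <- matrix(0, L, L)
    if (length(z) > 1) {
      for (t in 2:length(z)) n[z[t - 1], z[t]] <- n[z[t - 1], z[t]] + 1
    }
    eta <- prior_eta_matrix(K, hy$alpha, hy$kappa)
    for (j in seq_len(L)) {
      post <- transition_posterior(n[j, ], hy$alpha, hy$kappa, j)
      prior_total <- L * hy$alpha + hy$kappa
      p <- rdirichlet_one(post)
      eta[act[j], act] <- p * stats::rgamma(1, prior_total, rate = 1)
    }
    solution$eta[[i]] <- eta

    eta0 <- stats::rgamma(K, hy$alpha, rate = 1)
    init <- rep(hy$alpha, L)
    init[z[1]] <- init[z[1]] + 1
    eta0[act] <- rdirichlet_one(init) * stats::rgamma(1, L * hy$alpha,
                                                      rate = 1)
    solution$eta0[[i]] <- eta0
    solution <- sync_trans_i(solution, i)
  }
  solution
}

# Forward log-likelihood of sequence i if its active set were `act`,
# holding the transition weights fixed.
seq_loglik_under_act <- function(solution, i, act) {
  E <- solution$eta[[i]][act, act, drop = FALSE]
  trans <- E / rowSums(E)
  e0 <- solution$eta0[[i]][act]
  fwd_loglik_cpp(emission_probs(solution$seqs[[i]], solution$theta, act),
                 trans, e0 / sum(e0))
}

#' Metropolis-Hastings update of one sequence's feature assignments
#'
#' Two move families, both marginalizing the hidden path with the forward
#' algorithm while holding the sequence's transition weights fixed (the
#' weight augmentation covers inactive states, so a flip only changes which
#' weights are normalized):
#'
#' * **Shared features** (active in at least one other sequence): each
#'   activation bit is flipped with acceptance odds equal to the
#'   Indian-buffet conditional prior odds `m / (beta + N - 1 - m)` (or the
#'   inverse) times the marginal-likelihood ratio.
#' * **Unique features** (active only in this sequence): a birth proposes a
#'   new global state with a prior-drawn emission row and prior-drawn
#'   transition weights; a death removes a uniformly chosen unique state.
#'   The number of unique features carries a
#'   Poisson(`gamma * beta / (beta + N - 1)`) prior.
#'
#' Any move that would leave the sequence featureless is rejected outright.
#' After the moves the sequence's hidden path is redrawn, so paths never
#' reference an inactive state.
#'
#' @param solution A `bphmm_solution`.
#' @param i Sequence index.
#' @return The updated solution.
#' @export
update_features <- function(solution, i) {
  hy <- solution$hyper
  N <- nrow(solution$F)
  act_cur <- active_features(solution, i)
  cur_ll <- seq_loglik_under_act(solution, i, act_cur)

  # shared-feature flips
  m_others <- colSums(solution$F[-i, , drop = FALSE])
  for (k in which(m_others >= 1)) {
    f_cur <- solution$F[i, k]
    act_new <- if (f_cur == 1) setdiff(act_cur, k) else sort(c(act_cur, k))
    if (length(act_new) == 0) next  # would leave the row featureless
    prior_odds <- m_others[k] / (hy$beta + N - 1 - m_others[k])
    if (f_cur == 1) prior_odds <- 1 / prior_odds
    ll_new <- seq_loglik_under_act(solution, i, act_new)
    if (stats::runif(1) < prior_odds * exp(ll_new - cur_ll)) {
      solution$F[i, k] <- 1L - f_cur
      act_cur <- act_new
      cur_ll <- ll_new
    }
  }

  # unique-feature birth/death
  unique_k <- which(solution$F[i, ] == 1 & colSums(solution$F) == 1)
  n_unique <- length(unique_k)
  lambda_u <- hy$gamma * hy$beta / (hy$beta + N - 1)
  p_birth <- if (n_unique == 0) 1 else 0.5
  if (stats::runif(1) < p_birth) {
    K_new <- ncol(solution$F) + 1L
    theta_new <- rdirichlet_one(rep(hy$lambda0, solution$M))
    prop <- grow_weights(solution, i, hy)
    act_new <- c(act_cur, K_new)
    E <- prop$eta[act_new, act_new, drop = FALSE]
    e0 <- prop$eta0[act_new]
    ll_new <- fwd_loglik_cpp(
      emission_probs(solution$seqs[[i]], rbind(solution$theta, theta_new),
                     act_new),
      E / rowSums(E), e0 / sum(e0))
    accept <- (lambda_u / (n_unique + 1)) * exp(ll_new - cur_ll) *
      0.5 / p_birth
    if (stats::runif(1) < accept) {
      solution$theta <- rbind(solution$theta, theta_new)
      solution$F <- cbind(solution$F, 0L)
      solution$F[i, K_new] <- 1L
      solution$eta[[i]] <- prop$eta
      solution$eta0[[i]] <- prop$eta0
      # weights of the new state for every other sequence: prior draws for
      # coordinates the likelihood has never seen
      for (j in seq_len(N)[-i]) {
        grown <- grow_weights(solution, j, hy)
        solution$eta[[j]] <- grown$eta
        solution$eta0[[j]] <- grown$eta0
      }
      act_cur <- act_new
      cur_ll <- ll_new
    }
  } else {
    k_die <- unique_k[sample.int(n_unique, 1)]
    act_new <- setdiff(act_cur, k_die)
    if (length(act_new) > 0) {
      ll_new <- seq_loglik_under_act(solution, i, act_new)
      p_birth_rev <- if (n_unique == 1) 1 else 0.5
      accept <- (n_unique / lambda_u) * exp(ll_new - cur_ll) *
        p_birth_rev / 0.5
      if (stats::runif(1) < accept) {
        solution$F[i, k_die] <- 0L
        act_cur <- act_new
        cur_ll <- ll_new
      }
    }
  }

  solution <- sync_trans_i(solution, i)
  resample_states_i(solution, i)
}

# Extend sequence i's weight containers with prior draws for one new state.
grow_weights <- function(solution, i, hy) {
  eta <- solution$eta[[i]]
  K <- ncol(eta)
  new_col <- stats::rgamma(K, hy$alpha, rate = 1)
  new_row <- stats::rgamma(K + 1, hy$alpha, rate = 1)
  new_row[K + 1] <- stats::rgamma(1, hy$alpha + hy$kappa, rate = 1)
  eta <- rbind(cbind(eta, new_col, deparse.level = 0), new_row,
               deparse.level = 0)
  eta0 <- c(solution$eta0[[i]], stats::rgamma(1, hy$alpha, rate = 1))
  list(eta = eta, eta0 = eta0)
}

# Remove states active in no sequence, relabeling paths and reshaping the
# emission library and weight containers.
prune_empty_states <- function(solution) {
  keep <- which(colSums(solution$F) > 0)
  if (length(keep) == ncol(solution$F)) return(solution)
  relabel <- integer(ncol(solution$F))
  relabel[keep] <- seq_along(keep)
  solution$F <- solution$F[, keep, drop = FALSE]
  solution$theta <- solution$theta[keep, , drop = FALSE]
  solution$z <- lapply(solution$z, function(z) relabel[z])
  solution$eta <- lapply(solution$eta,
                         function(e) e[keep, keep, drop = FALSE])
  solution$eta0 <- lapply(solution$eta0, function(e) e[keep])
  solution
}

#' Fit the BP-HMM by MCMC
#'
#' Runs the full sampler over an ensemble of encoded sequences. Each sweep
#' performs, in order: a feature update ([update_features()]) for every
#' sequence, a blocked path redraw for every sequence, the emission Gibbs
#' update, the transition Gibbs update, and pruning of unused states. The
#' returned solution is the last sweep's sample (the package-wide
#' convention) unless `cfg$keep = "max_loglik"`.
#'
#' @param data Encoded events: either a tibble with `session_id` and
#'   `symbol` columns (the output of [encode_symbols()], whose attached
#'   codebook supplies the alphabet size) or a named list of integer symbol
#'   vectors.
#' @param hyper A [bp_hyperparams()] object.
#' @param cfg A [bp_mcmc_config()].
#' @param alphabet_size Alphabet size `M`; defaults to the attached
#'   codebook's size, or the largest observed symbol.
#' @return A `bphmm_solution` carrying a `trace` tibble with per-iteration
#'   `n_states` and `log_lik` diagnostics.
#' @export
run_mcmc <- function(data, hyper = bp_hyperparams(), cfg = bp_mcmc_config(),
                     alphabet_size = NULL) {
  parsed <- as_symbol_ensemble(data, alphabet_size)
  seqs <- parsed$seqs
  M <- parsed$M
  if (length(seqs) == 0) cli::cli_abort("the ensemble is empty")
  if (any(lengths(seqs) == 0)) cli::cli_abort("an encoded sequence is empty")

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(cfg$seed)

  N <- length(seqs)
  F <- sample_ibp_matrix(hyper$gamma, hyper$beta, N)
  K <- ncol(F)
  theta <- t(vapply(seq_len(K),
                    function(k) rdirichlet_one(rep(hyper$lambda0, M)),
                    numeric(M)))
  solution <- new_bphmm_solution(
    hyper = hyper, F = F, theta = theta,
    trans = vector("list", N), pi0 = vector("list", N),
    z = vector("list", N), seqs = seqs, M = M,
    sequence_ids = parsed$ids, seed = cfg$seed, codebook = parsed$codebook
  )
  solution$eta <- lapply(seq_len(N), function(i)
    prior_eta_matrix(K, hyper$alpha, hyper$kappa))
  solution$eta0 <- lapply(seq_len(N), function(i)
    stats::rgamma(K, hyper$alpha, rate = 1))
  for (i in seq_len(N)) {
    solution <- sync_trans_i(solution, i)
    solution <- resample_states_i(solution, i)
  }

  trace <- vector("list", cfg$n_iterations)
  best <- NULL
  best_ll <- -Inf
  for (iter in seq_len(cfg$n_iterations)) {
    for (i in seq_len(N)) solution <- update_features(solution, i)
    for (i in seq_len(N)) solution <- resample_states_i(solution, i)
    solution <- resample_emissions(solution)
    solution <- resample_transitions(solution)
    solution <- prune_empty_states(solution)
    ll <- joint_log_likelihood(solution)
    trace[[iter]] <- c(iteration = iter, n_states = ncol(solution$F),
                       log_lik = ll)
    if (cfg$keep == "max_loglik" && ll >= best_ll) {
      best_ll <- ll
      best <- solution
      best$iteration <- iter
    }
    if (cfg$progress_every > 0 && iter %% cfg$progress_every == 0) {
      cli::cli_inform("sweep {iter}/{cfg$n_iterations}: K={ncol(solution$F)} log_lik={round(ll, 1)}")
    }
  }
  trace <- tibble::as_tibble(do.call(rbind, trace))
  if (cfg$keep == "max_loglik") {
    solution <- best
  } else {
    solution$iteration <- cfg$n_iterations
  }
  solution$trace <- trace
  solution
}

#' Fit the BP-HMM over a hyperparameter grid
#'
#' Runs one MCMC chain per combination of `gamma`, `kappa` and `lambda0`
#' (with `beta` and `alpha` held fixed). The default grid is
#' `gamma = {2,3,4,5}` x `kappa = {50,100,200}` x `lambda0 = {2,3,5,10}`,
#' i.e. 48 chains. Each combination's seed is derived deterministically from
#' the base seed and the combination index, so individual runs are
#' independently reproducible.
#'
#' @inheritParams run_mcmc
#' @param gamma,kappa,lambda0 Value grids.
#' @param beta,alpha Fixed values shared by all combinations.
#' @return A tibble with one row per combination: the hyperparameter values,
#'   the derived `seed`, the fitted `n_states`, final `log_lik`, and the
#'   solution itself in the `solution` list-column.
#' @export
run_grid <- function(data, gamma = c(2, 3, 4, 5), kappa = c(50, 100, 200),
                     lambda0 = c(2, 3, 5, 10), beta = 1, alpha = 1,
                     cfg = bp_mcmc_config(), alphabet_size = NULL) {
  combos <- tidyr::expand_grid(gamma = gamma, kappa = kappa,
                               lambda0 = lambda0)
  if (nrow(combos) == 0) cli::cli_abort("the hyperparameter grid is empty")
  combos$seed <- cfg$seed + 101L * seq_len(nrow(combos))
  combos$solution <- purrr::pmap(combos, function(gamma, kappa, lambda0, seed) {
    cfg_i <- cfg
    cfg_i$seed <- seed
    run_mcmc(data,
             bp_hyperparams(gamma = gamma, beta = beta, kappa = kappa,
                            alpha = alpha, lambda0 = lambda0),
             cfg_i, alphabet_size = alphabet_size)
  })
  combos$beta <- beta
  combos$alpha <- alpha
  combos$n_states <- purrr::map_int(combos$solution, n_states)
  combos$log_lik <- purrr::map_dbl(combos$solution, joint_log_likelihood)
  combos[, c("gamma", "beta", "kappa", "alpha", "lambda0", "seed",
             "n_states", "log_lik", "solution")]
}

# Normalize the two accepted ensemble representations.
as_symbol_ensemble <- function(data, alphabet_size = NULL) {
  if (is.data.frame(data)) {
    if (!all(c("session_id", "symbol") %in% names(data))) {
      cli::cli_abort("encoded data needs {.field session_id} and {.field symbol} columns")
    }
    codebook <- attr(data, "codebook")
    ids <- unique(data$session_id)
    seqs <- lapply(ids, function(id) {
      as.integer(data$symbol[data$session_id == id])
    })
    names(seqs) <- ids
  } else if (is.list(data)) {
    codebook <- attr(data, "codebook")
    seqs <- lapply(data, as.integer)
    ids <- names(seqs) %||% as.character(seq_along(seqs))
  } else {
    cli::cli_abort("data must be an encoded tibble or a list of symbol vectors")
  }
  M <- alphabet_size %||%
    (if (!is.null(codebook)) alphabet_size(codebook) else
       if (length(seqs) > 0) max(unlist(seqs)) else 0L)
  list(seqs = seqs, ids = ids, M = as.integer(M), codebook = codebook)
}
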