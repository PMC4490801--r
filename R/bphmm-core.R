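# Dirichlet draw via normalized Gammas. The sticky transition construction
# eta_jk ~ Gamma(alpha + kappa*delta(j,k), 1) normalized over active
# features is distributionally identical to Dirichlet(alpha + kappa*delta),
# which is what this helper realizes.
rdirichlet_one <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  s <- sum(g)
  if (s == 0) {
    # numerically degenerate for very small shapes: fall back to the
    # argmax of a Gumbel-perturbed log-shape, a one-hot draw
    out <- numeric(length(shape))
    out[which.max(log(shape) + stats::rexp(length(shape)))] <- 1
    return(out)
  }
  g / s
}

# One sticky transition matrix over L active features.
sample_sticky_transitions <- function(L, alpha, kappa) {
  P <- matrix(0, L, L)
  for (j in seq_len(L)) {
    shape <- rep(alpha, L)
    shape[j] <- shape[j] + kappa
    P[j, ] <- rdirichlet_one(shape)
  }
  P
}

# Indian buffet process draw of a binary feature matrix: row i activates an
# existing feature k with probability m_k / (beta + i - 1), where m_k counts
# activations among earlier rows, and adds Poisson(gamma*beta/(beta+i-1))
# new features. Rows left featureless are repaired with one feature chosen
# uniformly among existing columns (or one new feature if none exist yet).
sample_ibp_matrix <- function(gamma, beta, n_seq) {
  F <- matrix(0L, nrow = n_seq, ncol = 0)
  for (i in seq_len(n_seq)) {
    K <- ncol(F)
    row <- integer(K)
    if (K > 0 && i > 1) {
      m <- colSums(F[seq_len(i - 1), , drop = FALSE])
      row <- as.integer(stats::runif(K) < m / (beta + i - 1))
    }
    n_new <- stats::rpois(1, gamma * beta / (beta + i - 1))
    if (n_new > 0) {
      F <- cbind(F, matrix(0L, nrow = n_seq, ncol = n_new))
      row <- c(row, rep(1L, n_new))
    } else if (K > 0) {
      row <- c(row, integer(ncol(F) - length(row)))
    }
    if (sum(row) == 0) {
      if (length(row) == 0) {
        F <- cbind(F, matrix(0L, nrow = n_seq, ncol = 1))
        row <- 1L
      } else {
        row[sample.int(length(row), 1)] <- 1L
      }
    }
    F[i, seq_along(row)] <- row
  }
  # drop columns never used (possible when later rows decline early dishes)
  if (ncol(F) > 0) F <- F[, colSums(F) > 0, drop = FALSE]
  F
}

#' Sample a BP-HMM from its prior
#'
#' Draws a full model configuration: a binary feature matrix from the
#' Indian-buffet-process scheme with mass `gamma` and concentration `beta`,
#' symmetric-Dirichlet(`lambda0`) emission rows over the `M`-symbol
#' alphabet, and per-sequence sticky transition rows
#' Dirichlet(`alpha` + `kappa` on the self-transition) over each sequence's
#' active features, with Dirichlet(`alpha`) initial distributions.
#'
#' @param hyper A [bp_hyperparams()] object.
#' @param n_seq Number of sequences (rows of the feature matrix).
#' @param M Alphabet size.
#' @param seed Integer seed.
#' @return List with elements `F` (n_seq x K binary matrix), `theta`
#'   (K x M emission rows), `trans` and `pi0` (per-sequence lists over
#'   active features in ascending order).
#' @export
sample_from_prior <- function(hyper, n_seq, M, seed = 1L) {
  stopifnot(inherits(hyper, "bp_hyperparams"), n_seq >= 1, M >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  F <- sample_ibp_matrix(hyper$gamma, hyper$beta, n_seq)
  K <- ncol(F)
  theta <- t(vapply(seq_len(K),
                    function(k) rdirichlet_one(rep(hyper$lambda0, M)),
                    numeric(M)))
  trans <- vector("list", n_seq)
  pi0 <- vector("list", n_seq)
  for (i in seq_len(n_seq)) {
    L <- sum(F[i, ])
    trans[[i]] <- sample_sticky_transitions(L, hyper$alpha, hyper$kappa)
    pi0[[i]] <- rdirichlet_one(rep(hyper$alpha, L))
  }
  list(F = F, theta = theta, trans = trans, pi0 = pi0)
}

#' Sample an observation sequence from one HMM
#'
#' Generative draw for a single sequence: the initial state from `pi0`, each
#' following state from its transition row, and each symbol from the active
#' state's emission distribution.
#'
#' @param theta K x M emission library (rows for all global states).
#' @param trans L x L transition matrix over the sequence's active features.
#' @param pi0 Initial distribution over the active features.
#' @param active Ascending global indices of the active features (length L).
#' @param n_events Sequence length (>= 1).
#' @param seed Optional integer seed; when `NULL` the ambient RNG stream is
#'   used.
#' @return Tibble with columns `position`, `state` (global index), `symbol`.
#' @export
sample_sequence <- function(theta, trans, pi0, active, n_events, seed = NULL) {
  L <- length(active)
  stopifnot(n_events >= 1, nrow(trans) == L, ncol(trans) == L,
            length(pi0) == L, all(active <= nrow(theta)))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  M <- ncol(theta)
  z <- integer(n_events)
  x <- integer(n_events)
  z[1] <- sample.int(L, 1, prob = pi0)
  for (t in seq_len(n_events)[-1]) {
    z[t] <- sample.int(L, 1, prob = trans[z[t - 1], ])
  }
  for (t in seq_len(n_events)) {
    x[t] <- sample.int(M, 1, prob = theta[active[z[t]], ])
  }
  tibble::tibble(position = seq_len(n_events),
                 state = active[z],
                 symbol = x)
}

# Emission-probability matrix (T x L) for a symbol vector under the active
# subset of the emission library.
emission_probs <- function(symbols, theta, active) {
  t(theta[active, symbols, drop = FALSE])
}

#' Marginal log-likelihood of a symbol sequence
#'
#' Computes `log p(symbols | theta, trans, pi0)` by the forward recursion
#' with per-step scaling, marginalizing over the hidden path. An impossible
#' sequence (some symbol with zero mass in every reachable state) yields
#' `-Inf`.
#'
#' @param symbols Integer vector of symbols in `1:ncol(theta)`.
#' @inheritParams sample_sequence
#' @return Log-probability (scalar).
#' @export
sequence_log_likelihood <- function(symbols, theta, trans, pi0, active) {
  M <- ncol(theta)
  if (any(symbols < 1 | symbols > M)) {
    cli::cli_abort("symbols must lie in 1..{M}")
  }
  L <- length(active)
  stopifnot(nrow(trans) == L, ncol(trans) == L, length(pi0) == L)
  fwd_loglik_cpp(emission_probs(symbols, theta, active), trans, pi0)
}

# Joint log-likelihood of every sequence under the current parameters.
joint_log_likelihood <- function(solution) {
  sum(vapply(seq_along(solution$seqs), function(i) {
    act <- active_features(solution, i)
    fwd_loglik_cpp(emission_probs(solution$seqs[[i]], solution$theta, act),
                   solution$trans[[i]], solution$pi0[[i]])
  }, numeric(1)))
}
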