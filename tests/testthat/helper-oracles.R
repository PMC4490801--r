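# Independent brute-force oracles and small fixture builders shared across
# the test files. The oracles enumerate hidden paths directly and never call
# the package's recursions.

# All length-T paths over states 1..L, one per row.
all_paths <- function(L, T) {
  as.matrix(expand.grid(rep(list(seq_len(L)), T)))
}

# log p(symbols) by explicit summation over every hidden path.
enum_loglik <- function(symbols, theta, trans, pi0, active) {
  T <- length(symbols)
  L <- length(active)
  paths <- all_paths(L, T)
  probs <- apply(paths, 1, function(z) {
    p <- pi0[z[1]] * theta[active[z[1]], symbols[1]]
    if (T > 1) {
      for (t in 2:T) {
        p <- p * trans[z[t - 1], z[t]] * theta[active[z[t]], symbols[t]]
      }
    }
    p
  })
  log(sum(probs))
}

# Joint probability of one specific path with the observations.
path_joint_prob <- function(z, symbols, theta, trans, pi0, active) {
  p <- pi0[z[1]] * theta[active[z[1]], symbols[1]]
  if (length(z) > 1) {
    for (t in 2:length(z)) {
      p <- p * trans[z[t - 1], z[t]] * theta[active[z[t]], symbols[t]]
    }
  }
  p
}

# Brute-force most probable path (local state indices).
enum_viterbi <- function(symbols, theta, trans, pi0, active) {
  paths <- all_paths(length(active), length(symbols))
  probs <- apply(paths, 1, path_joint_prob, symbols = symbols, theta = theta,
                 trans = trans, pi0 = pi0, active = active)
  unname(as.integer(paths[which.max(probs), ]))
}

rdir <- function(shape) {
  g <- stats::rgamma(length(shape), shape, rate = 1)
  g / sum(g)
}

# A random fully-specified single-sequence HMM instance.
random_instance <- function(K = NULL, T = NULL, M = 4) {
  K <- K %||% sample(1:3, 1)
  T <- T %||% sample(2:6, 1)
  theta <- t(vapply(seq_len(K), function(k) rdir(rep(1, M)), numeric(M)))
  trans <- t(vapply(seq_len(K), function(k) rdir(rep(1, K)), numeric(K)))
  pi0 <- rdir(rep(1, K))
  list(K = K, T = T, M = M, theta = theta, trans = trans, pi0 = pi0,
       symbols = sample.int(M, T, replace = TRUE), active = seq_len(K))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Minimal event tibble for the log-processing tests.
make_events <- function(timestamp, activity, session_id = "s1",
                        subject_id = "p1", interface = "wiggle",
                        instruction = "none") {
  tibble::tibble(session_id = session_id, subject_id = subject_id,
                 interface = interface, instruction = instruction,
                 timestamp = timestamp, activity = activity)
}

# Bare solution carrying only what model selection needs.
fake_solution <- function(theta) {
  bphmm:::new_bphmm_solution(
    hyper = bp_hyperparams(), F = matrix(1L, 1, nrow(theta)),
    theta = theta, trans = list(diag(nrow(theta))),
    pi0 = list(rep(1 / nrow(theta), nrow(theta))),
    z = list(1L), seqs = list(1L), M = ncol(theta),
    sequence_ids = "s1", seed = 1L
  )
}

# Fully specified solution with F fixed (no feature moves), used by the
# Gibbs-block tests. Weights are drawn from the prior.
fixed_f_solution <- function(seqs, M, K, hyper = bp_hyperparams(),
                             seed = 1) {
  set.seed(seed)
  N <- length(seqs)
  F <- matrix(1L, N, K)
  theta <- t(vapply(seq_len(K), function(k) rdir(rep(hyper$lambda0, M)),
                    numeric(M)))
  sol <- bphmm:::new_bphmm_solution(
    hyper = hyper, F = F, theta = theta,
    trans = vector("list", N), pi0 = vector("list", N),
    z = vector("list", N), seqs = lapply(seqs, as.integer), M = M,
    sequence_ids = as.character(seq_len(N)), seed = as.integer(seed)
  )
  sol$eta <- lapply(seq_len(N), function(i)
    bphmm:::prior_eta_matrix(K, hyper$alpha, hyper$kappa))
  sol$eta0 <- lapply(seq_len(N), function(i)
    stats::rgamma(K, hyper$alpha, rate = 1))
  for (i in seq_len(N)) {
    sol <- bphmm:::sync_trans_i(sol, i)
    sol <- bphmm:::resample_states_i(sol, i)
  }
  sol
}

# Tiny deterministic codebook: k centroids per activity at fixed values.
toy_codebook <- function(k = 2, vocabulary = wiggle_vocabulary()) {
  centroids <- stats::setNames(
    lapply(seq_along(vocabulary), function(a) seq_len(k)),
    as.character(vocabulary))
  bphmm:::new_codebook(centroids, k = k, seed = 1L, vocabulary = vocabulary)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# Best one-to-one matching of template rows to fitted rows by total
# variation, by enumeration over assignments.
matched_tv <- function(templates, fitted) {
  a <- nrow(templates)
  stopifnot(nrow(fitted) >= a)
  D <- outer(seq_len(a), seq_len(nrow(fitted)),
             Vectorize(function(i, j) total_variation(templates[i, ],
                                                      fitted[j, ])))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  best <- rep(Inf, a)
  for (cols in utils::combn(seq_len(nrow(fitted)), a, simplify = FALSE)) {
    for (p in perms(cols)) {
      tvs <- vapply(seq_len(a), function(i) D[i, p[i]], numeric(1))
      if (sum(tvs) < sum(best)) best <- tvs
    }
  }
  best
}
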