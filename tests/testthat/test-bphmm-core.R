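test_that("prior feature counts follow the Indian buffet marginals", {
  set.seed(42)
  draws <- replicate(400, {
    rowSums(bphmm:::sample_ibp_matrix(3, 1, 5))
  })
  counts <- as.numeric(draws)  # 2000 per-sequence active-feature counts
  # counts within one ensemble are correlated, so the standard error is
  # taken over independent ensemble means; the featureless-row repair adds
  # a small positive bias bounded by ~2 * P(Poisson(3) = 0)
  se <- stats::sd(colMeans(draws)) / sqrt(ncol(draws))
  expect_lt(abs(mean(counts) - 3), 3 * se + 2 * exp(-3))

  # mean new features for row i is gamma*beta/(beta+i-1)
  set.seed(43)
  new_per_row <- replicate(2000, {
    F <- bphmm:::sample_ibp_matrix(2, 1, 4)
    # count features first activated at each row
    first <- apply(F, 2, function(col) which(col == 1)[1])
    vapply(1:4, function(i) sum(first == i), numeric(1))
  })
  means <- rowMeans(new_per_row)
  expected <- 2 * 1 / (1 + (1:4) - 1)
  # row 1 carries the featureless-row repair, so allow its small bias
  expect_lt(max(abs(means - expected) - c(0.15, 0, 0, 0)), 0.12)
})

test_that("sticky transition rows have the stated Dirichlet means", {
  set.seed(7)
  # kappa = 0: symmetric rows
  rows <- replicate(4000, bphmm:::sample_sticky_transitions(2, 1, 0)[1, 1])
  expect_lt(abs(mean(rows) - 0.5), 0.03)
  # alpha = 1, kappa = 200, L = 2: self-transition mean 201/202
  self <- replicate(4000, bphmm:::sample_sticky_transitions(2, 1, 200)[1, 1])
  expect_lt(abs(mean(self) - 201 / 202), 3 * stats::sd(self) / sqrt(4000))
})

test_that("sample_from_prior returns a structurally valid model", {
  hyper <- bp_hyperparams(gamma = 2, kappa = 50)
  prior <- sample_from_prior(hyper, n_seq = 6, M = 10, seed = 5)
  expect_true(all(rowSums(prior$F) >= 1))
  expect_equal(nrow(prior$theta), ncol(prior$F))
  expect_equal(rowSums(prior$theta), rep(1, nrow(prior$theta)),
               tolerance = 1e-12)
  for (i in 1:6) {
    L <- sum(prior$F[i, ])
    expect_equal(dim(prior$trans[[i]]), c(L, L))
    expect_equal(rowSums(prior$trans[[i]]), rep(1, L), tolerance = 1e-12)
    expect_equal(sum(prior$pi0[[i]]), 1, tolerance = 1e-12)
  }
  expect_error(sample_from_prior(hyper, n_seq = 0, M = 5), "n_seq")
})

test_that("sample_sequence respects degenerate parameterizations", {
  theta <- rbind(c(1, 0, 0), c(0, 1, 0))
  # one active feature: constant hidden path
  out <- sample_sequence(theta, matrix(1, 1, 1), 1, active = 2L,
                         n_events = 20, seed = 1)
  expect_true(all(out$state == 2L))
  expect_true(all(out$symbol == 2L))

  # one-hot emissions make symbols determine the path
  trans <- matrix(0.5, 2, 2)
  out2 <- sample_sequence(theta, trans, c(0.5, 0.5), active = 1:2,
                          n_events = 50, seed = 2)
  expect_equal(out2$symbol, out2$state)

  # long single-state draw converges to theta in total variation
  th <- rbind(c(0.5, 0.3, 0.2))
  out3 <- sample_sequence(th, matrix(1, 1, 1), 1, active = 1L,
                          n_events = 10000, seed = 3)
  freq <- tabulate(out3$symbol, 3) / 10000
  expect_lt(total_variation(freq, th[1, ]), 0.05)
})

test_that("forward likelihood matches path enumeration and handles zeros", {
  # single state, uniform emissions
  theta <- matrix(0.25, 1, 4)
  ll <- sequence_log_likelihood(c(1L, 3L, 2L), theta, matrix(1, 1, 1), 1,
                                active = 1L)
  expect_equal(ll, 3 * log(0.25), tolerance = 1e-12)

  # fixed K=2, M=2, T=4 instance against the 16-path enumeration
  set.seed(99)
  inst <- random_instance(K = 2, T = 4, M = 2)
  ll_fwd <- sequence_log_likelihood(inst$symbols, inst$theta, inst$trans,
                                    inst$pi0, inst$active)
  expect_equal(ll_fwd, enum_loglik(inst$symbols, inst$theta, inst$trans,
                                   inst$pi0, inst$active),
               tolerance = 1e-10)

  # impossible symbol has zero likelihood
  theta0 <- rbind(c(0.5, 0.5, 0, 0))
  expect_identical(
    sequence_log_likelihood(c(1L, 3L), theta0, matrix(1, 1, 1), 1, 1L),
    -Inf)
  expect_error(
    sequence_log_likelihood(c(1L, 9L), theta0, matrix(1, 1, 1), 1, 1L),
    "1..4")
})

test_that("likelihood is invariant under relabeling of active features", {
  set.seed(17)
  for (rep in 1:20) {
    inst <- random_instance(K = 3, T = 5, M = 3)
    perm <- sample(3)
    ll1 <- sequence_log_likelihood(inst$symbols, inst$theta, inst$trans,
                                   inst$pi0, 1:3)
    ll2 <- sequence_log_likelihood(inst$symbols, inst$theta[perm, ],
                                   inst$trans[perm, perm], inst$pi0[perm],
                                   1:3)
    expect_equal(ll1, ll2, tolerance = 1e-10)
  }
})

test_that("solutions round-trip through JSON and validate", {
  truth <- ground_truth(n_subjects = 3, sessions_per_subject = 1)
  sim <- simulate_ensemble(truth, seed = 21, n_events = 60)
  feats <- compute_intervals(recode_selections(sim$events))
  cb <- fit_codebook(feats, k = 3, seed = 1)
  fit <- run_mcmc(encode_symbols(feats, cb), bp_hyperparams(),
                  bp_mcmc_config(n_iterations = 20, seed = 2))
  validate_solution(fit)
  path <- withr::local_tempfile(fileext = ".json")
  write_solution(fit, path)
  back <- read_solution(path)
  expect_equal(back$F, fit$F, ignore_attr = TRUE)
  expect_equal(back$theta, fit$theta, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$z, fit$z)
  expect_equal(joint_log_likelihood <- bphmm:::joint_log_likelihood(back),
               bphmm:::joint_log_likelihood(fit), tolerance = 1e-9)

  g <- glance(fit)
  expect_equal(g$n_states, n_states(fit))
  td <- tidy(fit)
  expect_equal(nrow(td), n_states(fit) * fit$M)
  expect_true(all(c("activity", "centroid") %in% names(td)))
})
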