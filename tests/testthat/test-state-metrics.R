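test_that("viterbi_decode matches brute-force argmax and is optimal", {
  set.seed(23)
  inst <- random_instance(K = 2, T = 4, M = 3)
  sol <- fixed_f_solution(list(inst$symbols), M = 3, K = 2, seed = 23)
  sol$theta <- inst$theta
  sol$trans <- list(inst$trans)
  sol$pi0 <- list(inst$pi0)
  path <- viterbi_decode(sol, 1)
  expect_equal(unname(path),
               enum_viterbi(inst$symbols, inst$theta, inst$trans,
                            inst$pi0, 1:2))

  # decoded path beats random paths in joint probability
  best <- path_joint_prob(path, inst$symbols, inst$theta, inst$trans,
                          inst$pi0, 1:2)
  rand <- replicate(100, path_joint_prob(sample.int(2, 4, replace = TRUE),
                                         inst$symbols, inst$theta,
                                         inst$trans, inst$pi0, 1:2))
  expect_true(all(best >= rand))

  # single active feature: constant path
  sol1 <- fixed_f_solution(list(c(1L, 2L)), M = 2, K = 1, seed = 1)
  expect_equal(viterbi_decode(sol1, 1), c(1L, 1L))
})

test_that("time_in_states weights by elapsed time", {
  expect_equal(time_in_states(c(1L, 1L, 2L), c(2, 2, 6), 3),
               c(0.4, 0.6, 0))
  expect_equal(time_in_states(rep(2L, 4), rep(1, 4), 2), c(0, 1))
  expect_error(time_in_states(1L, 0, 1), "zero")
  # event weighting alternative
  expect_equal(time_in_states(c(1L, 1L, 2L), c(2, 2, 6), 2,
                              weight = "events"),
               c(2 / 3, 1 / 3))
  # output is a probability vector for random cases
  set.seed(2)
  for (r in 1:10) {
    p <- time_in_states(sample.int(4, 30, replace = TRUE), runif(30), 4)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("excess kurtosis matches hand evaluations and the G2 oracle", {
  expect_equal(excess_kurtosis(c(0, 0, 0.5, 0.5)), -6)
  expect_equal(excess_kurtosis(c(0, 0, 0, 1)), 4)
  expect_error(excess_kurtosis(rep(0.25, 4)), "zero variance")
  # independent implementation: e1071's bias-corrected type 2
  set.seed(4)
  for (r in 1:25) {
    x <- runif(sample(4:9, 1))
    expect_equal(excess_kurtosis(x), e1071::kurtosis(x, type = 2),
                 tolerance = 1e-10)
  }
})

test_that("collapse_to_activities sums the activity blocks", {
  cb <- toy_codebook(k = 15)
  expect_equal(unname(collapse_to_activities(rep(1 / 60, 60), cb)),
               rep(0.25, 4))
  one_hot <- numeric(60)
  one_hot[50] <- 1  # a wiggle symbol (block 4: symbols 46-60)
  expect_equal(unname(collapse_to_activities(one_hot, cb)), c(0, 0, 0, 1))
  set.seed(5)
  p <- rdir(rep(1, 60))
  expect_equal(sum(collapse_to_activities(p, cb)), 1, tolerance = 1e-12)
})

test_that("the two classifiers agree on clearly peaked vs spread states", {
  cb <- toy_codebook(k = 15)
  spread <- rep(1 / 60, 60)
  peaked1 <- numeric(60); peaked1[1:3] <- c(0.6, 0.3, 0.1)   # all Sel
  peaked2 <- numeric(60); peaked2[46:48] <- c(0.5, 0.4, 0.1) # all W
  near_uniform <- c(rep(0.3 / 15, 15), rep(0.2 / 15, 15),
                    rep(0.3 / 15, 15), rep(0.2 / 15, 15))
  theta <- rbind(spread, peaked1, peaked2, near_uniform)
  k <- classify_states(theta, cb, method = "kurtosis")
  m <- classify_states(theta, cb, method = "max_average")
  expect_equal(k$label, m$label)
  expect_equal(k$label, c("diffuse", "peaked", "peaked", "diffuse"))
  # zero-variance profile is diffuse with NA statistic under kurtosis
  expect_true(is.na(k$statistic[1]))
  expect_equal(k$threshold[1], -1.2)
})

test_that("the packaged state table reproduces the published labels", {
  t5 <- load_fixture("table5")
  peaked_k <- t5$state[t5$kurtosis > uniform_excess_kurtosis()]
  expect_equal(peaked_k, c(1, 5, 8, 9, 10))
  thr <- mean(t5$max_average)
  expect_equal(round(thr, 3), 0.039)
  peaked_m <- t5$state[t5$max_average > thr]
  expect_equal(peaked_m, peaked_k)  # both methods give the same decisions
})

test_that("peaked-time fractions follow the occupancy fixture", {
  occ <- occupancy_fixture()
  peaked <- c(1, 5, 8, 9, 10)
  pk <- session_peakedness(occ, peaked)
  row <- function(subj, sess) {
    pk$peaked_fraction[pk$subject_id == subj & pk$session == sess]
  }
  expect_equal(row("9", 1), 0)     # all time in diffuse state 2
  expect_equal(row("1", 1), 1)     # all time in peaked state 8
  expect_equal(row("4", 1), 0.71)  # 0.67 (state 1) + 0.04 (state 5)
  expect_equal(pk$peaked_fraction + pk$diffuse_fraction,
               rep(1, nrow(pk)))

  # scalar helper agrees
  expect_equal(peaked_time_fraction(c(0.67, 0.29, 0, 0, 0.04, 0, 0, 0, 0, 0),
                                    peaked), 0.71)
})

test_that("transition-category means follow the off-diagonal definition", {
  P <- rbind(c(0.90, 0.06, 0.04),
             c(0.10, 0.80, 0.10),
             c(0.20, 0.30, 0.50))
  labels <- c("peaked", "peaked", "diffuse")
  mm <- transition_category_means(P, labels)
  expect_equal(mm$within, mean(c(0.06, 0.10)))
  expect_equal(mm$between, mean(c(0.04, 0.10, 0.20, 0.30)))

  # two states of the same category: between missing
  mm2 <- transition_category_means(P[1:2, 1:2], c("peaked", "peaked"))
  expect_equal(mm2$within, mean(c(0.06, 0.10)))
  expect_true(is.na(mm2$between))

  # single state: both missing
  mm1 <- transition_category_means(matrix(1, 1, 1), "peaked")
  expect_true(is.na(mm1$within) && is.na(mm1$between))
})

test_that("sticky ensembles favor within-category transitions", {
  truth <- ground_truth(n_subjects = 8, sessions_per_subject = 1)
  sim <- simulate_ensemble(truth, seed = 33, n_events = 250)
  feats <- compute_intervals(recode_selections(sim$events))
  cb <- fit_codebook(feats, k = 6, seed = 33, auto_reduce = TRUE)
  fit <- run_mcmc(encode_symbols(feats, cb), bp_hyperparams(),
                  bp_mcmc_config(n_iterations = 300, seed = 33))
  cls <- classify_states(fit, cb)
  stats <- transition_category_stats(fit, cls)
  ok <- !is.na(stats$within_mean) & !is.na(stats$between_mean)
  expect_gt(sum(ok), 0)
  expect_gt(mean(stats$within_mean[ok] > stats$between_mean[ok]), 0.5)
})

test_that("success flags respect the occupancy threshold", {
  occ <- occupancy_fixture()
  flags <- success_flags(occ, success_states = c(3, 4, 6), epsilon = 0.05)
  expect_true(flags$successful[flags$subject_id == "8"])   # state 6 = 0.65
  expect_false(flags$successful[flags$subject_id == "9"])  # never in 3/4/6
  expect_false(flags$successful[flags$subject_id == "5"])  # 0.04 < 0.05
})

test_that("pearson_r validates its input", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  x <- c(1, 2, 4, 5, 7)
  y <- c(2, 1, 5, 4, 8)
  expect_equal(pearson_r(x, y), stats::cor(x, y))
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "3 observations")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("activation_map is a pure permutation of F", {
  truth <- ground_truth(n_subjects = 6, sessions_per_subject = 1)
  sim <- simulate_ensemble(truth, seed = 41, n_events = 200)
  feats <- compute_intervals(recode_selections(sim$events))
  cb <- fit_codebook(feats, k = 5, seed = 41)
  fit <- run_mcmc(encode_symbols(feats, cb), bp_hyperparams(),
                  bp_mcmc_config(n_iterations = 200, seed = 41))
  sessions <- dplyr::distinct(sim$events[, c("session_id", "interface")])
  amap <- activation_map(fit, sessions)
  expect_equal(unname(amap$map),
               unname(fit$F[amap$row_order, amap$state_order]))
  # static rows come first
  expect_true(!is.unsorted(amap$interface != "static"))
  # wiggle mass ascends left to right
  expect_true(!is.unsorted(amap$wiggle_mass[amap$state_order]))

  # all-static ensemble: ordering is near-zero masses with ties by index
  truth_s <- ground_truth(n_subjects = 4, prop_wiggle = 0,
                          feature_plan = list(static = c(1, 2, 3),
                                              wiggle = c(1, 3, 4)))
  sim_s <- simulate_ensemble(truth_s, seed = 42, n_events = 150)
  feats_s <- compute_intervals(recode_selections(sim_s$events))
  cb_s <- fit_codebook(feats_s, k = 4, seed = 42, auto_reduce = TRUE)
  fit_s <- run_mcmc(encode_symbols(feats_s, cb_s), bp_hyperparams(),
                    bp_mcmc_config(n_iterations = 100, seed = 42))
  sess_s <- dplyr::distinct(sim_s$events[, c("session_id", "interface")])
  amap_s <- activation_map(fit_s, sess_s)
  expect_true(all(amap_s$wiggle_mass < 0.05))
})
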