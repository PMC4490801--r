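#' Pipeline configuration
#'
#' Assembles the knobs of the end-to-end pipeline with the package-wide
#' defaults: the 4-code vocabulary, a 50 ms recode window, 15 temporal
#' clusters per activity (60-symbol alphabet), the selected hyperparameter
#' combination gamma = 3, beta = 1, kappa = 200, lambda0 = 5 (alpha = 1),
#' 10,000 MCMC sweeps keeping the last sample, and the kurtosis classifier
#' with its -1.2 uniform benchmark.
#'
#' @param window Recode window in seconds.
#' @param k Temporal clusters per activity.
#' @param gamma,kappa,lambda0 Hyperparameter grids (scalars fit a single
#'   combination; vectors trigger a grid run).
#' @param beta,alpha Fixed hyperparameters.
#' @param n_iterations MCMC sweeps per combination.
#' @param seed Base seed for every random stage.
#' @param classification_method `"kurtosis"` or `"max_average"`.
#' @param success_epsilon Non-negligible occupancy threshold for
#'   [success_flags()].
#' @param vocabulary Activity codes.
#' @return A `bphmm_pipeline_config` list.
#' @export
pipeline_config <- function(window = 0.050, k = 15,
                            gamma = 3, kappa = 200, lambda0 = 5,
                            beta = 1, alpha = 1,
                            n_iterations = 10000, seed = 1L,
                            classification_method = "kurtosis",
                            success_epsilon = 0.05,
                            vocabulary = wiggle_vocabulary()) {
  structure(
    list(window = window, k = k, gamma = gamma, kappa = kappa,
         lambda0 = lambda0, beta = beta, alpha = alpha,
         n_iterations = n_iterations, seed = as.integer(seed),
         classification_method = classification_method,
         success_epsilon = success_epsilon,
         vocabulary = as.character(vocabulary),
         select_code = select_code_of(vocabulary),
         wiggle_code = wiggle_code_of(vocabulary)),
    class = "bphmm_pipeline_config"
  )
}

#' Desk-scale pipeline profile
#'
#' A reduced configuration for quick runs: single hyperparameter
#' combination, 500 sweeps, 8 clusters per activity. Useful for smoke tests
#' and examples; production analyses use [pipeline_config()] defaults.
#'
#' @param ... Overrides forwarded to [pipeline_config()].
#' @return A `bphmm_pipeline_config`.
#' @export
ci_profile <- function(...) {
  args <- utils::modifyList(list(k = 8, n_iterations = 500), list(...))
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Executes every stage in order — validate, recode, intervals, codebook,
#' encode, MCMC fit (grid when the config holds value vectors), group and
#' select representatives, decode, occupancy, classification, peaked-time
#' fractions, transition-category statistics, activity rates — and, when
#' `output_dir` is given, writes each intermediate artifact (sessions,
#' codebook JSON, solution JSONs, metric tables as CSV, the effective
#' configuration as YAML) beside a run log of seeds. A stage failure is
#' re-signalled with the stage name attached.
#'
#' @param events Raw event tibble (from [read_activity_log()] or
#'   [simulate_ensemble()]), or a path to a delimited log file.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for artifacts.
#' @return A list of pipeline artifacts: `events` (recoded, with deltas and
#'   symbols), `codebook`, `grid` (fit results tibble), `representatives`,
#'   `solution` (the representative of the modal feature count, or the
#'   single fit), `occupancy`, `classification`, `peakedness`,
#'   `transition_stats`, `rates`, `config`.
#' @export
run_pipeline <- function(events, config = pipeline_config(),
                         output_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cli::cli_abort("pipeline stage {.val {name}} failed",
                     parent = e)
    })
  }
  vocab <- config$vocabulary
  attr(vocab, "select") <- config$select_code
  attr(vocab, "wiggle") <- config$wiggle_code

  if (is.character(events) && length(events) == 1) {
    events <- stage("read", read_activity_log(events, vocabulary = vocab))
  }
  events <- stage("validate", validate_activity_log(events, vocabulary = vocab))
  recoded <- stage("recode",
                   recode_selections(events, window = config$window,
                                     vocabulary = vocab))
  feats <- stage("intervals", compute_intervals(recoded))
  codebook <- stage("codebook",
                    fit_codebook(feats, k = config$k, seed = config$seed,
                                 vocabulary = vocab, auto_reduce = TRUE))
  encoded <- stage("encode", encode_symbols(feats, codebook))

  cfg <- bp_mcmc_config(n_iterations = config$n_iterations,
                        seed = config$seed)
  grid <- stage("fit", run_grid(
    encoded, gamma = config$gamma, kappa = config$kappa,
    lambda0 = config$lambda0, beta = config$beta, alpha = config$alpha,
    cfg = cfg))
  reps <- stage("select", select_representatives(grid, seed = config$seed))
  # working solution: representative of the most common feature count
  modal <- reps$feature_count[which.max(reps$n_models)]
  solution <- reps$representative[[match(modal, reps$feature_count)]]

  classification <- stage("classify",
                          classify_states(solution, codebook,
                                          method = config$classification_method))
  occupancy <- stage("occupancy", state_occupancy(solution, encoded))
  peaked <- classification$state[classification$label == "peaked"]
  peakedness <- stage("peakedness", session_peakedness(occupancy, peaked))
  trans_stats <- stage("transition_stats",
                       transition_category_stats(solution, classification))
  rates <- stage("rates", activity_rate(recoded))

  artifacts <- list(events = encoded, codebook = codebook, grid = grid,
                    representatives = reps, solution = solution,
                    occupancy = occupancy, classification = classification,
                    peakedness = peakedness, transition_stats = trans_stats,
                    rates = rates, config = config)
  if (!is.null(output_dir)) {
    stage("write", write_pipeline_artifacts(artifacts, output_dir))
  }
  artifacts
}

write_pipeline_artifacts <- function(artifacts, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, ...)
  readr::write_csv(artifacts$events, p("encoded_events.csv"))
  write_codebook(artifacts$codebook, p("codebook.json"))
  for (r in seq_len(nrow(artifacts$grid))) {
    write_solution(artifacts$grid$solution[[r]],
                   p(sprintf("solution_%02d.json", r)))
  }
  write_solution(artifacts$solution, p("representative.json"))
  readr::write_csv(artifacts$occupancy, p("occupancy.csv"))
  readr::write_csv(artifacts$classification, p("classification.csv"))
  readr::write_csv(artifacts$peakedness, p("peakedness.csv"))
  readr::write_csv(artifacts$transition_stats, p("transition_stats.csv"))
  readr::write_csv(artifacts$rates, p("activity_rates.csv"))
  readr::write_csv(
    dplyr::select(artifacts$grid, -"solution"), p("grid_summary.csv"))
  yaml::write_yaml(unclass(artifacts$config), p("config.yaml"))
  invisible(output_dir)
}
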