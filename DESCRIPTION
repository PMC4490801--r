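Package: bphmm
Title: Beta-Process Hidden Markov Models for Time-Stamped Activity Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discovers shared behavioral states in ensembles of time-stamped
    software activity logs. Provides log ingestion with context-collapsing
    recoding of rapid select-then-act pairs, vector quantization of
    inter-event times into a discrete symbol alphabet, a sticky
    discrete-emission Beta-Process hidden Markov model (BP-HMM) fitted by
    Markov chain Monte Carlo over binary feature matrices, a model-selection
    procedure over hyperparameter grids, and derivative state metrics
    (peaked/diffuse classification by excess kurtosis, time-in-state
    occupancy, transition-category statistics, success heuristics). A
    synthetic-log generator and packaged reference tables make the full
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cli,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
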