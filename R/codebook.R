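#' Fit a temporal codebook by per-activity K-means
#'
#' Builds the discrete symbol alphabet used by the BP-HMM. The inter-event
#' intervals of the whole ensemble are pooled by activity code and each
#' activity's pool is clustered independently with 1-D K-means into `k`
#' temporal centroids. Symbols are ordered activity-block by activity-block
#' (in vocabulary order), and within each activity by increasing centroid
#' value (faster to slower), so with the default 4-code vocabulary and
#' `k = 15` the alphabet has 60 symbols.
#'
#' @param features Event tibble with `activity` and `delta` columns, normally
#'   the output of [compute_intervals()] over the full ensemble.
#' @param k Number of temporal clusters per activity (default 15).
#' @param seed Integer seed making the clustering deterministic.
#' @param vocabulary Activity codes fixing the block order of the alphabet.
#' @param auto_reduce If an activity has fewer distinct interval values than
#'   `k`, lower its cluster count to the distinct count (with a message)
#'   instead of erroring.
#' @param log_transform Cluster `log1p(delta)` instead of raw seconds
#'   (centroids are reported back on the seconds scale). Default off.
#' @return A `bphmm_codebook`: per-activity ascending centroids plus the
#'   symbol index map. Activities never observed get no centroids and
#'   contribute no symbols.
#' @export
fit_codebook <- function(features, k = 15, seed = 1L,
                         vocabulary = wiggle_vocabulary(),
                         auto_reduce = FALSE, log_transform = FALSE) {
  stopifnot(k >= 1)
  if (!all(c("activity", "delta") %in% names(features))) {
    cli::cli_abort("features must have {.field activity} and {.field delta} columns; run {.fn compute_intervals} first")
  }
  validate_activity_log_codes(features$activity, vocabulary)

  pools <- split(features$delta, factor(features$activity,
                                        levels = as.character(vocabulary)))
  centroids <- vector("list", length(vocabulary))
  names(centroids) <- as.character(vocabulary)

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)

  for (act in names(pools)) {
    x <- pools[[act]]
    if (length(x) == 0) {
      centroids[[act]] <- numeric(0)
      next
    }
    n_distinct <- length(unique(x))
    k_act <- k
    if (n_distinct < k) {
      if (!auto_reduce) {
        cli::cli_abort(paste0(
          "activity {.val {act}} has only {n_distinct} distinct interval ",
          "value{?s}, fewer than k = {k}; set {.arg auto_reduce = TRUE} to lower k"
        ))
      }
      k_act <- n_distinct
      cli::cli_inform("activity {.val {act}}: k reduced to {k_act} (distinct values)")
    }
    y <- if (log_transform) log1p(x) else x
    ctr <- if (k_act == n_distinct) {
      # every distinct value is its own cluster: the exact K-means optimum
      sort(unique(y))
    } else {
      fit <- stats::kmeans(y, centers = k_act, nstart = 10, iter.max = 100)
      sort(as.numeric(fit$centers))
    }
    if (log_transform) ctr <- expm1(ctr)
    centroids[[act]] <- ctr
  }

  new_codebook(centroids, k = k, seed = seed, vocabulary = vocabulary,
               log_transform = log_transform)
}

new_codebook <- function(centroids, k, seed, vocabulary, log_transform = FALSE) {
  sizes <- lengths(centroids)
  structure(
    list(
      centroids = centroids,
      k = k,
      seed = seed,
      vocabulary = as.character(vocabulary),
      select_code = select_code_of(vocabulary),
      wiggle_code = wiggle_code_of(vocabulary),
      offsets = stats::setNames(cumsum(c(0, utils::head(sizes, -1))),
                                names(centroids)),
      log_transform = log_transform
    ),
    class = "bphmm_codebook"
  )
}

#' @export
print.bphmm_codebook <- function(x, ...) {
  cat("<bphmm_codebook>\n")
  cat("  alphabet size:", alphabet_size(x), "symbols\n")
  for (act in names(x$centroids)) {
    ctr <- x$centroids[[act]]
    if (length(ctr) == 0) {
      cat(sprintf("  %-4s: (no observations)\n", act))
    } else {
      cat(sprintf("  %-4s: %d centroids, %.3f - %.3f s\n",
                  act, length(ctr), min(ctr), max(ctr)))
    }
  }
  invisible(x)
}

#' Alphabet size of a codebook
#'
#' @param codebook A `bphmm_codebook`.
#' @return Total number of symbols (sum of per-activity centroid counts).
#' @export
alphabet_size <- function(codebook) {
  stopifnot(inherits(codebook, "bphmm_codebook"))
  sum(lengths(codebook$centroids))
}

#' Encode interval features as alphabet symbols
#'
#' Maps each event to the symbol of its activity's nearest temporal centroid
#' (absolute difference; ties broken toward the lower, i.e. faster,
#' centroid). Encoding is deterministic given the codebook.
#'
#' @param features Event tibble with `activity` and `delta` columns.
#' @param codebook A fitted [fit_codebook()] object covering every activity
#'   present in `features`.
#' @return The input tibble with an integer `symbol` column in
#'   `1:alphabet_size(codebook)`; the codebook is attached as attribute
#'   `codebook` for downstream use.
#' @export
encode_symbols <- function(features, codebook) {
  stopifnot(inherits(codebook, "bphmm_codebook"))
  acts <- unique(features$activity)
  uncovered <- acts[!acts %in% names(codebook$centroids) |
                      lengths(codebook$centroids[acts]) == 0]
  if (length(uncovered) > 0) {
    cli::cli_abort("activity {.val {uncovered[1]}} has no centroids in the codebook")
  }
  symbol <- integer(nrow(features))
  for (act in acts) {
    idx <- which(features$activity == act)
    ctr <- codebook$centroids[[act]]
    d <- abs(outer(features$delta[idx], ctr, "-"))
    nearest <- max.col(-d, ties.method = "first")
    symbol[idx] <- codebook$offsets[[act]] + nearest
  }
  out <- dplyr::mutate(features, symbol = as.integer(symbol))
  attr(out, "codebook") <- codebook
  out
}

#' Decode symbols back to activity and centroid
#'
#' Inverse of the symbol index map: for each symbol, which activity block it
#' belongs to and which temporal centroid it stands for.
#'
#' @param symbol Integer vector of symbols in `1:alphabet_size(codebook)`.
#' @param codebook A `bphmm_codebook`.
#' @return Tibble with `symbol`, `activity`, `centroid_index`, `centroid`
#'   (seconds).
#' @export
symbol_info <- function(symbol, codebook) {
  stopifnot(inherits(codebook, "bphmm_codebook"))
  M <- alphabet_size(codebook)
  if (any(symbol < 1 | symbol > M | symbol != floor(symbol))) {
    cli::cli_abort("symbols must be integers in 1..{M}")
  }
  sizes <- lengths(codebook$centroids)
  act_of <- rep(names(sizes), sizes)
  idx_of <- unlist(lapply(sizes[sizes > 0], seq_len), use.names = FALSE)
  ctr_of <- unlist(codebook$centroids, use.names = FALSE)
  tibble::tibble(
    symbol = as.integer(symbol),
    activity = act_of[symbol],
    centroid_index = idx_of[symbol],
    centroid = ctr_of[symbol]
  )
}

#' Activity membership of every symbol
#'
#' @param codebook A `bphmm_codebook`.
#' @return Character vector of length `alphabet_size(codebook)` giving the
#'   activity owning each symbol.
#' @export
symbol_activities <- function(codebook) {
  sizes <- lengths(codebook$centroids)
  rep(names(sizes), sizes)
}

#' Serialize / restore a codebook
#'
#' The codebook is written as JSON holding the per-activity centroids,
#' `k`, the seed and the activity order.
#'
#' @param codebook A `bphmm_codebook`.
#' @param path File path.
#' @return `write_codebook()` returns `path` invisibly; `read_codebook()`
#'   returns the restored `bphmm_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "bphmm_codebook"))
  payload <- list(
    centroids = codebook$centroids,
    k = codebook$k,
    seed = codebook$seed,
    vocabulary = codebook$vocabulary,
    select_code = codebook$select_code,
    wiggle_code = codebook$wiggle_code,
    log_transform = codebook$log_transform
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- payload$vocabulary
  attr(vocab, "select") <- payload$select_code
  attr(vocab, "wiggle") <- payload$wiggle_code
  centroids <- lapply(payload$centroids, as.numeric)[vocab]
  new_codebook(centroids, k = payload$k, seed = payload$seed,
               vocabulary = vocab, log_transform = payload$log_transform)
}

validate_activity_log_codes <- function(activity, vocabulary) {
  bad <- which(!(activity %in% vocabulary))
  if (length(bad) > 0) {
    cli::cli_abort("unknown activity code {.val {activity[bad[1]]}} at row {bad[1]}")
  }
  invisible(TRUE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
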