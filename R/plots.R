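#' Plot a fitted solution's emission distributions
#'
#' Bar chart of each state's emission distribution over the symbol alphabet,
#' faceted by state and colored by activity block when a codebook is
#' attached — the standard way to read what a behavioral state does and how
#' fast it does it.
#'
#' @param object A `bphmm_solution`.
#' @param states Optional subset of states to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bphmm_solution <- function(object, states = NULL, ...) {
  d <- tidy.bphmm_solution(object)
  if (!is.null(states)) d <- dplyr::filter(d, .data$state %in% states)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$symbol,
                                       y = .data$probability))
  p <- if ("activity" %in% names(d)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$activity), width = 1)
  } else {
    p + ggplot2::geom_col(width = 1)
  }
  p +
    ggplot2::facet_wrap(ggplot2::vars(.data$state), labeller = "label_both") +
    ggplot2::labs(x = "symbol (activity x tempo)",
                  y = "emission probability") +
    ggplot2::theme_minimal()
}

#' Plot an activation map
#'
#' Tile plot of the ordered binary feature activation map: sessions as rows
#' (static interface on top), states as columns (wiggle mass increasing to
#' the right).
#'
#' @param object A `bphmm_activation_map` from [activation_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bphmm_activation_map <- function(object, ...) {
  d <- tibble::tibble(
    session = factor(rep(rownames(object$map), ncol(object$map)),
                     levels = rev(rownames(object$map))),
    state = factor(rep(colnames(object$map), each = nrow(object$map)),
                   levels = colnames(object$map)),
    active = as.integer(object$map) == 1
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$state, y = .data$session,
                                  fill = .data$active)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e8b57",
                                          `FALSE` = "white"),
                               guide = "none") +
    ggplot2::labs(x = "state (wiggle mass increasing)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot MCMC diagnostics
#'
#' Line plots of the per-sweep state count and joint log-likelihood trace
#' recorded by [run_mcmc()].
#'
#' @param solution A `bphmm_solution` with a trace.
#' @return A ggplot object.
#' @export
plot_trace <- function(solution) {
  stopifnot(inherits(solution, "bphmm_solution"),
            !is.null(solution$trace))
  d <- tidyr::pivot_longer(solution$trace, c("n_states", "log_lik"),
                           names_to = "quantity")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "sweep", y = NULL) +
    ggplot2::theme_minimal()
}
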