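#' Plot an early warning signal series
#'
#' Signal against the bifurcation parameter, the standard diagnostic view:
#' under critical slowing down the signal rises (falls towards a downward
#' transition) as the tipping point is approached.
#'
#' @param object A [signal_series()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sentinet_series <- function(object, ...) {
  kind <- attr(object, "kind")
  S <- attr(object, "node_set")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$parameter, y = .data$signal)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = attr(object, "parameter_name"),
      y = if (kind == "variance") "node-averaged sample variance" else "node-averaged sample SD",
      title = paste0("Early warning signal, S = {", paste(S, collapse = ", "), "}")
    ) +
    ggplot2::theme_minimal()
}

#' Plot candidate node sets: d against Kendall tau
#'
#' Scatter of the examined node sets of one size, the view used to judge
#' whether d (computable from two covariance snapshots) predicts tau (which
#' needs the whole series). The d-maximizer is highlighted.
#'
#' @param selection A [optimize_d()] result.
#' @param taus Kendall taus for the candidate sets, in the order of
#'   `selection$sets`.
#' @return A ggplot object.
#' @export
plot_tau_d <- function(selection, taus) {
  stopifnot(inherits(selection, "sentinet_selection"))
  df <- dplyr::mutate(selection$scores, tau = taus)
  best_key <- paste(selection$best$node_set, collapse = ",")
  best <- dplyr::filter(df, .data$node_set == best_key)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$tau)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = best$d, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = best$tau, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(data = best, colour = "firebrick", size = 2) +
    ggplot2::labs(
      x = "d", y = "Kendall tau",
      title = paste0("Node sets with n = ", selection$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot p1/p2 performance indices by node-set size
#'
#' @param experiment A [run_experiment()] tibble.
#' @return A ggplot object.
#' @export
plot_performance <- function(experiment) {
  summ <- summarize_experiment(experiment)
  long <- tidyr_pivot(summ)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$n, y = .data$value,
    colour = .data$index
  )) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "node-set size n", y = "index value",
      colour = NULL,
      title = "Performance of the d-maximizing node set (0 = best, 1 = random pick)"
    ) +
    ggplot2::theme_minimal()
}

# minimal long-format helper (avoids a tidyr dependency for one call)
tidyr_pivot <- function(summ) {
  dplyr::bind_rows(
    tibble::tibble(n = summ$n, index = "p1", value = summ$p1),
    tibble::tibble(n = summ$n, index = "p2", value = summ$p2)
  )
}
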