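#' Unbiased sample covariance of an L x N sample matrix
#'
#' Thin wrapper over [stats::cov()] (divisor `L - 1`), the estimator of the
#' equilibrium covariance `C` used throughout the selection stage.
#'
#' @param samples `L` x `N` numeric matrix; rows are observations.
#' @return Symmetric `N` x `N` matrix.
#' @export
sample_covariance <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) stop("need at least 2 samples (L >= 2)", call. = FALSE)
  cov(samples)
}

#' Score a node set by the d statistic from two covariance matrices
#'
#' Computes the signal moments of the node-averaged sample variance at the
#' two measurement points from `C1` and `C2` and forms the separability
#' statistic `d`.
#'
#' @param C1,C2 Covariance matrices of the same dimension (measurement
#'   points 1 and 2).
#' @param S Integer vector of node indices.
#' @param L Samples per node used for the variance estimates.
#' @return A list of class `scored_node_set` with `node_set`, `d`,
#'   `moments1`, `moments2`.
#' @export
score_node_set <- function(C1, C2, S, L) {
  stopifnot(all(dim(C1) == dim(C2)))
  m1 <- signal_moments(C1, S, L)
  m2 <- signal_moments(C2, S, L)
  structure(
    list(node_set = as.integer(S), d = d_statistic(m1, m2), moments1 = m1, moments2 = m2),
    class = "scored_node_set"
  )
}

#' @export
print.scored_node_set <- function(x, ...) {
  cat(
    "<scored_node_set> S = {", paste(x$node_set, collapse = ", "),
    "} d =", format(x$d), "\n"
  )
  invisible(x)
}

#' Enumerate or sample node sets of a given size
#'
#' All `choose(N, n)` sets when that count does not exceed `cap`, otherwise
#' `cap` distinct sets sampled uniformly at random. The scheme follows the
#' study design: exhaustive for `n <= 2` on a 50-node network, 5000 random
#' sets for `n` in 3..5.
#'
#' @param N Number of nodes.
#' @param n Set size, `1 <= n <= N`.
#' @param cap Maximum number of sets (default 5000).
#' @return List of sorted integer vectors, all distinct.
#' @export
enumerate_node_sets <- function(N, n, cap = 5000) {
  stopifnot(n >= 1, n <= N)
  total <- choose(N, n)
  if (total <= cap) {
    return(unname(as.list(as.data.frame(combn(N, n)))))
  }
  seen <- new.env(hash = TRUE)
  out <- vector("list", cap)
  got <- 0L
  while (got < cap) {
    S <- sort(sample.int(N, n))
    key <- paste(S, collapse = ".")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- S
    }
  }
  out
}

#' Maximize d over node sets of size n
#'
#' Scores every enumerated (or sampled) node set of size `n` with
#' [score_node_set()] and returns the maximizer, ties broken by
#' lexicographically smallest node set.
#'
#' @inheritParams score_node_set
#' @param n Node-set size.
#' @param cap Enumeration cap passed to [enumerate_node_sets()].
#' @param node_sets Optional list of candidate sets, overriding
#'   enumeration.
#' @return An object of class `sentinet_selection`: list with `best` (a
#'   `scored_node_set`), `scores` (tibble of all candidates: `node_set`
#'   label, `d`, `mu1`, `mu2`), `n`, `L`.
#' @export
optimize_d <- function(C1, C2, n, L, cap = 5000, node_sets = NULL) {
  if (is.null(node_sets)) node_sets <- enumerate_node_sets(nrow(C1), n, cap)
  scored <- purrr::map(node_sets, function(S) score_node_set(C1, C2, S, L))
  d <- purrr::map_dbl(scored, "d")
  keys <- purrr::map_chr(node_sets, function(S) {
    paste(sprintf("%06d", S), collapse = ".")
  })
  best_i <- order(-d, keys)[1]
  out <- structure(
    list(
      best = scored[[best_i]],
      scores = tibble::tibble(
        node_set = purrr::map_chr(node_sets, paste, collapse = ","),
        d = d,
        mu1 = purrr::map_dbl(scored, function(s) s$moments1$mean),
        mu2 = purrr::map_dbl(scored, function(s) s$moments2$mean)
      ),
      sets = node_sets, n = n, L = L
    ),
    class = "sentinet_selection"
  )
  out
}

#' @export
print.sentinet_selection <- function(x, ...) {
  cat(
    "<sentinet_selection> n =", x$n, "|", nrow(x$scores),
    "candidate sets | best S = {",
    paste(x$best$node_set, collapse = ", "), "} with d =",
    format(x$best$d), "\n"
  )
  invisible(x)
}

#' @rdname optimize_d
#' @param x A `sentinet_selection`.
#' @param ... Unused.
#' @export
tidy.sentinet_selection <- function(x, ...) {
  dplyr::arrange(x$scores, dplyr::desc(.data$d))
}

#' @rdname optimize_d
#' @export
glance.sentinet_selection <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_candidates = nrow(x$scores),
    best_set = paste(x$best$node_set, collapse = ","),
    d_max = x$best$d,
    d_mean = mean(x$scores$d)
  )
}

#' Large SD baseline selector
#'
#' Selects the `n` nodes with the largest sample standard deviation of
#' their state at the second measurement point. A strong baseline under
#' homogeneous noise, but under heterogeneous noise it favours inherently
#' noisy nodes whose signals carry proportionately large uncertainty.
#'
#' @param samples `L` x `N` sample matrix at the second measurement
#'   parameter value.
#' @param n Number of nodes to select.
#' @return Integer vector of node indices (ties broken by lowest index).
#' @export
large_sd_select <- function(samples, n) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) stop("need at least 2 samples (L >= 2)", call. = FALSE)
  sds <- apply(samples, 2, sd)
  sort(order(-sds, seq_along(sds))[seq_len(n)])
}

#' High/Low Input baseline selector
#'
#' Scores node `i` by its total input `sum_j w_ij x_j` from the other nodes
#' near the bifurcation point and selects the top `n` (`direction = "up"`,
#' for transitions from the lower state upward: double-well, SIS) or the
#' bottom `n` (`direction = "down"`: mutualistic, gene regulatory). Unlike
#' the d statistic and Large SD, this baseline requires the network
#' structure.
#'
#' @param net An igraph graph.
#' @param states Length-`N` state vector near the bifurcation point
#'   (typically the time-averaged states at the second measurement point).
#' @param n Number of nodes to select.
#' @param direction `"up"` or `"down"`.
#' @return Integer vector of node indices (ties broken by lowest index).
#' @export
high_low_input_select <- function(net, states, n, direction = c("up", "down")) {
  direction <- match.arg(direction)
  w <- net_adjacency(net)
  stopifnot(length(states) == nrow(w))
  input <- drop(w %*% states)
  ord <- if (direction == "up") {
    order(-input, seq_along(input))
  } else {
    order(input, seq_along(input))
  }
  sort(ord[seq_len(n)])
}
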