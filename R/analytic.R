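#' Closed-form toy models: two-node directed edge and three-node chain
#'
#' Both models place each node near the lower stable equilibrium of the
#' saddle-node normal form `dx/dt = r + x^2` (with `r < 0`), coupled through
#' terms `w (x_j + 1)`. They admit closed-form equilibria and stationary
#' covariances and are used to validate the node-set selection statistic.
#'
#' @name analytic_models
NULL

#' Equilibrium of the two-node directed model
#'
#' Node 1 drives node 2 through a directed edge of weight `w`; node 2 feels
#' the extra stress offset `delta_r`. The lower (stable) equilibrium is
#' `x1* = -sqrt(-r)` and `x2* = -sqrt(-r + delta_r + w (sqrt(-r) - 1))`.
#'
#' @param r Bifurcation parameter, negative (saddle-node at `r = 0`).
#' @param delta_r Nonnegative stress offset applied to node 2.
#' @param w Nonnegative coupling weight of the edge from node 1 to node 2.
#' @return Numeric vector `c(x1, x2)`, both negative.
#' @examples
#' two_node_equilibrium(-0.3, delta_r = 1, w = 0.5)
#' @export
two_node_equilibrium <- function(r, delta_r, w) {
  if (r >= 0) stop("`r` must be negative (below the bifurcation)", call. = FALSE)
  arg2 <- -r + delta_r + w * (sqrt(-r) - 1)
  if (arg2 <= 0) {
    stop("no lower equilibrium for node 2: -r + delta_r + w(sqrt(-r)-1) <= 0",
      call. = FALSE
    )
  }
  c(-sqrt(-r), -sqrt(arg2))
}

#' Stationary covariance of the two-node directed model
#'
#' Closed form obtained from the Lyapunov equation with the sign-flipped
#' Jacobian `A = [[-2 x1*, 0], [-w, -2 x2*]]` and `B = diag(sigma1, sigma2)`:
#' `C11 = -sigma1^2 / (4 x1*)`,
#' `C12 = sigma1^2 w / (8 x1* (x1* + x2*))`,
#' `C22 = -sigma1^2 w^2 / (16 x1* x2* (x1* + x2*)) - sigma2^2 / (4 x2*)`.
#' All entries are positive and diverge like `(-r)^(-1/2)` as `r -> 0-`.
#'
#' @inheritParams two_node_equilibrium
#' @param sigma1,sigma2 Noise intensities of nodes 1 and 2.
#' @return A 2x2 covariance matrix.
#' @export
two_node_covariance <- function(r, delta_r, w, sigma1, sigma2) {
  xs <- two_node_equilibrium(r, delta_r, w)
  x1 <- xs[1]
  x2 <- xs[2]
  C11 <- -sigma1^2 / (4 * x1)
  C12 <- sigma1^2 * w / (8 * x1 * (x1 + x2))
  C22 <- -sigma1^2 * w^2 / (16 * x1 * x2 * (x1 + x2)) - sigma2^2 / (4 * x2)
  matrix(c(C11, C12, C12, C22), 2, 2)
}

#' Drift matrix of the two-node model at its lower equilibrium
#'
#' @inheritParams two_node_equilibrium
#' @return The 2x2 sign-flipped Jacobian.
#' @export
two_node_drift_matrix <- function(r, delta_r, w) {
  xs <- two_node_equilibrium(r, delta_r, w)
  matrix(c(-2 * xs[1], -w, 0, -2 * xs[2]), 2, 2)
}

#' Lower bound on the first bifurcation of the three-node chain
#'
#' Closed form `r_c'' = 2 w (-(w + 1) + sqrt(w (w + 1)))`, a lower bound on
#' the tangency point `r_c` at which the chain loses its lower stable
#' equilibrium; for small `w` the two nearly coincide (about -0.082 at
#' `w = 0.05`).
#'
#' @param w Nonnegative coupling weight.
#' @return Nonpositive scalar.
#' @export
chain_bifurcation_bound <- function(w) {
  if (w < 0) stop("`w` must be nonnegative", call. = FALSE)
  2 * w * (-(w + 1) + sqrt(w * (w + 1)))
}

#' Equilibrium of the three-node chain
#'
#' Symmetric chain 1 - 2 - 3 with coupling `w`; by symmetry `x3* = x1*`. The
#' lower equilibrium solves `r + x1^2 + w (x2 + 1) = 0` and
#' `r + x2^2 + 2 w (x1 + 1) = 0`. Eliminating `x2` yields a quartic in `x1`;
#' the root with `x1, x2 < 0` whose sign-flipped Jacobian is positive
#' definite is the unique stable lower state, which exists for `r` below the
#' tangency point (see [chain_bifurcation_bound()]).
#'
#' @param r Bifurcation parameter.
#' @param w Positive coupling weight.
#' @return Numeric vector `c(x1, x2)` (with `x3 = x1`).
#' @examples
#' chain_equilibrium(-0.3, w = 0.05) # approx (-0.52452, -0.50246)
#' @export
chain_equilibrium <- function(r, w) {
  if (w <= 0) stop("`w` must be positive", call. = FALSE)
  # candidate x1 roots of the quartic from eliminating x2, plus the
  # decoupled seed (the quartic is ill-conditioned for small w, so every
  # candidate is polished by Newton on the 2-equation system)
  a <- r + w
  roots <- polyroot(c(a^2 + r * w^2 + 2 * w^3, 2 * w^3, 2 * a, 0, 1))
  seeds <- Re(roots[abs(Im(roots)) < 1e-6])
  seeds <- lapply(seeds, function(x1) c(x1, -(r + x1^2) / w - 1))
  if (r < 0) seeds <- c(seeds, list(rep(-sqrt(-r), 2)))
  stable <- NULL
  for (seed in seeds) {
    xs <- chain_newton(seed, r, w)
    if (is.null(xs) || xs[1] >= 0 || xs[2] >= 0) next
    A <- chain_drift_matrix_at(xs[1], xs[2], w)
    if (min(eigen(A, symmetric = TRUE, only.values = TRUE)$values) > 0) {
      stable <- rbind(stable, xs)
    }
  }
  if (is.null(stable)) {
    stop("no stable lower equilibrium: r = ", r,
      " is above the bifurcation point of the chain (r_c'' = ",
      format(chain_bifurcation_bound(w)), ")",
      call. = FALSE
    )
  }
  # stability singles out one branch; if round-off yields near-duplicates,
  # take the one closest to the decoupled root -sqrt(-r)
  if (nrow(stable) > 1) {
    ref <- if (r < 0) -sqrt(-r) else 0
    stable <- stable[which.min(abs(stable[, 1] - ref)), , drop = FALSE]
  }
  unname(drop(stable))
}

# Newton iteration on F = (r + x1^2 + w(x2+1), r + x2^2 + 2w(x1+1))
chain_newton <- function(xs, r, w, max_iter = 60, tol = 1e-13) {
  for (it in seq_len(max_iter)) {
    f <- c(
      r + xs[1]^2 + w * (xs[2] + 1),
      r + xs[2]^2 + 2 * w * (xs[1] + 1)
    )
    if (max(abs(f)) < tol) {
      return(xs)
    }
    J <- matrix(c(2 * xs[1], 2 * w, w, 2 * xs[2]), 2, 2)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      return(NULL)
    }
    xs <- xs - step
  }
  NULL
}

chain_drift_matrix_at <- function(x1, x2, w) {
  matrix(
    c(
      -2 * x1, -w, 0,
      -w, -2 * x2, -w,
      0, -w, -2 * x1
    ),
    3, 3,
    byrow = TRUE
  )
}

#' Drift matrix of the chain at its lower equilibrium
#'
#' @inheritParams chain_equilibrium
#' @return The 3x3 sign-flipped Jacobian (symmetric, positive definite).
#' @export
chain_drift_matrix <- function(r, w) {
  xs <- chain_equilibrium(r, w)
  chain_drift_matrix_at(xs[1], xs[2], w)
}

#' Stationary covariance of the three-node chain
#'
#' Closed form from the Lyapunov equation with `B = diag(sigma1, sigma2,
#' sigma1)` (nodes 1 and 3 share the noise intensity), satisfying
#' `C11 = C33` and `C12 = C23` by symmetry.
#'
#' @inheritParams chain_equilibrium
#' @param sigma1 Noise intensity of nodes 1 and 3.
#' @param sigma2 Noise intensity of node 2.
#' @return A 3x3 covariance matrix.
#' @export
chain_covariance <- function(r, w, sigma1, sigma2) {
  xs <- chain_equilibrium(r, w)
  x1 <- xs[1]
  x2 <- xs[2]
  den <- (2 * x1 * x2 - w^2) * (x1 + x2)
  C11 <- (-4 * x1 * x2 * (x1 + x2) * sigma1^2 +
    w^2 * ((2 * x1 + x2) * sigma1^2 - x1 * sigma2^2)) / (8 * x1 * den)
  C12 <- w * (x2 * sigma1^2 + x1 * sigma2^2) / (4 * den)
  C13 <- -w^2 * (x2 * sigma1^2 + x1 * sigma2^2) / (8 * x1 * den)
  C22 <- (-2 * x1 * x2 * (x1 + x2) * sigma2^2 +
    w^2 * x2 * (sigma2^2 - sigma1^2)) / (4 * x2 * den)
  matrix(
    c(
      C11, C12, C13,
      C12, C22, C12,
      C13, C12, C11
    ),
    3, 3,
    byrow = TRUE
  )
}

#' Reduction in signal noise from pairing the chain's outer nodes
#'
#' For the chain with `sigma3 = sigma1`, averaging the variance signals of
#' nodes 1 and 3 keeps the mean (`E[V_{1,3}] = E[V_1]`) but shrinks the
#' standard deviation by the factor
#' `sqrt((1 + rho^2)/2)`, where `rho` is the equilibrium Pearson
#' correlation between `x_1` and `x_3`. Because
#' `rho^2 = corr(V_1, V_3)` for Gaussian fluctuations, this is
#' `sqrt((1 + corr(V_1, V_3))/2)`: the familiar variance reduction from
#' averaging two correlated estimators. The factor is below 1 whenever the
#' two nodes are not perfectly correlated, which never happens here since
#' they receive independent noise, so pairing the outer nodes always helps.
#'
#' @param C A 3x3 chain covariance matrix.
#' @return The factor `sqrt((1 + rho^2)/2)` in `(sqrt(1/2), 1]`.
#' @export
chain_pair_sd_factor <- function(C) {
  rho <- C[1, 3] / sqrt(C[1, 1] * C[3, 3])
  sqrt((1 + rho^2) / 2)
}

#' Table of d statistics for the analytic models
#'
#' Computes the signal moments at two bifurcation-parameter values from the
#' closed-form covariances and ranks node sets by the separability statistic
#' [d_statistic()].
#'
#' @param model `"two_node"` or `"chain"`.
#' @param r_values Length-2 numeric: the two bifurcation-parameter values
#'   (both below the relevant bifurcation point).
#' @param w Coupling weight.
#' @param sigma1 Noise of node 1 (two-node model) or of nodes 1 and 3
#'   (chain).
#' @param sigma2 Noise of node 2.
#' @param delta_r Stress offset of node 2 (two-node model only).
#' @param L Number of samples per node.
#' @param node_sets List of integer vectors; defaults to all sets reported
#'   for the model (`{1}, {2}, {1,2}` for two nodes; `{1}, {2}, {1,2},
#'   {1,3}, {1,2,3}` for the chain).
#' @return A tibble with columns `node_set` (label), `mu1`, `var1`, `mu2`,
#'   `var2`, `d`, ordered as `node_sets`.
#' @examples
#' d_table("two_node",
#'   r_values = c(-0.3, -0.1), w = 0.5,
#'   sigma1 = 0.1, sigma2 = 0.1, delta_r = 1, L = 100
#' )
#' @export
d_table <- function(model = c("two_node", "chain"), r_values, w,
                    sigma1, sigma2, delta_r = NULL, L = 100,
                    node_sets = NULL) {
  model <- match.arg(model)
  stopifnot(length(r_values) == 2)
  if (model == "two_node") {
    if (is.null(delta_r)) stop("`delta_r` is required for the two-node model", call. = FALSE)
    covs <- lapply(r_values, two_node_covariance,
      delta_r = delta_r, w = w, sigma1 = sigma1, sigma2 = sigma2
    )
    if (is.null(node_sets)) node_sets <- list(1, 2, c(1, 2))
  } else {
    covs <- lapply(r_values, chain_covariance,
      w = w, sigma1 = sigma1, sigma2 = sigma2
    )
    if (is.null(node_sets)) {
      node_sets <- list(1, 2, c(1, 2), c(1, 3), c(1, 2, 3))
    }
  }
  rows <- purrr::map(node_sets, function(S) {
    m1 <- signal_moments(covs[[1]], S, L)
    m2 <- signal_moments(covs[[2]], S, L)
    tibble::tibble(
      node_set = paste(S, collapse = ","),
      mu1 = m1$mean, var1 = m1$variance,
      mu2 = m2$mean, var2 = m2$variance,
      d = d_statistic(m1, m2)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "model") <- model
  attr(out, "r_values") <- r_values
  if (model == "chain") {
    attr(out, "pair_sd_factor") <- chain_pair_sd_factor(covs[[2]])
  }
  out
}
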