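#' Multivariate Ornstein-Uhlenbeck system
#'
#' Container for the linearized fluctuation dynamics
#' `dz = -A z dt + B dW`, where `A` is the sign-flipped Jacobian of the drift
#' at a stable equilibrium and `B` scales independent Wiener processes. The
#' equilibrium is stable iff every eigenvalue of `A` has positive real part,
#' which also guarantees a unique stationary covariance.
#'
#' @param A Square drift matrix (sign-flipped Jacobian).
#' @param B Noise matrix of the same dimension (often `diag(sigma)`).
#' @return An object of class `ou_system`.
#' @seealso [solve_lyapunov()]
#' @export
ou_system <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  stopifnot(nrow(A) == ncol(A), all(dim(A) == dim(B)))
  structure(list(A = A, B = B), class = "ou_system")
}

#' @export
print.ou_system <- function(x, ...) {
  ev <- eigen(x$A, only.values = TRUE)$values
  cat(
    "<ou_system> dim", nrow(x$A), "| min Re(eigenvalue of A) =",
    format(min(Re(ev))), "\n"
  )
  invisible(x)
}

#' Stationary covariance of an OU process
#'
#' Solves the Lyapunov equation `A C + C A' = B B'` for the equal-time
#' stationary covariance `C` of `dz = -A z dt + B dW`. The linear system is
#' solved directly via the Kronecker identity
#' `(I (x) A + A (x) I) vec(C) = vec(B B')` and the result symmetrized; an
#' unstable `A` (an eigenvalue with real part below `tol`) is an error.
#'
#' @param sys An [ou_system()].
#' @param tol Stability tolerance on the smallest real part of the
#'   eigenvalues of `A`. Near-critical systems are legitimately close to
#'   singular, hence the small default `1e-12`.
#' @return Symmetric positive semidefinite covariance matrix.
#' @examples
#' sys <- ou_system(A = 2 * diag(3), B = 0.1 * diag(3))
#' solve_lyapunov(sys) # 0.1^2 / (2 * 2) on the diagonal
#' @export
solve_lyapunov <- function(sys, tol = 1e-12) {
  stopifnot(inherits(sys, "ou_system"))
  A <- sys$A
  ev <- eigen(A, only.values = TRUE)$values
  worst <- which.min(Re(ev))
  if (Re(ev[worst]) <= tol) {
    stop("drift matrix A is not stable: eigenvalue ", format(ev[worst]),
      " has real part <= ", tol,
      call. = FALSE
    )
  }
  n <- nrow(A)
  Q <- sys$B %*% t(sys$B)
  M <- kronecker(diag(n), A) + kronecker(A, diag(n))
  C <- matrix(solve(M, as.vector(Q)), n, n)
  (C + t(C)) / 2
}

#' Residual of the Lyapunov equation
#'
#' Max-norm of `A C + C A' - B B'`; used to verify solver output.
#'
#' @param sys An [ou_system()].
#' @param C Candidate covariance matrix.
#' @return Nonnegative scalar.
#' @export
lyapunov_residual <- function(sys, C) {
  max(abs(sys$A %*% C + C %*% t(sys$A) - sys$B %*% t(sys$B)))
}

#' Moments of the node-set-averaged sample variance
#'
#' For `L` i.i.d. Gaussian observations with covariance `C`, the average
#' `V_S` over the node set `S` of the unbiased per-node sample variances has
#' \deqn{E[V_S] = \frac{1}{n}\sum_{i \in S} C_{ii}, \qquad
#'   var[V_S] = \frac{2}{n^2(L-1)} \sum_{i,j \in S} C_{ij}^2,}
#' equivalently `Tr(Cbar)/n` and `2 Tr(Cbar^2) / (n^2 (L-1))` for the
#' principal submatrix `Cbar = C[S, S]`. The coefficient of variation follows
#' as `sqrt(var)/mean`; for a single node it equals `sqrt(2/(L-1))`
#' regardless of the node.
#'
#' @param C Covariance matrix.
#' @param S Integer vector of node indices (distinct, within `1..N`).
#' @param L Number of samples per node (at least 2).
#' @return An object of class `signal_moments` with fields `mean`,
#'   `variance`, `cv`, `n`, `L`.
#' @examples
#' C <- matrix(c(4, 1, 1, 2), 2, 2) * 1e-3
#' signal_moments(C, S = c(1, 2), L = 100)
#' @export
signal_moments <- function(C, S, L) {
  C <- as.matrix(C)
  S <- as.integer(S)
  if (L < 2) stop("`L` must be at least 2", call. = FALSE)
  if (anyDuplicated(S) || any(S < 1) || any(S > nrow(C))) {
    stop("`S` must be distinct node indices within the matrix dimension",
      call. = FALSE
    )
  }
  n <- length(S)
  Cb <- C[S, S, drop = FALSE]
  m <- sum(diag(Cb)) / n
  v <- 2 * sum(Cb^2) / (n^2 * (L - 1))
  structure(
    list(
      mean = m, variance = v,
      cv = if (m > 0) sqrt(v) / m else NA_real_,
      n = n, L = as.integer(L)
    ),
    class = "signal_moments"
  )
}

#' @export
print.signal_moments <- function(x, ...) {
  cat(
    "<signal_moments> n =", x$n, " L =", x$L,
    " mean =", format(x$mean), " sd =", format(sqrt(x$variance)),
    " cv =", format(x$cv), "\n"
  )
  invisible(x)
}

#' @rdname signal_moments
#' @param x A `signal_moments` object.
#' @param ... Unused.
#' @export
tidy.signal_moments <- function(x, ...) {
  tibble::tibble(
    mean = x$mean, variance = x$variance, cv = x$cv, n = x$n, L = x$L
  )
}

#' Coefficient of variation of the averaged variance signal
#'
#' `sqrt(var)/mean`, equal to
#' `sqrt(2/(L-1)) * sqrt(sum(lambda_i^2)) / sum(lambda_i)` in terms of the
#' eigenvalues `lambda_i` of the principal submatrix. Adding a second node
#' strictly lowers the CV unless all but one eigenvalue vanish.
#'
#' @param m A [signal_moments()] object.
#' @return Nonnegative scalar.
#' @export
coefficient_of_variation <- function(m) {
  stopifnot(inherits(m, "signal_moments"))
  if (!is.finite(m$mean) || m$mean <= 0) {
    stop("CV requires a positive mean", call. = FALSE)
  }
  sqrt(m$variance) / m$mean
}

#' Separability statistic d between two signal distributions
#'
#' `d = |mu_1 - mu_2| / sqrt(var_1 + var_2)`, the t-statistic-like distance
#' between the (normal) distributions of the averaged variance signal at two
#' values of the bifurcation parameter. Larger `d` means the growth of the
#' signal between the two parameter values is easier to distinguish from its
#' own fluctuations; node sets are ranked by `d`.
#'
#' @param m1,m2 [signal_moments()] objects (or lists with `mean` and
#'   `variance`).
#' @return Nonnegative scalar; symmetric in its arguments and invariant
#'   under a common positive rescaling of both distributions.
#' @examples
#' d_statistic(list(mean = 0, variance = 1), list(mean = 2, variance = 3)) # 1
#' @export
d_statistic <- function(m1, m2) {
  tot <- m1$variance + m2$variance
  if (tot <= 0) stop("both variances are zero: d is undefined", call. = FALSE)
  abs(m1$mean - m2$mean) / sqrt(tot)
}

#' Read or write a covariance matrix as CSV
#'
#' Plain CSV with a header row of node labels; row order follows the header.
#'
#' @param C Covariance matrix (for writing).
#' @param path File path.
#' @return `read_covariance_csv()` returns a symmetric matrix;
#'   `write_covariance_csv()` returns `path` invisibly.
#' @export
write_covariance_csv <- function(C, path) {
  C <- as.matrix(C)
  labels <- colnames(C)
  if (is.null(labels)) labels <- paste0("node_", seq_len(ncol(C)))
  utils::write.table(
    matrix(C, nrow(C), dimnames = list(NULL, labels)),
    path,
    sep = ",", row.names = FALSE, col.names = TRUE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_covariance_csv
#' @export
read_covariance_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  C <- as.matrix(df)
  rownames(C) <- colnames(C)
  if (nrow(C) != ncol(C)) stop("covariance CSV is not square", call. = FALSE)
  (C + t(C)) / 2
}
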