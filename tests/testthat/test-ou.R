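test_that("Lyapunov solver recovers the scalar OU stationary variance", {
  sys <- ou_system(A = 2.5 * diag(4), B = 0.3 * diag(4))
  C <- solve_lyapunov(sys)
  expect_equal(C, 0.3^2 / (2 * 2.5) * diag(4), tolerance = 1e-12)
})

test_that("Lyapunov solver reproduces the two-node closed forms entrywise", {
  A <- two_node_drift_matrix(-0.3, delta_r = 1, w = 0.5)
  C <- solve_lyapunov(ou_system(A, diag(c(0.1, 0.1))))
  C_closed <- two_node_covariance(-0.3, delta_r = 1, w = 0.5, sigma1 = 0.1, sigma2 = 0.1)
  expect_lt(max(abs(C - C_closed)), 1e-10)
  expect_equal(C_closed[1, 1], 4.564e-3, tolerance = 1e-3)
  expect_equal(C_closed[1, 2], 7.204e-4, tolerance = 1e-3)
  expect_equal(C_closed[2, 2], 2.586e-3, tolerance = 1e-3)
})

test_that("Lyapunov solutions have small residual and are symmetric PSD", {
  set.seed(14)
  for (rep in 1:20) {
    sys <- random_stable_ou(sample(2:8, 1))
    C <- solve_lyapunov(sys)
    expect_lt(
      lyapunov_residual(sys, C),
      1e-10 * max(abs(sys$B %*% t(sys$B)))
    )
    expect_equal(C, t(C))
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  }
})

test_that("unstable drift matrices are rejected with the offending eigenvalue", {
  expect_error(
    solve_lyapunov(ou_system(diag(c(1, -0.2)), diag(2))),
    "not stable.*-0.2"
  )
})

test_that("Lyapunov covariance matches a long Euler-Maruyama simulation", {
  # independent oracle: sample covariance of simulated OU paths (using a
  # double-well linearization is indirect; here we simulate the OU process
  # itself with a plain R loop, independent of the package integrator)
  set.seed(21)
  sys <- random_stable_ou(5, a = 1)
  C <- solve_lyapunov(sys)
  dt <- 0.01
  reps <- 24
  ests <- replicate(reps, {
    x <- rep(0, 5)
    n_keep <- 4000
    keep <- matrix(0, n_keep, 5)
    for (s in seq_len(500 + n_keep)) {
      x <- x - drop(sys$A %*% x) * dt + diag(sys$B) * sqrt(dt) * rnorm(5)
      if (s > 500) keep[s - 500, ] <- x
    }
    cov(keep)
  })
  est_mean <- apply(ests, 1:2, mean)
  est_se <- apply(ests, 1:2, sd) / sqrt(reps)
  expect_true(all(abs(est_mean - C) <= 3 * est_se + 1e-4))
})

test_that("signal moments match the stated trace and eigenvalue forms", {
  set.seed(8)
  L <- 50
  for (rep in 1:20) {
    C <- random_psd(sample(2:7, 1))
    S <- sort(sample(nrow(C), sample(nrow(C), 1)))
    m <- signal_moments(C, S, L)
    Cb <- C[S, S, drop = FALSE]
    lam <- eigen(Cb, symmetric = TRUE, only.values = TRUE)$values
    n <- length(S)
    expect_equal(m$mean, sum(lam) / n, tolerance = 1e-10)
    expect_equal(m$variance, 2 * sum(lam^2) / (n^2 * (L - 1)), tolerance = 1e-10)
  }
})

test_that("single-node moments reduce to the known closed form", {
  m <- signal_moments(matrix(0.7), 1, L = 30)
  expect_equal(m$mean, 0.7)
  expect_equal(m$variance, 2 * 0.7^2 / 29)
  expect_equal(coefficient_of_variation(m), sqrt(2 / 29))
})

test_that("signal moments agree with Monte-Carlo sampling of V_S", {
  set.seed(33)
  C <- chain_covariance(-0.3, w = 0.05, sigma1 = 0.1, sigma2 = 0.1)
  L <- 10
  reps <- 1e5
  R <- chol(C)
  S <- 1:3
  vhat <- numeric(reps)
  for (r in seq_len(reps)) {
    z <- matrix(rnorm(L * 3), L) %*% R
    vhat[r] <- mean(apply(z, 2, var))
  }
  m <- signal_moments(C, S, L)
  se_mean <- sd(vhat) / sqrt(reps)
  expect_lt(abs(mean(vhat) - m$mean), 3 * se_mean)
  # SE of a sample variance of vhat: use the normal-theory approximation
  se_var <- var(vhat) * sqrt(2 / (reps - 1))
  expect_lt(abs(var(vhat) - m$variance), 3 * se_var)
})

test_that("CV properties: L-scaling, single-node constancy, averaging gain", {
  set.seed(4)
  C <- random_psd(5)
  S <- c(1, 3, 4)
  cvs <- sapply(c(10, 100, 1000), function(L) {
    coefficient_of_variation(signal_moments(C, S, L)) * sqrt(L - 1)
  })
  expect_equal(max(cvs) - min(cvs), 0, tolerance = 1e-12)

  # n = 1: sqrt(2/(L-1)) regardless of the node
  for (i in 1:5) {
    expect_equal(
      coefficient_of_variation(signal_moments(C, i, 100)),
      sqrt(2 / 99)
    )
  }

  # n = 2 equal uncorrelated variances: CV drops by sqrt(2)
  Ceq <- diag(c(2, 2))
  expect_equal(
    coefficient_of_variation(signal_moments(Ceq, 1:2, 100)),
    sqrt(2 / 99) / sqrt(2)
  )

  # degenerate: second eigenvalue 0 keeps the single-node CV
  Cdeg <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(
    coefficient_of_variation(signal_moments(Cdeg, 1:2, 100)),
    sqrt(2 / 99)
  )

  # adding a not-perfectly-correlated node strictly lowers the CV
  for (rep in 1:10) {
    Cr <- random_psd(4) + 0.1 * diag(4)
    expect_lt(
      coefficient_of_variation(signal_moments(Cr, 1:2, 100)),
      coefficient_of_variation(signal_moments(Cr, 1, 100))
    )
  }
})

test_that("d statistic: symmetry, scale invariance, and hand values", {
  m1 <- list(mean = 0, variance = 1)
  m2 <- list(mean = 2, variance = 3)
  expect_equal(d_statistic(m1, m2), 1)
  expect_equal(d_statistic(m2, m1), 1)
  expect_equal(d_statistic(m1, m1), 0)
  # common positive rescaling of both distributions leaves d unchanged
  s <- 3.7
  m1s <- list(mean = s * m1$mean, variance = s^2 * m1$variance)
  m2s <- list(mean = s * m2$mean, variance = s^2 * m2$variance)
  expect_equal(d_statistic(m1s, m2s), d_statistic(m1, m2))
  expect_error(
    d_statistic(list(mean = 1, variance = 0), list(mean = 2, variance = 0)),
    "undefined"
  )
})

test_that("argument validation: L and S bounds, CV domain", {
  C <- diag(2)
  expect_error(signal_moments(C, 1, L = 1), "at least 2")
  expect_error(signal_moments(C, c(1, 1), 10), "distinct")
  expect_error(signal_moments(C, 3, 10), "distinct|dimension")
  expect_error(
    coefficient_of_variation(signal_moments(matrix(0), 1, 10)),
    "positive mean"
  )
})

test_that("covariance CSV round-trips", {
  C <- random_psd(4)
  colnames(C) <- paste0("n", 1:4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_covariance_csv(C, path)
  C2 <- read_covariance_csv(path)
  expect_equal(unname(as.matrix(C2)), unname(C), tolerance = 1e-12)
  expect_equal(colnames(C2), colnames(C))
})
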