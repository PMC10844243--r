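# Independent oracles used across test files.

# O(n^2) concordant/discordant pair counting (tau-a; valid when there are
# no ties).
kendall_brute <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  s / choose(n, 2)
}

# random stable OU system: A = M M' + a I is symmetric positive definite
random_stable_ou <- function(n, a = 0.5) {
  M <- matrix(rnorm(n * n), n)
  ou_system(M %*% t(M) / n + a * diag(n), diag(runif(n, 0.05, 0.2)))
}

# random covariance matrix (Wishart-like)
random_psd <- function(n, scale = 1) {
  M <- matrix(rnorm(n * n), n)
  scale * (M %*% t(M)) / n
}

# Draw L iid N(0, C) rows
gaussian_samples <- function(L, C) {
  R <- chol(C)
  matrix(rnorm(L * nrow(C)), L) %*% R
}
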