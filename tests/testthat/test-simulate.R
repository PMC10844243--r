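pmax_if_clamped <- function(spec, x) {
  if (spec$model %in% c("gene_regulatory", "sis")) pmax(x, 0) else x
}

test_that("noiseless integration stays at a fixed point and matches the R drift", {
  set.seed(17)
  g <- net_ba(10, 2)
  spec <- dynamics_spec("double_well", g, noise = 0)
  # all-ones is not exactly a fixed point with coupling; use D = 0, u = 0
  spec0 <- dynamics_spec("double_well", g, coupling = 0, noise = 0)
  traj <- euler_maruyama(spec0, x0 = rep(1, 10), duration = 5)
  expect_lt(max(abs(traj[nrow(traj), ] - 1)), 1e-8)

  # one noiseless step equals x + drift(x) dt for every model
  for (model in c("double_well", "mutualistic", "gene_regulatory", "sis")) {
    sp <- dynamics_spec(model, g,
      coupling = if (model == "sis") 0.3 else NULL, noise = 0
    )
    x0 <- initial_state(sp) * runif(10, 0.9, 1.1)
    step <- euler_maruyama(sp, x0 = x0, dt = 0.01, duration = 0.01)
    expect_equal(drop(step[1, ]), pmax_if_clamped(sp, x0 + drift(sp, x0) * 0.01),
      tolerance = 1e-12
    )
  }
})

test_that("1-D OU integration reproduces the stationary variance", {
  # dx = -a x dt + sigma dW realized as SIS with lambda = 0, mu = a = 1:
  # drift is exactly -x, but SIS clamps at 0; use double_well shifted
  # instead: a single node, D = 0, around the lower well the linearization
  # of the cubic at x* has slope f'(x*) = -(x*-r2)(x*-r3)-... ; simpler to
  # check against the Lyapunov solution of the linearization itself.
  set.seed(23)
  g <- igraph::make_ring(2)
  spec <- dynamics_spec("double_well", g, coupling = 0, noise = 0.05)
  # lower equilibrium x* = 1; slope of the cubic drift at x* = 1:
  # d/dx [-(x-1)(x-3)(x-5)] at 1 = -(1-3)(1-5) = -8
  a <- 8
  reps <- 30
  vars <- replicate(reps, {
    traj <- euler_maruyama(spec, x0 = c(1, 1), duration = 60, record_every = 10)
    c(var(traj[100:nrow(traj), 1]), var(traj[100:nrow(traj), 2]))
  })
  est <- mean(vars)
  se <- sd(colMeans(vars)) / sqrt(reps)
  expect_lt(abs(est - 0.05^2 / (2 * a)), 3 * se + 2e-6)
})

test_that("clamped models reset negative states to zero", {
  g <- igraph::make_ring(3)
  # huge noise guarantees negative excursions within a few steps
  spec <- dynamics_spec("sis", g, coupling = 0.1, noise = 5)
  set.seed(2)
  traj <- euler_maruyama(spec, x0 = rep(0.001, 3), duration = 1)
  expect_true(all(traj >= 0))
  expect_true(any(traj == 0)) # clamping actually fired

  # the unclamped double-well may go negative freely
  spec_dw <- dynamics_spec("double_well", g, coupling = 0, noise = 5)
  set.seed(2)
  traj_dw <- euler_maruyama(spec_dw, x0 = rep(1, 3), duration = 1)
  expect_true(any(traj_dw < 0))
})

test_that("equilibrium samples have the right shape, spacing, and transition flag", {
  set.seed(31)
  g <- net_ba(8, 2)
  spec <- dynamics_spec("double_well", g)
  s <- equilibrium_samples(spec, L = 50)
  expect_equal(dim(s), c(50, 8))
  expect_false(attr(s, "transition"))
  expect_equal(length(attr(s, "final_state")), 8)

  # mutualistic spacing: 10 TU transient + 100 * 0.1 TU of samples
  spec_m <- dynamics_spec("mutualistic", g, noise = 0)
  s_m <- equilibrium_samples(spec_m, L = 10)
  expect_equal(dim(s_m), c(10, 8))

  # a spec past its tipping point flags the transition
  spec_hot <- dynamics_spec("double_well", g, stress = 5)
  s_hot <- equilibrium_samples(spec_hot, L = 10)
  expect_true(attr(s_hot, "transition"))
})

test_that("low-stress sample variance approximates the linearized OU covariance", {
  set.seed(37)
  g <- net_ba(10, 2)
  spec <- dynamics_spec("double_well", g, coupling = 0.05, stress = 0)
  # deterministic equilibrium near 1: solve by relaxation without noise
  spec0 <- spec
  spec0$noise <- rep(0, 10)
  xstar <- attr(euler_maruyama(spec0, duration = 200), "final_state")
  # Jacobian of the coupled cubic at xstar
  J <- -diag((xstar - 3) * (xstar - 5) + (xstar - 1) * (xstar - 5) +
    (xstar - 1) * (xstar - 3)) + 0.05 * spec$adjacency
  C_theory <- solve_lyapunov(ou_system(-J, diag(spec$noise)))
  s <- equilibrium_samples(spec, L = 100)
  v <- apply(s, 2, var)
  expect_true(all(v < 3 * diag(C_theory) & v > diag(C_theory) / 3))
})

test_that("measurement indices follow the rounded 10%/90% rule", {
  expect_equal(select_measurement_indices(10), c(1, 9))
  expect_equal(select_measurement_indices(20), c(2, 18))
  expect_equal(select_measurement_indices(37), c(4, 33))
  expect_equal(select_measurement_indices(2), c(1, 2))
  expect_equal(select_measurement_indices(5), c(1, 5)) # round(0.5) away from zero
  expect_error(select_measurement_indices(1), "at least 2")
})

test_that("sweeps are reproducible, monotone, and record pre-transition samples", {
  set.seed(41)
  g <- net_ba(10, 2)
  spec <- dynamics_spec("double_well", g)
  sw <- run_sweep(spec, "u", seed = 5)
  sw2 <- run_sweep(spec, "u", seed = 5)
  expect_identical(sw$samples, sw2$samples)
  expect_identical(sw$parameter_values, sw2$parameter_values)

  K <- length(sw$parameter_values)
  expect_gte(K, 2)
  expect_equal(length(sw$samples), K)
  expect_true(all(diff(sw$parameter_values) > 0))
  expect_equal(diff(sw$parameter_values)[1], 0.025)
  expect_equal(sw$transition_parameter, sw$parameter_values[K] + 0.025)
  expect_equal(sw$measurement_indices, select_measurement_indices(K))
  # no recorded sample crosses the stop threshold
  expect_true(all(sapply(sw$samples, max) < 3))
})

test_that("a sweep that cannot reach a transition hits the hard cap cleanly", {
  set.seed(43)
  g <- igraph::make_ring(4)
  spec <- dynamics_spec("double_well", g, noise = 1e-4)
  expect_error(
    run_sweep(spec, "u", seed = 1, L = 3, max_values = 3),
    "max_values"
  )
})

test_that("sweep results persist to a plain-text directory and back", {
  set.seed(47)
  g <- net_ba(6, 2)
  spec <- dynamics_spec("double_well", g)
  sw <- run_sweep(spec, "u", seed = 7, L = 10)
  dir <- withr::local_tempdir()
  write_sweep(sw, dir)
  expect_true(file.exists(file.path(dir, "params.csv")))
  sw2 <- read_sweep(dir)
  expect_equal(sw2$parameter_values, sw$parameter_values)
  expect_equal(length(sw2$samples), length(sw$samples))
  expect_equal(
    as.vector(sw2$samples[[1]]),
    as.vector(sw$samples[[1]]),
    tolerance = 1e-12
  )
  expect_equal(dim(sw2$samples[[1]]), dim(sw$samples[[1]]))
  expect_equal(sw2$measurement_indices, sw$measurement_indices)
})
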