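#' Euler-Maruyama integration of a networked dynamics model
#'
#' Integrates `dx = drift(x) dt + sigma_i sqrt(dt) xi_i` with independent
#' standard normal increments `xi_i`, using the compiled inner loop. States
#' are clamped at zero after each step for the `gene_regulatory` and `sis`
#' models (negative excursions caused by noise are reset). Randomness comes
#' from R's RNG, so results are reproducible under [set.seed()].
#'
#' @param spec A [dynamics_spec()].
#' @param x0 Initial state vector (default [initial_state()]).
#' @param dt Time step (default 0.01).
#' @param duration Total integration time; at least `dt`.
#' @param record_every Record the state every this many steps (default 1).
#' @return Matrix of recorded states (rows = recorded steps, columns =
#'   nodes) with the final state as attribute `final_state`.
#' @export
euler_maruyama <- function(spec, x0 = initial_state(spec), dt = 0.01,
                           duration, record_every = 1) {
  stopifnot(inherits(spec, "dynamics_spec"), dt > 0, duration >= dt)
  n_steps <- floor(duration / dt + 1e-9)
  record_at <- seq(record_every, n_steps, by = record_every)
  out <- em_integrate_cpp(
    model_code(spec$model), spec$adjacency, spec$coupling,
    stress_vector(spec), spec$noise, x0, dt, n_steps,
    as.integer(record_at), spec$model %in% c("gene_regulatory", "sis"),
    unlist(spec$constants)
  )
  structure(out$samples, final_state = out$final_state, dt = dt)
}

#' Equilibrium samples at a fixed parameter value
#'
#' Integrates from `x0`, discards the model-specific transient (100 time
#' units, 10 for the faster mutualistic model), then records `L` states
#' evenly spaced at the model-specific interval (1 TU; 0.1 TU for
#' mutualistic). A `transition` attribute flags whether any recorded state
#' (or the post-transient state) satisfies the model's stop condition.
#'
#' @inheritParams euler_maruyama
#' @param L Number of samples (default 100).
#' @return `L` x `N` matrix of sampled states, with attributes
#'   `final_state` and `transition`.
#' @export
equilibrium_samples <- function(spec, x0 = initial_state(spec), L = 100,
                                dt = 0.01) {
  stopifnot(inherits(spec, "dynamics_spec"), L >= 1)
  trans_steps <- round(transient_tu(spec$model) / dt)
  spacing_steps <- round(sample_spacing_tu(spec$model) / dt)
  record_at <- trans_steps + spacing_steps * seq_len(L)
  n_steps <- record_at[L]
  out <- em_integrate_cpp(
    model_code(spec$model), spec$adjacency, spec$coupling,
    stress_vector(spec), spec$noise, x0, dt, n_steps,
    as.integer(record_at), spec$model %in% c("gene_regulatory", "sis"),
    unlist(spec$constants)
  )
  samples <- out$samples
  transition <- any(apply(samples, 1, function(s) stop_condition(spec, s)))
  structure(samples,
    final_state = out$final_state, transition = transition
  )
}

#' Measurement indices for a sweep
#'
#' Given `K` pre-transition parameter values, the covariance matrices
#' entering the d statistic are estimated at indices `round(0.1 K)` and
#' `round(0.9 K)` (rounding half away from zero), with the first clipped
#' into `[1, K]`.
#'
#' @param K Number of pre-transition parameter values (at least 2).
#' @return Integer vector `c(k1, k2)` with `k1 < k2`.
#' @examples
#' select_measurement_indices(37) # c(4, 33)
#' @export
select_measurement_indices <- function(K) {
  if (K < 2) stop("need at least 2 pre-transition parameter values", call. = FALSE)
  k1 <- min(max(round_half_away(0.1 * K), 1), K)
  k2 <- min(max(round_half_away(0.9 * K), 1), K)
  if (k1 >= k2) k1 <- k2 - 1L
  as.integer(c(k1, k2))
}

#' Run a bifurcation-parameter sweep
#'
#' Simulates the system at linearly spaced values of the bifurcation
#' parameter (increasing for `double_well` and `sis`, decreasing for
#' `mutualistic` and `gene_regulatory`), restarting every simulation from
#' the model's initial state, and stops once the stop condition fires (any
#' node leaves its initial state). The last parameter value at which all
#' nodes stayed near their initial state defines the series length `K`;
#' samples at every pre-transition value are kept. Each simulation uses its
#' own RNG stream derived from `seed` and `(series, k)`, so runs are
#' reproducible and parallelizable.
#'
#' @param spec A [dynamics_spec()]; its `stress`/`coupling` fields provide
#'   the non-swept parameter (the swept one starts from [sweep_start()]).
#' @param parameter `"u"`, `"D"`, or `"lambda"` (SIS).
#' @param seed Master seed for the per-simulation RNG streams.
#' @param series Series index mixed into the RNG stream (default 1).
#' @param L Samples per parameter value (default 100).
#' @param dt Integration time step.
#' @param max_values Hard cap on the number of parameter values, to
#'   guarantee termination (default 10000).
#' @return An object of class `sentinet_sweep`: list with
#'   `parameter_name`, `parameter_values` (length `K`), `samples` (list of
#'   `L` x `N` matrices), `measurement_indices` `c(k1, k2)`,
#'   `transition_parameter`, `spec`, `seed`, `series`.
#' @export
run_sweep <- function(spec, parameter = c("u", "D", "lambda"), seed,
                      series = 1L, L = 100, dt = 0.01, max_values = 10000) {
  stopifnot(inherits(spec, "dynamics_spec"))
  parameter <- normalize_parameter(spec$model, match.arg(parameter))
  start <- sweep_start(spec$model, parameter)
  step <- parameter_step(spec, parameter)
  spec$stress <- if (spec$model == "sis") 0 else unname(start["u"])
  spec$coupling <- unname(start["D"])
  if (parameter == "u") {
    value <- unname(start["u"])
  } else {
    value <- unname(start["D"])
  }
  values <- numeric(0)
  samples <- list()
  transition_parameter <- NA_real_
  for (k in seq_len(max_values)) {
    if (parameter == "u") spec$stress <- value else spec$coupling <- value
    set.seed(derive_seed(seed, series, k))
    s <- equilibrium_samples(spec, L = L, dt = dt)
    if (attr(s, "transition")) {
      transition_parameter <- value
      break
    }
    values <- c(values, value)
    samples[[k]] <- s
    value <- value + step
    if (k == max_values) {
      stop("sweep did not reach a transition within `max_values` = ",
        max_values, " parameter values",
        call. = FALSE
      )
    }
  }
  K <- length(values)
  if (K == 0) {
    stop("transition at the very first parameter value: no usable series",
      call. = FALSE
    )
  }
  structure(
    list(
      parameter_name = if (spec$model == "sis") "lambda" else parameter,
      parameter_values = values,
      samples = samples,
      measurement_indices = if (K >= 2) select_measurement_indices(K) else NULL,
      transition_parameter = transition_parameter,
      spec = spec, seed = seed, series = series, L = L, dt = dt
    ),
    class = "sentinet_sweep"
  )
}

#' @export
print.sentinet_sweep <- function(x, ...) {
  K <- length(x$parameter_values)
  cat(
    "<sentinet_sweep>", x$spec$model, "on", x$spec$n_nodes, "nodes |",
    x$parameter_name, "swept over", K, "pre-transition values",
    if (K > 0) {
      paste0(
        "[", format(x$parameter_values[1]), ", ",
        format(x$parameter_values[K]), "]"
      )
    } else {
      ""
    },
    "| transition at", format(x$transition_parameter), "\n"
  )
  if (!is.null(x$measurement_indices)) {
    cat(
      "  measurement indices: k1 =", x$measurement_indices[1],
      ", k2 =", x$measurement_indices[2], "\n"
    )
  }
  invisible(x)
}

#' Covariance matrices at the two measurement points of a sweep
#'
#' @param sweep A [run_sweep()] result.
#' @return List with elements `C1`, `C2` (sample covariances at `k1`,
#'   `k2`), and `indices`.
#' @export
sweep_covariances <- function(sweep) {
  stopifnot(inherits(sweep, "sentinet_sweep"))
  ks <- sweep$measurement_indices
  if (is.null(ks)) stop("sweep has fewer than 2 parameter values", call. = FALSE)
  list(
    C1 = sample_covariance(sweep$samples[[ks[1]]]),
    C2 = sample_covariance(sweep$samples[[ks[2]]]),
    indices = ks
  )
}

#' Persist or load a sweep as a plain-text directory
#'
#' Writes `params.csv` (k, parameter value), one `samples_<k>.csv` per
#' parameter value (`L` rows by `N` node columns), and `meta.yaml` (seed,
#' series, indices, and the dynamics config).
#'
#' @param sweep A [run_sweep()] result.
#' @param dir Directory path (created if missing).
#' @return `dir` invisibly; `read_sweep()` returns a `sentinet_sweep`.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "sentinet_sweep"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(k = seq_along(sweep$parameter_values), value = sweep$parameter_values),
    file.path(dir, "params.csv"),
    row.names = FALSE
  )
  for (k in seq_along(sweep$samples)) {
    m <- sweep$samples[[k]]
    colnames(m) <- paste0("node_", seq_len(ncol(m)))
    utils::write.csv(as.data.frame(m),
      file.path(dir, sprintf("samples_%d.csv", k)),
      row.names = FALSE
    )
  }
  write_spec_config(sweep$spec, file.path(dir, "spec.yaml"))
  yaml::write_yaml(
    list(
      parameter_name = sweep$parameter_name, seed = sweep$seed,
      series = sweep$series, L = sweep$L, dt = sweep$dt,
      transition_parameter = sweep$transition_parameter
    ),
    file.path(dir, "meta.yaml")
  )
  invisible(dir)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(dir) {
  params <- utils::read.csv(file.path(dir, "params.csv"))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  spec <- read_spec_config(file.path(dir, "spec.yaml"))
  samples <- lapply(params$k, function(k) {
    as.matrix(utils::read.csv(file.path(dir, sprintf("samples_%d.csv", k))))
  })
  K <- nrow(params)
  structure(
    list(
      parameter_name = meta$parameter_name,
      parameter_values = params$value,
      samples = samples,
      measurement_indices = if (K >= 2) select_measurement_indices(K) else NULL,
      transition_parameter = meta$transition_parameter,
      spec = spec, seed = meta$seed, series = meta$series,
      L = meta$L, dt = meta$dt
    ),
    class = "sentinet_sweep"
  )
}
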