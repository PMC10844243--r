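#' Dynamics specification for a networked stochastic system
#'
#' Bundles a network with one of four node dynamics models and all per-node
#' parameters. The models (state `x_i`, adjacency `w_ij`, coupling `D`,
#' per-node stress `u_i = u + du_i`, noise `sigma_i`):
#'
#' * `double_well`: `dx_i = [-(x_i - r1)(x_i - r2)(x_i - r3) + D sum_j w_ij
#'   x_j + u_i] dt + sigma_i dW_i`, with `(r1, r2, r3) = (1, 3, 5)`; lower
#'   state near 1, upper near 5.
#' * `mutualistic`: species-abundance dynamics with migration
#'   `B_i = 0.1 + u_i`, logistic growth with carrying capacity `K = 5` and
#'   Allee constant `C = 1`, and a saturating mutualistic term with constants
#'   `Dtilde = 5`, `E = 0.9`, `H = 0.1`.
#' * `gene_regulatory`: Michaelis-Menten regulation `dx_i = [-B x_i^f +
#'   D sum_j w_ij x_j^h / (1 + x_j^h) + u_i] dt + ...` with `B = f = 1`,
#'   `h = 2`.
#' * `sis`: `dx_i = [lambda sum_j w_ij (1 - x_i) x_j - mu x_i] dt + ...`
#'   with recovery rate `mu = 1`; `coupling` is the infection rate `lambda`
#'   and the model has no node stress.
#'
#' Negative states are reset to zero after each integration step for the
#' `gene_regulatory` and `sis` models only.
#'
#' @param model One of `"double_well"`, `"mutualistic"`,
#'   `"gene_regulatory"`, `"sis"`.
#' @param network An igraph graph.
#' @param coupling Coupling strength `D` (infection rate `lambda` for
#'   `sis`). Default: the sweep starting value for the `u` sweep of the
#'   model (see [sweep_start()]).
#' @param stress Global stress `u` (ignored for `sis`). Default 0.
#' @param stress_offsets Per-node offsets `du_i` (default all zero); see
#'   [make_heterogeneity()].
#' @param noise Per-node noise intensities `sigma_i`, recycled to length
#'   `N`. Default: the model's base noise (`double_well` 0.05,
#'   `mutualistic` 0.25, `gene_regulatory` 5e-6, `sis` 5e-4).
#' @return An object of class `dynamics_spec`.
#' @export
dynamics_spec <- function(model = c(
                            "double_well", "mutualistic",
                            "gene_regulatory", "sis"
                          ),
                          network, coupling = NULL, stress = 0,
                          stress_offsets = NULL, noise = NULL) {
  model <- match.arg(model)
  n <- igraph::vcount(network)
  if (is.null(coupling)) {
    coupling <- sweep_start(model, if (model == "sis") "D" else "u")["D"]
  }
  if (is.null(noise)) noise <- base_noise(model)
  if (is.null(stress_offsets)) stress_offsets <- numeric(n)
  noise <- rep_len(noise, n)
  stopifnot(length(stress_offsets) == n, all(noise >= 0))
  if (model == "sis" && any(stress_offsets != 0 | stress != 0)) {
    stop("the SIS model has no node stress", call. = FALSE)
  }
  structure(
    list(
      model = model, network = network, adjacency = net_adjacency(network),
      n_nodes = n, coupling = unname(coupling), stress = stress,
      stress_offsets = stress_offsets, noise = noise,
      constants = model_constants(model)
    ),
    class = "dynamics_spec"
  )
}

#' @export
print.dynamics_spec <- function(x, ...) {
  cat(
    "<dynamics_spec>", x$model, "on", x$n_nodes, "nodes |",
    if (x$model == "sis") "lambda =" else "D =", format(x$coupling),
    if (x$model != "sis") paste(" u =", format(x$stress)) else "",
    "\n"
  )
  invisible(x)
}

model_constants <- function(model) {
  switch(model,
    double_well = list(r1 = 1, r2 = 3, r3 = 5),
    mutualistic = list(B0 = 0.1, C = 1, Dtilde = 5, E = 0.9, H = 0.1, K = 5),
    gene_regulatory = list(B = 1, f = 1, h = 2),
    sis = list(mu = 1)
  )
}

#' Base noise intensity of each model
#'
#' @param model Model identifier.
#' @return Scalar sigma.
#' @export
base_noise <- function(model) {
  switch(model,
    double_well = 0.05,
    mutualistic = 0.25,
    gene_regulatory = 5e-6,
    sis = 5e-4,
    stop("unknown model: ", model, call. = FALSE)
  )
}

# integer codes shared with src/em.cpp
model_code <- function(model) {
  match(model, c("double_well", "mutualistic", "gene_regulatory", "sis")) - 1L
}

# Effective per-node stress vector entering the drift. For the mutualistic
# model the stress enters through the migration rate B_i = 0.1 + u + du_i.
stress_vector <- function(spec) {
  if (spec$model == "sis") {
    numeric(spec$n_nodes)
  } else {
    spec$stress + spec$stress_offsets
  }
}

#' Deterministic drift of a dynamics specification
#'
#' The drift part of `dx_i/dt` for the model held by `spec`, including the
#' coupling and stress terms; reference implementation in R against which
#' the compiled integrator is checked.
#'
#' @param spec A [dynamics_spec()].
#' @param state Numeric state vector of length `N`.
#' @return Numeric vector of length `N`.
#' @export
drift <- function(spec, state) {
  stopifnot(inherits(spec, "dynamics_spec"), length(state) == spec$n_nodes)
  w <- spec$adjacency
  D <- spec$coupling
  u <- stress_vector(spec)
  k <- spec$constants
  x <- state
  switch(spec$model,
    double_well = -(x - k$r1) * (x - k$r2) * (x - k$r3) +
      D * drop(w %*% x) + u,
    mutualistic = {
      Bi <- k$B0 + u
      inter <- outer(x, x) / (k$Dtilde + k$E * x + matrix(k$H * x,
        nrow = length(x), ncol = length(x), byrow = TRUE
      ))
      Bi + x * (1 - x / k$K) * (x / k$C - 1) + D * rowSums(w * inter)
    },
    gene_regulatory = -k$B * x^k$f +
      D * drop(w %*% (x^k$h / (1 + x^k$h))) + u,
    sis = D * (1 - x) * drop(w %*% x) - k$mu * x
  )
}

#' Draw heterogeneous stress and noise for a specification
#'
#' Heterogeneous stress draws each `du_i` independently from
#' `U[-0.25, 0.25]`; heterogeneous noise draws `dsigma_i` from
#' `U[-0.9 sigma, 0.9 sigma]` around the model's base noise, so every
#' `sigma_i` stays positive. Draws are made once per series: the offsets are
#' fixed node properties while the bifurcation parameter is swept. The SIS
#' model has no concept of node stress; requesting heterogeneous stress for
#' it is an error.
#'
#' @param spec A [dynamics_spec()] template (its offsets are replaced).
#' @param heterogeneous_stress,heterogeneous_noise Logical switches.
#' @param stress_half_width Half width of the stress-offset distribution
#'   (0.25 under heterogeneity).
#' @param noise_relative_half_width Relative half width of the noise
#'   distribution (0.9 under heterogeneity; must be < 1).
#' @return A new `dynamics_spec` with offsets and noise filled in.
#' @export
make_heterogeneity <- function(spec, heterogeneous_stress = FALSE,
                               heterogeneous_noise = FALSE,
                               stress_half_width = 0.25,
                               noise_relative_half_width = 0.9) {
  stopifnot(inherits(spec, "dynamics_spec"))
  if (noise_relative_half_width >= 1) {
    stop("`noise_relative_half_width` must be < 1 so that sigma_i > 0",
      call. = FALSE
    )
  }
  n <- spec$n_nodes
  if (heterogeneous_stress) {
    if (spec$model == "sis") {
      stop("the SIS model has no node stress to make heterogeneous",
        call. = FALSE
      )
    }
    spec$stress_offsets <- runif(n, -stress_half_width, stress_half_width)
  } else {
    spec$stress_offsets <- numeric(n)
  }
  sigma <- base_noise(spec$model)
  if (heterogeneous_noise) {
    spec$noise <- sigma + runif(
      n, -noise_relative_half_width * sigma,
      noise_relative_half_width * sigma
    )
  } else {
    spec$noise <- rep(sigma, n)
  }
  spec
}

#' Protocol constants: initial state, stop condition, parameter steps
#'
#' `initial_state()` is the common starting state of every simulation in a
#' sweep (`double_well` 1, `mutualistic` 5, `gene_regulatory` 5, `sis`
#' 0.001). `stop_condition()` is TRUE once any node has left its initial
#' state (`x_i >= 3`, `x_i < 0.1`, `x_i < 0.1`, `x_i >= 0.1` respectively).
#' `parameter_step()` is the signed increment of the bifurcation parameter
#' between consecutive simulations, and `sweep_start()` the initial
#' `(u, D)` pair: the parameter increases for `double_well` and `sis` and
#' decreases for `mutualistic` and `gene_regulatory`.
#'
#' @param spec A [dynamics_spec()] (or model string for `sweep_start`).
#' @param state Numeric state vector.
#' @param parameter `"u"`, `"D"`, or `"lambda"` (alias of `"D"` for SIS).
#' @return See details.
#' @name sweep_protocol
NULL

#' @rdname sweep_protocol
#' @export
initial_state <- function(spec) {
  x0 <- switch(spec$model,
    double_well = 1, mutualistic = 5, gene_regulatory = 5, sis = 0.001
  )
  rep(x0, spec$n_nodes)
}

#' @rdname sweep_protocol
#' @export
stop_condition <- function(spec, state) {
  switch(spec$model,
    double_well = any(state >= 3),
    mutualistic = any(state < 0.1),
    gene_regulatory = any(state < 0.1),
    sis = any(state >= 0.1)
  )
}

#' @rdname sweep_protocol
#' @export
parameter_step <- function(spec, parameter = c("u", "D", "lambda")) {
  parameter <- normalize_parameter(spec$model, match.arg(parameter))
  switch(spec$model,
    double_well = if (parameter == "u") 0.025 else 0.0025,
    mutualistic = if (parameter == "u") -0.1 else -0.01,
    gene_regulatory = -0.01,
    sis = 0.0025
  )
}

#' @rdname sweep_protocol
#' @export
sweep_start <- function(spec, parameter = c("u", "D", "lambda")) {
  model <- if (inherits(spec, "dynamics_spec")) spec$model else spec
  parameter <- normalize_parameter(model, match.arg(parameter))
  switch(model,
    double_well = if (parameter == "u") c(u = 0, D = 0.05) else c(u = 0, D = 0),
    mutualistic = c(u = 0, D = 1),
    gene_regulatory = c(u = 0, D = 1),
    sis = c(u = 0, D = 0)
  )
}

normalize_parameter <- function(model, parameter) {
  if (model == "sis") {
    if (parameter == "u") {
      stop("the SIS model is swept in its infection rate lambda, not u",
        call. = FALSE
      )
    }
    return("D")
  }
  if (parameter == "lambda") {
    stop("`lambda` is the SIS infection rate; use \"D\" for ", model,
      call. = FALSE
    )
  }
  parameter
}

# transient length and sample spacing in time units
transient_tu <- function(model) if (model == "mutualistic") 10 else 100
sample_spacing_tu <- function(model) if (model == "mutualistic") 0.1 else 1

#' Serialize a dynamics specification to a key-value config file
#'
#' YAML round-trip of everything needed to rebuild the specification; the
#' network is stored as an edge list inline.
#'
#' @param spec A [dynamics_spec()].
#' @param path File path.
#' @return `path` invisibly; `read_spec_config()` returns a
#'   `dynamics_spec`.
#' @export
write_spec_config <- function(spec, path) {
  el <- igraph::as_edgelist(spec$network, names = FALSE)
  yaml::write_yaml(
    list(
      model = spec$model, n_nodes = spec$n_nodes,
      edges = apply(el, 1, paste, collapse = " "),
      coupling = spec$coupling, stress = spec$stress,
      stress_offsets = spec$stress_offsets, noise = spec$noise
    ),
    path,
    precision = 15
  )
  invisible(path)
}

#' @rdname write_spec_config
#' @export
read_spec_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ends <- do.call(rbind, lapply(strsplit(cfg$edges, " "), as.integer))
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  g <- igraph::add_vertices(g, cfg$n_nodes - igraph::vcount(g))
  dynamics_spec(cfg$model, g,
    coupling = cfg$coupling, stress = cfg$stress,
    stress_offsets = as.numeric(cfg$stress_offsets),
    noise = as.numeric(cfg$noise)
  )
}
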