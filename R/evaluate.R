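#' Early warning signal series along a sweep
#'
#' For each pre-transition parameter value, the unbiased sample variance of
#' each node in `S` averaged over `S` (`kind = "variance"`), or the sample
#' standard deviation averaged over `S` (`kind = "standard_deviation"`, the
#' common alternative signal). Note the two coincide only up to a square
#' root for `n = 1`; for `n >= 2` the SD-average is not the square root of
#' the variance-average.
#'
#' @param sweep A [run_sweep()] result.
#' @param S Integer vector of node indices.
#' @param kind `"variance"` or `"standard_deviation"`.
#' @return A tibble with columns `parameter` and `signal`, one row per
#'   pre-transition parameter value; attributes `node_set`, `kind`,
#'   `parameter_name`.
#' @export
signal_series <- function(sweep, S, kind = c("variance", "standard_deviation")) {
  stopifnot(inherits(sweep, "sentinet_sweep"))
  kind <- match.arg(kind)
  S <- as.integer(S)
  vals <- purrr::map_dbl(sweep$samples, function(m) {
    v <- apply(m[, S, drop = FALSE], 2, var)
    if (kind == "variance") mean(v) else mean(sqrt(v))
  })
  out <- tibble::tibble(parameter = sweep$parameter_values, signal = vals)
  attr(out, "node_set") <- S
  attr(out, "kind") <- kind
  attr(out, "parameter_name") <- sweep$parameter_name
  class(out) <- c("sentinet_series", class(out))
  out
}

#' Kendall rank correlation between a signal series and its parameter
#'
#' Kendall's tau (tau-b under ties, via [stats::cor()]) between the early
#' warning signal and the bifurcation parameter. A perfect signal yields
#' `tau = 1` for an increasing sweep and `tau = -1` for a decreasing one. A
#' constant series has no defined rank correlation and returns `NA`.
#'
#' @param series A [signal_series()] tibble, or a numeric vector of signal
#'   values (then `parameter` must be supplied).
#' @param parameter Parameter values matching `series` when it is a bare
#'   vector.
#' @return Scalar in `[-1, 1]`, or `NA` for a constant series.
#' @export
kendall_tau <- function(series, parameter = NULL) {
  if (is.data.frame(series)) {
    parameter <- series$parameter
    series <- series$signal
  }
  stopifnot(length(series) == length(parameter), length(series) >= 2)
  if (sd(series) == 0 || sd(parameter) == 0) {
    return(NA_real_)
  }
  cor(series, parameter, method = "kendall")
}

#' Quality indices p1 and p2 of the d-maximizing node set
#'
#' Given the Kendall taus of all examined node sets of one size and the tau
#' `tau_star` of the d-maximizer, `p1` is twice the fraction of sets whose
#' tau is strictly larger than `tau_star` (0 = best, 1 = no better than a
#' random pick, 2 = worst) and
#' `p2 = (tau_max - tau_star) / (tau_max - mean(tau))` (0 iff the maximizer
#' attains `tau_max`, 1 iff it matches the average set). For downward
#' transitions (`direction = "down"`), where more negative tau is better,
#' all taus are negated before comparison.
#'
#' @param taus Numeric vector of taus over the examined node sets
#'   (including the optimized set).
#' @param tau_star Tau of the d-maximizing set.
#' @param direction `"up"` (larger tau better) or `"down"`.
#' @return Named numeric vector `c(p1, p2)`; `p2` is `NA` when all taus are
#'   equal.
#' @export
p1_p2 <- function(taus, tau_star, direction = c("up", "down")) {
  direction <- match.arg(direction)
  keep <- !is.na(taus)
  taus <- taus[keep]
  stopifnot(length(taus) > 0, !is.na(tau_star))
  if (direction == "down") {
    taus <- -taus
    tau_star <- -tau_star
  }
  p1 <- 2 * mean(taus > tau_star)
  tau_max <- max(taus)
  tau_mean <- mean(taus)
  p2 <- if (tau_max > tau_mean) (tau_max - tau_star) / (tau_max - tau_mean) else NA_real_
  c(p1 = p1, p2 = p2)
}

#' Sweep direction of a model
#'
#' `"up"` when the bifurcation parameter increases towards the transition
#' (double-well, SIS), `"down"` when it decreases (mutualistic, gene
#' regulatory).
#'
#' @param model Model identifier.
#' @return `"up"` or `"down"`.
#' @export
sweep_direction <- function(model) {
  if (model %in% c("double_well", "sis")) "up" else "down"
}

#' Simulation study: performance of d-based node-set selection
#'
#' Runs independent series of bifurcation-parameter sweeps; in each series
#' estimates the covariance matrices at the two measurement points, finds
#' the d-maximizing node set for each size `n`, computes the Kendall tau of
#' every examined set over the whole series, and summarizes the maximizer's
#' standing with [p1_p2()] and the Pearson correlation between tau and d
#' across sets. Heterogeneous stress/noise offsets are redrawn once per
#' series.
#'
#' @param spec A [dynamics_spec()] template.
#' @param parameter Swept parameter (`"u"`, `"D"`, or `"lambda"`).
#' @param n_values Node-set sizes to evaluate (default `1:5`).
#' @param n_series Number of independent series (default 50, as in the full
#'   study design).
#' @param seed Master seed.
#' @param heterogeneous_stress,heterogeneous_noise Heterogeneity condition
#'   passed to [make_heterogeneity()].
#' @param cap Node-set enumeration cap per size (default 5000).
#' @param L Samples per parameter value.
#' @param dt Integration time step.
#' @return A tibble with one row per (series, n): columns `series`, `n`,
#'   `K` (pre-transition values), `best_set`, `d_star`, `tau_star`,
#'   `tau_max`, `tau_mean`, `p1`, `p2`, `cor_tau_d`. Series whose sweep
#'   ends before two parameter values are dropped with a warning.
#' @export
run_experiment <- function(spec, parameter = c("u", "D", "lambda"),
                           n_values = 1:5, n_series = 50, seed = 1,
                           heterogeneous_stress = FALSE,
                           heterogeneous_noise = FALSE,
                           cap = 5000, L = 100, dt = 0.01) {
  stopifnot(inherits(spec, "dynamics_spec"))
  parameter <- match.arg(parameter)
  direction <- sweep_direction(spec$model)
  rows <- list()
  for (series in seq_len(n_series)) {
    set.seed(derive_seed(seed, series, 0L))
    spec_s <- make_heterogeneity(spec, heterogeneous_stress, heterogeneous_noise)
    sweep <- tryCatch(
      run_sweep(spec_s, parameter, seed = seed, series = series, L = L, dt = dt),
      error = function(e) {
        warning("series ", series, " dropped: ", conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (is.null(sweep) || length(sweep$parameter_values) < 2) {
      if (!is.null(sweep)) {
        warning("series ", series, " dropped: fewer than 2 pre-transition values",
          call. = FALSE
        )
      }
      next
    }
    covs <- sweep_covariances(sweep)
    # per-node variance at every parameter value, once per series
    V <- do.call(rbind, purrr::map(sweep$samples, function(m) apply(m, 2, var)))
    for (n in n_values) {
      set.seed(derive_seed(seed, series, 100000L + n))
      sel <- optimize_d(covs$C1, covs$C2, n, L = L, cap = cap)
      taus <- purrr::map_dbl(sel$sets, function(S) {
        kendall_tau(rowMeans(V[, S, drop = FALSE]), sweep$parameter_values)
      })
      best_key <- paste(sel$best$node_set, collapse = ",")
      tau_star <- taus[match(best_key, sel$scores$node_set)]
      p <- p1_p2(taus, tau_star, direction)
      signed <- if (direction == "down") -taus else taus
      rows[[length(rows) + 1]] <- tibble::tibble(
        series = series, n = n, K = length(sweep$parameter_values),
        best_set = best_key, d_star = sel$best$d,
        tau_star = tau_star,
        tau_max = if (direction == "down") -max(signed, na.rm = TRUE) else max(signed, na.rm = TRUE),
        tau_mean = mean(taus, na.rm = TRUE),
        p1 = p[["p1"]], p2 = p[["p2"]],
        cor_tau_d = suppressWarnings(cor(taus, sel$scores$d,
          use = "complete.obs"
        ))
      )
    }
  }
  if (length(rows) == 0) stop("no usable series", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  attr(out, "direction") <- direction
  out
}

#' Summarize a simulation study over series
#'
#' Mean p1, p2, and tau-d correlation per node-set size.
#'
#' @param experiment A [run_experiment()] tibble.
#' @return A tibble with one row per `n`.
#' @export
summarize_experiment <- function(experiment) {
  dplyr::summarise(
    dplyr::group_by(experiment, .data$n),
    n_series = dplyr::n(),
    p1 = mean(.data$p1, na.rm = TRUE),
    p2 = mean(.data$p2, na.rm = TRUE),
    cor_tau_d = mean(.data$cor_tau_d, na.rm = TRUE),
    .groups = "drop"
  )
}
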