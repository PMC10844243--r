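---
title: "Selecting sentinel node sets for early warning signals on networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting sentinel node sets for early warning signals on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentinet)
```

## The problem

Ecosystems, gene regulatory circuits, epidemics, and other networked
dynamical systems can undergo regime shifts: as a slowly varying parameter
(environmental stress, coupling strength, an infection rate) crosses a
bifurcation, the system jumps abruptly to a different stable state. Near
such a tipping point the dominant relaxation rate goes to zero — critical
slowing down — so fluctuations around the equilibrium grow, and the sample
variance of an observed node is a classic early warning signal.

On a network, not all nodes are equally informative. Nodes close to tipping
emit stronger signals; nodes with large intrinsic noise emit large but
uninformative signals; nearby nodes emit redundant, correlated signals.
`sentinet` implements a principled way to choose a *sentinel node set* `S`:
the subset of nodes whose per-node sample variances are averaged into one
signal,

$$\hat V_S = \frac{1}{n}\sum_{i \in S} \hat V_i, \qquad n = |S|.$$

## The model behind the statistic

Fluctuations `z = x - x*` around a stable equilibrium of a stochastic
dynamical system `dx = F(x) dt + B dW` are approximated by the linearized
multivariate Ornstein–Uhlenbeck process `dz = -A z dt + B dW`, where `A` is
the sign-flipped Jacobian. Its stationary covariance `C` solves the
Lyapunov equation `A C + C A' = B B'` (`solve_lyapunov()`); the solution is
unique when all eigenvalues of `A` have positive real part.

For `L` i.i.d. Gaussian samples with covariance `C`, the averaged variance
signal has exactly

$$E[\hat V_S] = \frac{1}{n}\sum_{i\in S} C_{ii}, \qquad
  \mathrm{var}[\hat V_S] = \frac{2}{n^2 (L-1)}\sum_{i,j\in S} C_{ij}^2,$$

implemented in `signal_moments()`. Three consequences shape the method:

* the coefficient of variation of a single-node signal is
  `sqrt(2/(L-1))` *regardless of the node* — a big signal carries
  proportionately big noise, so ranking nodes by signal size is
  meaningless;
* averaging over `n >= 2` nodes strictly lowers the CV unless the
  node states are perfectly correlated;
* but averaging in a noisy, unresponsive node can still hurt, because what
  matters is how the signal *changes* relative to its own spread.

That trade-off is captured by measuring the signal at two values of the
bifurcation parameter and computing the separability statistic

$$d = \frac{|\mu_1 - \mu_2|}{\sqrt{\mathrm{var}_1 + \mathrm{var}_2}}$$

(`d_statistic()`). The proposed sentinel set is the `S` maximizing `d`
(`optimize_d()`), which needs only the covariance matrices observed at the
two parameter values — not the network structure and not the model
equations.

## Closed-form validation models

Two toy systems built from the saddle-node normal form `dx/dt = r + x^2`
(stable branch `x* = -sqrt(-r)`, tipping at `r = 0`) validate the whole
pipeline analytically.

**Two nodes, directed edge.** Node 1 drives node 2 with weight `w`; node 2
feels extra stress `delta_r`. Equilibrium, Jacobian, and covariance are
closed-form (`two_node_equilibrium()`, `two_node_covariance()`). At the
study parameters (`w = 0.5`, `sigma1 = 0.1`, `L = 100`, measured at
`r = -0.3` and `-0.1`):

```{r}
d_table("two_node",
  r_values = c(-0.3, -0.1), w = 0.5,
  sigma1 = 0.1, sigma2 = 0.1, delta_r = 1, L = 100
)
```

The upstream node's `d` is invariant to `delta_r` and `sigma2` (nothing
feeds back into node 1), and averaging helps in scenario 1 but *hurts* when
node 2 is noisy (`sigma2 = 0.2`): `d` drops from 2.58 to 2.12.

**Three-node chain.** A symmetric chain 1–2–3 with coupling `w`; the
middle node receives input from both ends and tips first. The lower
equilibrium solves two coupled quadratics; the closed-form tangency bound
`chain_bifurcation_bound()` gives `r_c'' = 2w[-(w+1) + sqrt(w(w+1))]`
(about −0.082 at `w = 0.05`). Covariances are again closed-form
(`chain_covariance()`), and the `d` table reproduces the full ranking of
`S = {1}, {2}, {1,2}, {1,3}, {1,2,3}` across the three noise scenarios.

### A note on the outer-pair averaging factor

With `sigma3 = sigma1`, pairing the symmetric outer nodes keeps the mean
signal and shrinks its standard deviation. From the variance formula above,

$$\mathrm{std}[\hat V_{\{1,3\}}]
  = \mathrm{std}[\hat V_1]\,\sqrt{\tfrac{1+\rho^2}{2}},$$

where `rho = corr(x_1, x_3)`; since `corr(V_1, V_3) = rho^2` for Gaussian
fluctuations this is the textbook reduction from averaging two correlated
estimators, `sqrt((1 + corr(V_1, V_3))/2)`. `chain_pair_sd_factor()`
returns this factor. A linear (square-root-free) form of this relation
sometimes quoted for this model is inconsistent with the variance formula
except at perfect correlation; the package uses the form that follows from
the formula, and the Monte-Carlo moment tests confirm it.

## The simulation study

For networks too large for closed forms, the package simulates four
dynamics models (Euler–Maruyama, `dt = 0.01`, compiled inner loop):
coupled double-well (`(r1, r2, r3) = (1, 3, 5)`), mutualistic species
interactions, Michaelis–Menten gene regulation, and SIS epidemics. Each
model carries its protocol constants (initial states 1 / 5 / 5 / 0.001;
stop thresholds `x >= 3`, `x < 0.1`, `x < 0.1`, `x >= 0.1`; base noise
0.05 / 0.25 / 5e-6 / 5e-4; sweep steps ±0.025, ±0.0025, …) in
`dynamics_spec()` and the `sweep_protocol` helpers, so a sweep is fully
specified by the model, the network, and a seed.

A *sweep* (`run_sweep()`) simulates at linearly spaced parameter values —
increasing for double-well and SIS, decreasing for mutualistic and gene
regulatory — restarting every simulation from the same initial state,
discarding a transient (100 TU; 10 TU for the faster mutualistic model),
recording `L = 100` equilibrium samples spaced 1 TU (0.1 TU mutualistic),
and stopping once any node leaves its initial state. With `K`
pre-transition values, covariances are estimated at indices
`round(0.1 K)` and `round(0.9 K)`: early enough to be far from tipping,
late enough that the signal contrast is large.

`run_experiment()` repeats independent series, scores candidate node sets
by `d` from the two estimated covariances (exhaustively for `n <= 2`, 5000
random sets for larger `n`), measures each set's Kendall `tau` between its
signal series and the parameter, and summarizes the `d`-maximizer's
standing with

* `p1`: twice the fraction of examined sets with strictly larger `tau`
  (0 best, 1 equals a random pick, → 2 worst), and
* `p2 = (tau_max - tau*) / (tau_max - <tau>)` (0 iff the maximizer is the
  top performer, 1 iff it matches the average set).

For downward sweeps all `tau` comparisons are sign-flipped, since a perfect
signal then has `tau = -1`. Two baselines are included: `large_sd_select()`
(top-`n` nodes by state SD near the transition — strong under homogeneous
noise, misled by inherently noisy nodes under heterogeneous noise) and
`high_low_input_select()` (extreme total input from neighbors, which needs
the adjacency matrix).

### What the generators emulate — and what they do not

The network generators reproduce the study's topologies: G(n, M)
Erdős–Rényi with exactly 125 edges (`<k> = 5`), Barabási–Albert grown from
a triangle with `m = 2` (97 edges on 50 nodes, deterministically), and a
node-fitness model with `f_i = (i + i0 - 1)^(-alpha)`. Heterogeneity draws
`du_i ~ U[-0.25, 0.25]` and `dsigma_i ~ U[-0.9 sigma, 0.9 sigma]` once per
series, treating them as fixed node properties.

Synthetic sweeps capture critical slowing down under slow parameter drift
at equilibrium; they do not emulate measurement noise, irregular sampling,
non-stationary transients, or regime shifts without critical slowing down
(noise- or impulse-driven transitions), for which variance-based signals
are by design insensitive. Passing tests therefore demonstrate
correctness of the method under its own model assumptions, not performance
on any particular empirical system.

## Numerical choices

* **Lyapunov solver**: direct dense solve of
  `(I ⊗ A + A ⊗ I) vec(C) = vec(BB')`, symmetrized; residuals are checked
  below `1e-10` relative in the tests. Stability is required with
  tolerance `1e-12` on the smallest real part — near-critical systems are
  legitimately close to singular, so the tolerance is deliberately tiny.
* **Chain equilibrium**: eliminating `x2` gives a quartic in `x1`, but the
  back-substitution `x2 = -(r + x1^2)/w - 1` amplifies root error for
  small `w`; every quartic root and the decoupled `w = 0` seed are
  therefore polished by Newton iteration on the original pair of
  equations, and the positive-definite-Jacobian (stability) filter selects
  the physical branch. Past the tangency no stable root survives and a
  bifurcation-passed error is raised.
* **Rounding**: reported `d` values are rounded half away from zero (2
  decimals), matching the reporting precision of the reference values; the
  same convention implements the `round(0.1 K)` measurement-index rule,
  with the lower index clipped to 1.
* **Ties**: `optimize_d()` and the top-`n` rankings break ties by
  lexicographically smallest node set / lowest node index, and `p1` counts
  only *strictly* larger `tau` values, so ties never count against the
  optimized set.
* **RNG**: every simulation derives its own seed from the master seed and
  `(series, parameter index)`, so series are reproducible independently of
  execution order; the compiled integrator draws from R's RNG.
* **Degenerate inputs**: constant signal series have no defined rank
  correlation and propagate as `NA` (not 0); `p2` is `NA` when all `tau`
  are equal; sweeps that tip at the very first parameter value are errors,
  and a hard cap (default 10^4 values) guarantees termination.

## Open design points resolved here

* The fitness-model offset `i0 = N^(1-1/alpha) [10 sqrt(2) (1-alpha)]^(1/alpha)`
  has a negative bracket for `alpha = 2`; the package reads it as
  `|1 - alpha|`, flagged in the documentation as an interpretation. As
  printed, the pairwise connection probabilities sum to less than one, so
  the independent-pairs reading yields a near-empty graph; `net_fitness()`
  additionally offers a fixed-edge-count variant (pairs drawn with the
  same per-attempt probability until the target edge count) that produces
  the dense realizations the study design describes.
* The exact tangency point `r_c` of the chain is found numerically as the
  `r` where the stable root disappears; the closed form `r_c''` is exposed
  and the two agree to about 5% at `w = 0.05`.
* High/Low Input uses the time-averaged states over the `L` samples at the
  second measurement point as its "state near the bifurcation"; the
  instantaneous-state alternative differs only by sampling noise.
* Whether consecutive simulations should chain their final states is
  resolved in favor of restarting from the common initial state, which is
  what makes the per-value samples i.i.d. in the moment formulas.

## Scale of the shipped checks

The test suite validates the moment formulas against 10^5-replicate
Monte-Carlo draws, the closed-form covariances against the Lyapunov solver
on a 130-point parameter grid, and the full selection pipeline on a
reduced-scale study: 5 series of double-well `u`-sweeps on a 20-node BA
network with exhaustive node sets for `n = 1, 2`. At that scale the
`d`-maximizer's mean `p1` and `p2` are below 1 and `tau` and `d` are
positively correlated — the qualitative behavior of the full 50-node,
50-series design, which the same functions reproduce by changing the
arguments. Per-figure scatter values of the original study depend on
unpublished network realizations and seeds and are intentionally not
asserted.

## Limitations

The moment formulas assume i.i.d. Gaussian samples; samples taken 1 TU
apart along a trajectory are weakly autocorrelated, which the study design
mitigates by spacing rather than modeling. The sample covariance is used
as the estimator of `C` throughout — adequate here (`L = 100`,
`N <= 50`), but shrinkage estimators would be needed when `L` is small
relative to `N`. Lagged autocorrelation signals and metaheuristic search
over node sets for large `n` are out of scope.
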