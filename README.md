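# sentinet

Sentinel node selection for early warning signals of tipping points on
networks.

Networked dynamical systems — ecosystems, gene circuits, epidemics —
can shift abruptly between states when a slowly drifting parameter crosses
a bifurcation. Critical slowing down makes the fluctuations of observed
nodes grow beforehand, so the sample variance of a node is a standard
early warning signal. But on a network the nodes differ: some are close to
tipping, some are just intrinsically noisy, and nearby nodes give
redundant signals. `sentinet` answers the practical question *which subset
of nodes should you watch, and should you combine them?*

## The method

Fluctuations around a stable equilibrium are modeled as a multivariate
Ornstein–Uhlenbeck process `dz = -A z dt + B dW`, whose stationary
covariance `C` solves the Lyapunov equation `AC + CA' = BB'`. For the
node-set-averaged variance signal
`V_S = (1/n) Σ_{i∈S} V_i` estimated from `L` samples,

```
E[V_S]   = (1/n) Σ_{i∈S} C_ii
var[V_S] = 2 / (n² (L−1)) Σ_{i,j∈S} C_ij²
```

Measuring the signal at two values of a bifurcation parameter gives two
distributions with moments `(μ₁, var₁)` and `(μ₂, var₂)`, and node sets
are ranked by the separability statistic

```
d = |μ₁ − μ₂| / sqrt(var₁ + var₂)
```

The proposed sentinel set maximizes `d`. It needs only two covariance
snapshots — no network structure, no model equations — and it
automatically discounts nodes whose large signals are merely large noise
(for a single node the coefficient of variation is `sqrt(2/(L−1))`
whatever the node), while rewarding averaging exactly when the added nodes
are responsive and not too correlated.

The package ships: the exact moment/CV/d machinery and a Lyapunov solver;
closed-form two-node and three-node-chain validation models; network
generators (fixed-edge-count Erdős–Rényi, Barabási–Albert, node-fitness)
and an edge-list reader; Euler–Maruyama simulation (compiled inner loop)
of coupled double-well, mutualistic, gene-regulatory, and SIS dynamics
with the full sweep protocol; d-maximizing node-set search plus the
Large SD and High/Low Input baselines; and Kendall-τ based performance
indices `p1`/`p2`. A command-line front end lives at
`inst/cli/sentinet.R` (subcommands `analytic`, `network`, `sweep`,
`select`, `evaluate`).

## Worked example

Closed-form two-node model (node 1 drives node 2), with node 2 twice as
noisy — averaging *hurts* here and the method notices:

```r
library(sentinet)
d_table("two_node", r_values = c(-0.3, -0.1), w = 0.5,
        sigma1 = 0.1, sigma2 = 0.2, delta_r = 1, L = 100)
#> # A tibble: 3 × 6
#>   node_set     mu1        var1     mu2       var2     d
#> 1 1        0.00456 0.000000421 0.00791 0.00000126 2.58
#> 2 2        0.00982 0.00000195  0.0120  0.00000289 0.972
#> 3 1,2      0.00719 0.000000598 0.00993 0.00000107 2.12
```

Node 2 has the *largest* signal (`mu` column) but the worst `d`: its
variance is inflated by noise, not by proximity to tipping. Watching node
1 alone (`d = 2.58`) beats averaging both (`d = 2.12`).

Simulation pipeline on a 20-node Barabási–Albert network with coupled
double-well dynamics, sweeping the stress `u` until the first node tips:

```r
set.seed(7)
g <- net_ba(20, 2)
spec <- dynamics_spec("double_well", g)
sw <- run_sweep(spec, "u", seed = 7)
sw
#> <sentinet_sweep> double_well on 20 nodes | u swept over 89 pre-transition
#>   values [0, 2.2] | transition at 2.225
#>   measurement indices: k1 = 9 , k2 = 80

covs <- sweep_covariances(sw)
sel <- optimize_d(covs$C1, covs$C2, n = 2, L = 100)
glance(sel)
#> # A tibble: 1 × 5
#>       n n_candidates best_set d_max d_mean
#> 1     2          190 1,11      6.11   4.33

kendall_tau(signal_series(sw, sel$best$node_set))
#> [1] 0.765
```

The transition happens at `u = 2.225`; covariances are estimated at the
9th and 80th of the 89 pre-transition stress values; among all 190 node
pairs the maximizer of `d` is `{1, 11}`, and its averaged variance signal
trends strongly upward toward the tipping point (Kendall τ = 0.765).
`run_experiment()` repeats this over many series and reports how often the
`d`-maximizer beats the other examined sets (`p1`, `p2`);
`autoplot()`/`plot_tau_d()`/`plot_performance()` draw the standard
diagnostics.

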