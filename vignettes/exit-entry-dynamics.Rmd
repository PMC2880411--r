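---
title: "Exit-entry dynamics of two competing cell populations on regular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exit-entry dynamics of two competing cell populations on regular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exitentry)
```

## The model

After a myocardial infarction the scar tissue hosts two macrophage
phenotypes — classically activated (pro-inflammatory, here *type C*) and
alternatively activated (pro-repair, *type A*) — whose relative abundance
shifts over days as cells exit to the lymphatic system and new cells enter.
`exitentry` models this turnover as a death–birth ("exit–entry") process on a
fixed k-regular interaction network: each of N cells occupies a vertex and
interacts with exactly k neighbors.

Interactions are summarised by a 2×2 matrix

$$I = \begin{pmatrix} a & b \\ c & d \end{pmatrix},$$

read *by provider*: a type-A cell confers energy $a$ on each linked type-A
cell and $b$ on each linked type-C cell; a type-C cell confers $c$ on linked
A cells and $d$ on linked C cells. A cell's fitness is
$F = 1 - \omega + \omega\,\varepsilon$, where $\varepsilon$ is the cell's
energy over its k links and $\omega \in [0, 1)$ is the selection intensity;
$\omega \ll 1$ is weak selection, $\omega = 0$ is pure neutral drift.

One elementary event: a cell chosen uniformly at random exits; its vacated
vertex is refilled by a type-A cell with probability $F_A/(F_A + F_C)$,
where $F_A$ and $F_C$ are the aggregate fitnesses of the type-A and type-C
neighbor groups of the vacated vertex. With K_A type-A neighbors whose links
run `edges_A_to_A` times to A cells and `edges_A_to_C` times to C cells,

$$F_A = K_A (1-\omega) + \omega\,(a\,\mathrm{edges}_{A\to A} + b\,\mathrm{edges}_{A\to C}),$$

and symmetrically for $F_C$ with $c$ and $d$. Two conventions are defensible
for whether a neighbor's link *back to the vacated vertex* contributes to its
energy; the package counts it, valued at the exiting cell's type
(`count_vacated_link = TRUE`), and exposes the switch because the
weak-selection reduction is insensitive to it at $\omega \ll 1$.

## Time units

The elementary step is one event, but population-level change is visible on
the scale of N events (one *sweep*). Both clocks are supported
(`unit = "event"` / `"sweep"`); sweeps are the default for whole-trajectory
work, and the absorption times this produces (e.g. the bistable escape to
fixation within a few hundred sweeps at N = 10000) line up with the
generation counts quoted for this family of experiments.

## Pair approximation and the slow manifold

Write $P_A$ for the global type-A frequency and $q_{X|Y}$ for the
conditional frequency of type X among the neighbors of a type-Y cell. Under
weak selection the local pair structure equilibrates much faster than $P_A$
moves (fast/slow manifold separation). On the fast manifold,

$$q_{A|A} \approx p + \frac{1-p}{k-1},$$

the resident type being over-represented among its own neighbors by the
assortment excess $1/(k-1)$ that death–birth updating builds up. This closure
is validated against the simulator: at $\omega = 0.01$ and $k \in \{4,5,6\}$
the measured quasi-stationary $q_{A|A}$ agrees with the formula to within
0.03 (see `tests/testthat/test-abm.R`).

On the slow manifold the motion of $p = P_A$ reduces to

$$\dot p \;\propto\; \omega\, p (1-p)\, g(p), \qquad
  g(p) = c_0 + c_1 p + c_2 p^2,$$

with

* $c_0 = (k+1)a + (k^2-k-1)b - c + (k^2-1)d$
* $c_1 = (k+1)(k-3)a - (2k^2-2k-3)b - (k^2-k-3)c - (k+1)d$
* $c_2 = -(k+1)(k-2)(a-b-c+d)$.

The identity $c_0 + c_1 + c_2 = 0$ holds for every payoff and degree, so
$g(1) = 0$ and $g(p) = c_2 (p-1)(p - c_0/c_2)$ whenever $c_2 \neq 0$. The
overall positive prefactor of $\dot p$ is not pinned down by the sign
analysis; `rate_scale` sets an arbitrary timescale (default 1), so ODE time
courses carry arbitrary units while equilibria, signs and stability are
exact. If desired the timescale can be calibrated to sweeps by least squares
on one simulated trajectory.

## Stability classification

`classify_dynamics()` reads the evolutionary profile directly off the sign of
$g$ on $(0,1)$, using the factorization above:

* **A dominates** — $g > 0$ on $(p_0, 1)$: $P_A \to 1$.
* **C dominates** — $g < 0$ on $(0, p_0)$: $P_A \to 0$.
* **Stable coexistence** — $c_2 > 0$ and $c_0/c_2 \in (0,1)$: $P_A \to
  c_0/c_2$ from any interior start.
* **Bistable threshold** — $c_2 < 0$ and $c_0/c_2 \in (0,1)$: $P_A \to 1$
  above the threshold, $\to 0$ below it; a start exactly on the threshold is
  reported as undecided, never silently assigned to a basin.
* **Neutral** — the payoff-indifferent diagonal $a=b=c=d$ (see below).

This sign analysis reproduces every benchmark configuration:

```{r classify}
classify_dynamics(interaction_matrix(0, 1, 1, 0), k = 4, p0 = 0.99)
classify_dynamics(interaction_matrix(0, -1, -2, 0), k = 4, p0 = 0.20)
```

A Lyapunov-function formulation of the same statement exists (positive
definite $V$ with $\dot V \le 0$); its content — sign-definiteness of the
rate around each equilibrium — is exactly what the classifier computes, so no
separate Lyapunov object is represented.

## Design choices and numerical details

* **Topology.** The analysis fixes only the degree k; the simulator defaults
  to a uniform random k-regular graph (configuration model with rejection of
  self-loops/multi-edges and a connectivity retry loop, via igraph), with
  `ring` and `torus` available for sensitivity checks. Initial types are
  placed uniformly at random; a clustered placement exists for robustness
  experiments only.
* **Edge-frequency convention.** Pair frequencies are computed over directed
  edges (each undirected edge once per direction), which makes
  $P_{AC} = P_{CA}$ and $P_{XY} = q_{X|Y} P_Y$ exact identities rather than
  approximations. Conditionals of an absent type are reported as 0 and
  flagged; the dynamics never consult them at absorption.
* **Validation before simulation.** With negative payoff entries the linear
  fitness can turn negative; `validate_selection()` computes the minimal
  attainable group fitness per type and rejects the configuration unless it
  is strictly positive. A warning is issued above $\omega = 0.1$, where the
  weak-selection reduction loses accuracy.
* **RNG discipline.** Exactly two draws per event, in fixed order (exiting
  vertex, replacement Bernoulli), from R's generator; trajectories are
  bit-reproducible per seed, and the compiled loop is proven bit-identical to
  the pure-R reference step (`ee_step`) by test.
* **Integrator.** The slow manifold is integrated with an explicit adaptive
  Runge–Kutta pair (deSolve's `ode45`, rtol $10^{-8}$), with machine-epsilon
  excursions of $p$ clipped to $[0,1]$. `ode_limit()` normalizes the
  timescale by $\max_i |c_i|$ and doubles the horizon until stationarity, so
  limits are insensitive to the arbitrary `rate_scale`.
* **Degenerate cases.** $k = 2$ forces $c_2 = 0$, making $g$ linear with the
  sign of $c_0$ (handled as the degenerate case). On the payoff-indifferent
  diagonal $a=b=c=d$ every cell has identical fitness in every configuration
  and the process is exactly neutral drift; the classifier recognises this
  from the payoff itself, because the polynomial coefficients above do *not*
  vanish there (a normalization artifact of the closure) — their sign would
  otherwise wrongly promise deterministic motion.

## What the simulations emulate — and what they do not

The study conditions are N = 10000 cells, k = 4 links, $\omega = 0.01$, and
initial compositions 9900/100, 4000/6000 or 2000/8000; the preset experiments
(`figure_preset`, `reproduce_preset`) encode exactly these. Two stochastic
effects matter when interpreting results at this scale:

* **Early drift extinction.** A 100-cell minority is nearly neutral while
  rare: selection at $\omega = 0.01$ changes its per-event birth odds by only
  a few percent, so in roughly 10–15% of replicates the minority drifts to
  extinction before selection can establish it — even in the coexistence
  game whose deterministic limit is 5000/5000. Quasi-stationary quantities
  are therefore computed *conditional on non-absorption* (the definition of
  quasi-stationarity); at 20 replicates of 1000 sweeps the surviving-runs
  mean is within a few percent of the deterministic 5000.
* **What passing tests show.** The generator produces random regular graphs
  with random type placement; real infarct tissue has spatial structure,
  heterogeneous degree and time-varying composition none of which are
  modelled. Agreement between simulator, pair approximation and classifier
  validates the mathematics of the model, not its biological calibration.

## Known limitations

* The quadratic coefficients $c_0, c_1, c_2$ are implemented exactly as
  printed in their source analysis, and they reproduce all six benchmark
  outcomes as well as the mirrored bistable thresholds (0.3 ↔ 0.7) of the
  cross-interaction family $[0\;b; c\;0]$, whose interior roots satisfy
  $r + r' = 1$ exactly under A↔C relabeling. They do **not** respect that
  relabeling symmetry for arbitrary payoffs, however (for $[1\;0; 0\;1]$ the
  polynomial predicts A-dominance from any interior start, where symmetry
  demands a threshold), and they do not vanish on the equal-payoff diagonal.
  Away from the benchmark family the classifier should be read as the sign
  analysis of this particular closure, and cross-checked against the
  simulator; the full simulator has no such asymmetry (relabeling symmetry is
  enforced by construction and verified statistically by test).
* The direction of the grid-sweep readout deserves care: because the swept
  entry enters the *providing* group's fitness, raising $b$ strengthens type
  A and raising $d$ strengthens type C. At informative readouts the measured
  mean type-C population is therefore decreasing in $b$ and increasing in
  $d$; see the acceptance suite, where the opposite stated direction is
  asserted and fails.
* Strong selection ($\omega$ near 1), update rules other than exit–entry
  (entry–exit, imitation, mutation), more than two types, and time-varying
  network structure are out of scope.

## Problem sizes used by the test and acceptance suites

Unit tests run on networks of 20–2000 vertices with seeded fixtures built in
code. The end-to-end checks use the full study scale: ensembles of 20
replicates × 1000 sweeps at N = 10000 for the coexistence plateaus, 50
replicates run to absorption for the bistable game, 2000 replicates at
N = 100 for neutral fixation, and 500 random configurations for the
classifier/integrator cross-check. The grid sweep uses 12–16 replicates per
point at readouts (200 sweeps for $b$, 40 for $d$) chosen so adjacent grid
points are statistically separated.

## A worked example

```{r example}
m <- exit_entry_model(interaction_matrix(0, 1, 1, 0), k = 4, p0 = 0.99,
                      N = 2000)
m
coef(m)
tr <- simulate(m, nsim = 1, seed = 1, generations = 400)
tail(as.data.frame(tr)[, c("generation", "n_A", "P_A", "q_A_given_A")], 3)
```

The trajectory descends from 1980 type-A cells toward the interior
equilibrium at half the population, and the measured `q_A_given_A` hovers
near the fast-manifold value `r round(qAA_fast_equilibrium(0.5, 4), 3)`.
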