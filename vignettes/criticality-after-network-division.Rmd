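---
title: "Cluster-based criticality indicators on divided networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based criticality indicators on divided networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

A popular diagnostic of whether a dynamical system operates near a continuous
phase transition is the time-averaged size of its second-largest cluster of
co-active elements, $S_2$: at the critical value of the control parameter the
system fragments into many large clusters and $S_2$ shows an interior peak.
In brain-network modeling this diagnostic is applied to simulated activity on
structural connectomes, and an *absent* $S_2$ peak has been read as evidence
that an injured brain can no longer reach criticality.

`criticonn` implements the models and measures needed to examine a competing
explanation: when structural damage splits a network into weakly connected or
disconnected subsystems, the whole-system cluster ranking mixes clusters from
different subsystems, and the $S_2$ peak can disappear *even though every
subsystem remains critical*. The peak loss is then an ordering artifact of
lost network integrity, not lost criticality.

# Models

## Excitable automaton on a weighted network

Each node of a weighted network (entry $w_{ij}$ = weight of the connection
from node $j$ into node $i$) is inactive (I), active (A), or refractory (R).
One synchronous step, evaluated against the start-of-step state:

* $A \to R$ always;
* $R \to I$ with probability $r_2$;
* $I \to A$ deterministically if $\sum_{j\,\text{active}} w_{ij} > \mathcal{T}$
  (strict inequality), otherwise spontaneously with probability $r_1$.

The activation threshold $\mathcal{T}$ is the control parameter. Simulations
start with $\lceil 0.01\,N \rceil$ active nodes chosen uniformly, run for
`t_max = 10000` steps, and discard the first `t_init = 200`; the raster is
then conflated to active/non-active (refractory $\to$ 0) before any cluster
or activity statistic is computed. The standard rates tie the timescale to
the system size: $r_1 = 2/N$ and $r_2 = r_1^{0.2}$ ($r_2 \approx 0.29$ at
$N = 998$); `default_rates()` implements this rule, and `gh_params()` accepts
any explicit pair (for the Watts–Strogatz runs the conventional choice is
$r_1 = 0.001$, $r_2 = 0.3$).

A mean-field estimate of the critical threshold is
$\mathcal{T}_c = \langle w^{\mathrm{in}} \rangle\, r_2 / (1 + 2 r_2)$
(`mean_field_tc()`). With homeostatic normalization
$\tilde w_{ij} = w_{ij} / w^{\mathrm{in}}_i$ (`normalize_in_strength()`)
every node receives unit total input and
$\langle w^{\mathrm{in}} \rangle = 1$.

Design choices worth making explicit:

* **Synchronous semantics.** All three transitions read the start-of-step
  state; a node activated within a step is not an active neighbor until the
  next step.
* **Initial-condition rounding.** The 1% initially active nodes are
  $\lceil 0.01 N\rceil$; for $N = 324$ that is 4 nodes.
* **Strict threshold test.** Input exactly equal to $\mathcal{T}$ does not
  activate; this matters only on measure-zero inputs but is asserted in the
  tests.

## Ising model on (divided) square lattices

Spins $s_i = \pm 1$ live on a nonperiodic square lattice (or any unit-weight
network); the energy counts each unordered bond once,
$E = -J \sum_{\{i,j\}} s_i s_j$. A sweep proposes $N$ uniformly chosen
single-spin flips, each accepted with probability
$\min(e^{-\Delta E/T}, 1)$, $\Delta E = 2 J s_i \sum_{j \sim i} s_j$.
The standard protocol is $J = 1$, a $100 \times 100$ lattice, initial spins
$-1$ with probability 0.75, 30 equally spaced temperatures between 0.01 and
4.5, 5000 sweeps with 200 discarded. Under the bond-once convention the
infinite-lattice critical temperature is
$T_c = 2/\ln(1+\sqrt{2}) \approx 2.27$.

One convention deserves emphasis: a sum over ordered pairs would double every
bond and shift $T_c$ to $\approx 4.54$; all formulas and the compiled kernel
use the bond-once convention consistent with $T_c = 2.27$. Proposal order
within a sweep is random with replacement by default (`sequential = TRUE` is
exposed for sensitivity checks; the cluster statistics are insensitive to the
choice).

`build_lattice()` constructs undivided lattices and the two studied
divisions: `equal_halves` (two $R \times C/2$ rectangles, all crossing bonds
removed) and `central_patch` (a centered $s \times s$ patch disconnected from
its complement; $100\times100$ with $s = 50$ gives subsystems of 7500 and
2500 sites). Divisions remove *all* bonds between the parts, so subsystem
dynamics are exactly independent.

## Clusters and the ordering decomposition

A cluster is a maximal set of nodes with the same activity value connected
through the symmetrized structural support ($w_{ij} + w_{ji} > 0$); for the
excitable automaton only *active* nodes form clusters, for the Ising model
every site belongs to a same-spin domain. `find_clusters()` and
`cluster_series()` compute per-time-step sizes; `time_average()` gives
$S_i = t_{\mathrm{sim}}^{-1}\sum_t S_i(t)$; missing ranks count as zero.

For a network fully divided into subsystems A and B, every whole-system
cluster lies inside one subsystem, so at each step
$$S_1(t) = \max\big(S_1^A(t), S_1^B(t)\big), \qquad
S_2(t) = \mathrm{2nd\ largest\ of}\ \big\{S_1^A(t), S_2^A(t), S_1^B(t),
S_2^B(t)\big\}.$$
`ordering_decomposition()` implements this selection, and the test suite
asserts it reproduces the directly measured whole-system series *exactly*,
step by step, for both dynamics. This identity is the heart of the package's
argument: when $N_A = N_B$, the two largest whole-system clusters are almost
always $\{S_1^A, S_1^B\}$, so $S_1$ and $S_2$ share one functional form —
saturating at $N/2$ at the ordered end — and the interior $S_2$ peak
disappears from the whole-system curve while both subsystem curves retain it.
For $N_A > N_B$, $S_2^A$ and $S_1^B$ compete for the second rank near the
transition, producing the same loss above a subsystem-size threshold.

## Artificial strokes

`apply_node_severity()` selects a fraction (severity) of the target module's
nodes — rounded half-up — and removes all their connections to the rest of
the network, both directions; `apply_edge_fraction()` removes a fraction of
the undirected inter-module connections chosen uniformly (a tract is one
connection: both directions are zeroed together). Both variants leave the
module's internal structure and the node count untouched, so parcellations
remain valid; severity 1 disconnects the module exactly.
`lesion_ensemble()` draws seeded realizations and averages any named numeric
summary over them (20 realizations is the conventional ensemble size).

## Integrity measures

For a weighted, possibly directed graph: conductance of a node set $S$,
$$h_G = \frac{\sum_{i \in S, j \in \bar S}(w_{ij} + w_{ji})}
{\min(\mathrm{vol}\,S, \mathrm{vol}\,\bar S)}, \qquad
\mathrm{vol}\,S = \sum_{i \in S} w^{\mathrm{out}}_i,$$
modularity
$Q = (2w)^{-1}\sum_{ij}(w_{ij} - w^{\mathrm{out}}_i w^{\mathrm{in}}_j/2w)\,
\delta_{c_i c_j}$, its ceiling $Q_{\max}$ for a perfectly mixed network with
the same strengths, and the normalized $Q/Q_{\max}$ (1 exactly when no weight
crosses modules). Community detection delegates to the Louvain heuristic
(igraph) with 10 seeded restarts, but every reported $Q$ is evaluated by this
package's own formula, never the library's. The summary statistic coupling
dynamics to structure is the area under the $S_2(\mathcal{T})$ curve,
$I_2 = \int S_2\, d\mathcal{T}$ (trapezoidal, over the sweep grid; curves
being compared must share one grid), and across lesion conditions all
quantities are reported as relative changes $(A - A^0)/A^0$ against the
unmodified network.

# The synthetic connectome generator

The package has no access to empirical connectomes, so `networks` ships two
generators that define the study conditions:

* **Watts–Strogatz small-world networks** (`generate_ws_network()`):
  $N = 2000$, ring degree $k$ with single-endpoint rewiring at probability
  $\pi = 0.5$, i.i.d. exponential weights $p(w) = \lambda e^{-\lambda w}$,
  $\lambda = 12.5$. Total degree $k = 10$ yields a continuous transition
  (interior $S_2$ peak); $k = 2$ yields transient, non-critical dynamics.
  The rewiring preserves the edge count $nk/2$ exactly and avoids duplicate
  edges.
* **Modular connectomes** (`generate_modular_connectome()`): a weighted
  stochastic-block network of $N = 998$ nodes in 8 labeled modules (one of
  119 nodes, labeled `auditory`, the conventional lesion target), exponential
  weights with $\lambda = 12.5$, each module internally connected. The free
  density parameters default to mean within-module degree 12 and cross-module
  degree 3. These were calibrated — once, against the reference magnitudes of
  the *healthy* in-strength-normalized system (largest active cluster
  $\approx 0.17N$ at low threshold; an interior $S_2$ peak of order
  $0.006N$) — because at substantially higher densities the normalized
  dynamics collapse abruptly with a vanishing $S_2$ peak and make a poor
  stand-in for an empirical connectome.

What the generator does *not* emulate: heavy-tailed weight distributions
(streamline counts in real tractography span orders of magnitude; the
exponential law has a thin tail), spatial embedding and distance-dependent
wiring, hub/rich-club organization, and inter-subject variability. Passing
tests on these networks therefore demonstrate properties of the *models and
measures*, not of any particular empirical dataset.

## A known consequence: the mean-field gap

On the normalized synthetic connectomes the simulated $S_2$-peak threshold
sits at $0.75$–$0.78$ of the mean-field $\mathcal{T}_c$ — slightly more than
two grid steps of the default sweep grid below it — and this offset is robust
across topology variants (block, hierarchical, heavy-tailed-degree and
ring-module versions were all probed) and across seeds. The reason is the
thin exponential weight tail: after unit in-strength normalization no node
has the few dominant afferents that would let activity reverberate close to
the mean-field balance point, so fluctuations kill the active phase somewhat
earlier than mean field predicts. Empirical connectomes, with their
heavy-tailed weights, are reported to get closer (within roughly 20% of the
estimate). The acceptance suite asserts the two-grid-step consistency bound
and documents this as the one check the synthetic family does not meet; all
qualitative conclusions (peak loss under division, integrity coupling) are
unaffected.

# Sweeps, seeds, and reproducibility

`threshold_sweep()` / `temperature_sweep()` run one independent simulation
per grid point. Sub-seeds are derived deterministically from the master seed
(an affine map modulo $2^{31}-1$), so results are independent of execution
order and bit-reproducible; every table records its sub-seeds. The default
threshold grid spans $[0.2, 3] \times \mathcal{T}_c^{\mathrm{MF}}$ with 30
points so the transition is covered for arbitrary synthetic networks; the
default temperature grid is the 30-point $[0.01, 4.5]$ protocol.
Indicator conventions: population (divisor $t_{\mathrm{sim}}$) moments for
$\langle A \rangle$, $\sigma_A$ and the $S_1$ variance; lag-1 autocorrelation
$\rho(1)$ computed on the raw total-activity series (magnetization modulus
for spin rasters) with the zero-variance case defined as 0; curve argmax
ties broken toward the smaller grid value; "loss of peak" operationalized as
a boundary argmax of $S_2$ over the sweep grid.

# Experiment orchestration

`run_experiment()` binds the modules into five reproducible experiments
(`ws_contrast`, `stroke_sweep`, `structural`, `ising_divided`, `comb`)
configured by a named list or YAML file (YAML rather than a bespoke format,
since a robust parser ships with the environment), writing TSV tables and a
JSON summary per run; `make_report()` regenerates plots from saved bundles
without re-simulation. The test suite exercises reduced problem sizes
(lattices from $12^2$ to $40^2$ with shortened sweeps for qualitative
claims; the full $100\times100$, 30-temperature, 5000-sweep protocol for the
critical-temperature check; 200-node connectomes with 10-realization lesion
ensembles for the integrity trends; full 998-node connectomes for peak-loss
and mean-field checks) — chosen as the smallest systems for which the
respective phenomena are unambiguous.

# Limitations

* Cluster-size *distributions* and avalanche statistics are out of scope;
  only the two largest clusters are tracked.
* The Ising implementation targets unit-weight bonds (binary support);
  weighted couplings, external fields, periodic boundaries and cluster
  updates (Wolff/Swendsen–Wang) are not implemented.
* The lesion model is deliberately minimal — it reproduces global integrity
  statistics, and makes no claim of biological mechanism.
* Conductance requires positive volume on both sides of the cut; the fully
  disconnected case is defined as 0.
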