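---
title: "Flow-based analysis of directed connectomes: models and design choices"
author: "wormflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-based analysis of directed connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormflow)
```

# The model

All analyses in this package are built on one linear dynamical system. A
connectome is a directed, weighted graph: `A[i, j]` counts the synapses from
neuron `i` to neuron `j`, split into a directed chemical channel and a
symmetric gap-junction channel (`A = chem + gap`). Signal mass `phi(t)` (a
row vector summing to one) diffuses along edges according to

    dphi/dt = phi (M - I),      phi(t) = phi(0) exp(t (M - I)),

where `M` is the teleported transition matrix: a node passes a fraction
`tau` of its outflow along its outgoing edges in proportion to their weights
and re-injects the remaining `1 - tau` uniformly; a node with no outgoing
synapses (a sink) redistributes uniformly. Teleportation models diffuse
interaction with the environment and, mathematically, guarantees a unique
stationary distribution `pi` (PageRank) even though the graph is not
strongly connected. We use `tau = 0.85`, the value customary in the PageRank
literature, everywhere — including on synthetic and similarity graphs — so
that every stage probes the same dynamics.

Three analyses sit on top of this kernel:

**Multiscale flow communities (Markov Stability).** For a partition with
indicator matrix `H`, the clustered autocovariance
`R(t) = H' (diag(pi) exp(t(M - I)) - pi'pi) H` measures the probability
that diffusing mass starting in a community is found in a community after
Markov time `t`, in excess of chance; its trace `r(t, H)` is the Markov
Stability of the partition. Maximising `r` over partitions at each `t`
yields finer communities at small times and coarser ones at large times:
the Markov time is the resolution parameter. The objective's trace is
invariant under symmetrisation of the autocovariance, so the optimiser works
on `(B + B')/2` — the standard reduction that makes modularity-type
heuristics applicable to directed flows; the optimisation itself is a
Louvain-style greedy algorithm implemented in C++ (local moves with strictly
positive gains, then aggregation, repeated to convergence).

**Robustness criteria.** At each time the optimiser runs `ell` times from
seeded random visit orders. Two signals identify meaningful partitions: the
ensemble's mean pairwise normalised variation of information `<VI>(t)`
(consistency: dips mean the optimiser keeps finding the same structure),
and the cross-time matrix `VI(t, t')` between best partitions (persistence:
plateaux mean the same partition is optimal over a stretch of Markov time).
`select_robust_partitions()` returns, for every maximal plateau (pairwise
VI below `eps_plateau` with a constant community count) whose `<VI>` dips
below `dip_threshold`, the partition at the time of lowest `<VI>`.

**Ablations.** Deleting a node removes its row and column from both synapse
channels. The robustness route compares the `<VI>(t)` curve of every
single deletion against a Gaussian-process fit to the whole ensemble of
curves and flags sustained outliers (at least two predictive standard
deviations away over a contiguous log-time interval longer than the epoch
width `ln(t2/t1)` of the reference partition). The make-up route computes
the community variation `CV = min_t VI(P_ref, P_deleted(t))` and flags
scores above `P90 + |P90 - P10|`. Double deletions are compared against the
additive prediction (the mean of the two single CVs) by pinball-loss
quantile regression on a dense grid of levels; a pair's quantile score is
the highest level whose fitted curve lies at or below the pair's observed
CV, and per-node over-representation in the top pairs is tested with
one-sided Fisher exact tests (unadjusted).

**Flow roles (role-based similarity).** Each node's profile counts its
damped in- and out-paths of all lengths: blocks `rowSums((beta A')^k)` and
`rowSums((beta A)^k)` for `k = 1..K`, with `beta = alpha / lambda1` so
contributions decay geometrically (`alpha = 0.95` by default; `K` grows
until appended blocks stop changing any node's normalised profile
direction, capped at 50). Cosine similarity of profiles gives `Y`; a
relaxed minimum spanning tree sparsifies it (keep the MST plus any edge
beating the weakest link of its MST path, relaxed by a local density term
`gamma (d_i^k + d_j^k)`); the similarity graph is clustered with the same
stability sweep. Role ids are ordered by descending mean out-strength, so
role 1 is the most source-like.

**Stimulus propagation.** A unit of flow is localised uniformly on a set of
input neurons and propagated; `theta(t) = phi(t) - pi` (sums to zero,
decays to zero) and `q_i(t) = phi_i(t) / pi_i` describe each node's path to
stationarity. Nodes whose `q` transiently exceeds 1 overshoot; those with
`q_max > 1 + 2/3` are strong responders, and their peak times, stratified
by neuron type or flow role, summarise the propagation cascade.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tau` | 0.85 | teleportation; fraction of flow following edges |
| time grid | 200 log-spaced points on [0.01, 1000] | Markov-time resolution sweep ("paper mode"); screens use 50 points |
| `ell` | 100 (sweeps), 20 (screens) | optimisation ensemble size per time |
| `eps_plateau` | 0.02 | normalised VI under which best partitions count as identical |
| `dip_threshold` | 0.05 | `<VI>` consistency threshold |
| `alpha` | 0.95 | damping of long paths in role profiles |
| RMST `k`, `gamma` | 1, 0.5 | local-density neighbour index and relaxation strength |
| strong threshold | 5/3 | `q_max` cutoff for strong responders |
| propagation grid | 300 log-spaced points on [0, 200] | resolves order-one peak times; `q_max` agrees with a 10x finer grid to well under 1% |

The plateau and dip thresholds are package defaults: the selection criteria
are qualitative ("low values or dips") and any operational rule needs
numbers; both are exposed as arguments.

# The synthetic generator

Real wiring data cannot ship with the package, so every downstream stage is
exercised on seeded synthetic connectomes with planted ground truth
(`synthetic_spec()` / `generate_connectome()`). The generator emulates the
statistical skeleton of a somatic connectome: directed integer-weighted
edges (geometric weight law, mean 2.7), a two-level assortative block
hierarchy, a gap-junction-like symmetric channel (about 887/6394 of edge
weight, placed within fine blocks so that direction-bias constraints cannot
be violated by the duplication), planted upstream/middle/downstream flow
layers biasing edge direction, at least one pure sink, and optional bridge
nodes. The defaults echo the headline statistics reported for the
*C. elegans* somatic connectome: 279 neurons, mean out-strength about 29,
a single sink. What the generator does *not* emulate: degree-sequence or
motif structure, spatial wiring costs, neuron-class-specific connectivity
rules, or correlated weight distributions. Passing the recovery suites
therefore demonstrates that the machinery detects the structure it is
designed to detect, not that real connectomes contain such structure.

## Frozen study fixtures

The tests and the acceptance script use three reduced fixtures, chosen once
and documented here. Reduced settings (n <= 60, 50 time points, ell = 20)
keep the whole synthetic suite desk-scale.

*Hierarchy* (n = 60, 4 fine blocks in 2 coarse, p = 0.5 / 0.05 / 0.005):
two-level recovery requires the planted partition to be the stability
optimum with margin; at weaker contrast (e.g. 0.4 / 0.1 / 0.01) the
realised optimum legitimately differs from the planted labels on a few
nodes, which is a detectability property of block models, not an optimiser
failure — we verified that the optimiser's partitions score strictly above
the planted ones in those regimes.

*Feed-forward roles* (n = 60, layers 24/12/24, flat p = 0.4, full
direction bias, analysed with RMST `k = 5`): planted homogeneous layers
give near-duplicate profiles, so within-layer cosine distances are nearly
degenerate and the RMST local-density term needs a deeper neighbour
(`k` about 5 percent of `n`) to retain enough within-layer edges for the
flow clustering; with the default `k = 1` the pruned graph is close to a
tree and branch artefacts dominate. A k-means oracle on the raw profiles
confirms the features separate the layers; the pipeline then matches.

*Ablation screen* (n = 40, 4 fine blocks in 2 coarse, p = 0.5 / 0.005 /
0.005, one bridge): the bridge is the top-out-strength node with its whole
chemical out-neighbourhood rewired uniformly across three foreign blocks,
and background between-block coupling is near zero, so the coarse reference
partitions are bridge-mediated and its deletion measurably disrupts them.
An earlier design (half-rewiring over appreciable background coupling)
produced the opposite: deleting the bridge *cleaned up* the structure and
its community variation was the lowest in the ensemble. A planted
"disruptive target" must carry structure, not just noise.

# Numerical choices

- **Heat kernels.** `exp(t(M - I))` is computed from one eigendecomposition
  of `M` reused across the time grid, validated against a
  scaling-and-squaring matrix exponential at the median time (tolerance
  1e-9); if the eigenbasis is ill-conditioned every kernel falls back to
  scaling-and-squaring. No time discretisation is involved anywhere.
- **Stationary distribution** by dense left eigendecomposition with a
  power-iteration fallback (tolerance 1e-12).
- **Louvain tie-breaks.** A node moves only on a strictly positive gain
  (> 1e-12), so equal-gain moves keep the current community; node visit
  order is shuffled per run from the seeded RNG — deterministic given the
  seed, diverse across the ensemble.
- **Washout guard.** Teleportation bounds every structural eigenvalue of
  `M` by `tau`, so the autocovariance amplitude decays at least like
  `exp(-(1 - tau) t)`; beyond `t ~ ln(1e3)/(1 - tau)` (about 46 at
  `tau = 0.85`) the objective is numerical noise and the optimal community
  count degenerates back towards singletons. `select_robust_partitions()`
  truncates the sweep at sharp upward jumps of the community count, and the
  role-clustering step ignores plateaux that begin beyond the washout
  horizon, preferring the longest-lived robust plateau before it.
- **Community variation across node sets.** A reference partition of `n`
  nodes and a partition of an ablated network live on different node sets;
  the reference is restricted to the survivors and the VI is normalised by
  `log` of the surviving count — the only well-defined comparison. This
  convention affects all CV values and is applied uniformly.
- **GP regression** (robustness outliers): exact GP with a
  squared-exponential kernel on log Markov time plus white noise,
  hyperparameters by marginal-likelihood maximisation. All curves share one
  grid, so the likelihood is evaluated through per-time means and
  within-time scatter (cost scales with grid size, not curve count), and
  the predictive sd includes the noise term — it describes the spread of
  curves, which is what the two-sigma rule needs. The sustained-outlier
  span is measured in natural-log Markov time by default (a grid-point
  count variant is available), since epochs are log-time intervals.
- **Quantile scoring**: linear pinball-loss quantile regression
  (`quantreg`) on levels 0.005..0.995 in steps of 0.005, followed by
  monotone rearrangement (sorting the fitted values per observation), which
  removes quantile crossings without changing their distribution. A
  degenerate predictor falls back to marginal quantiles with a warning.
- **Interchangeable nodes.** For duplicate flow profiles the trace
  objective strictly prefers singletons (off-diagonal autocovariance is
  negative at all finite times), so role clustering collapses nodes joined
  by similarity >= 1 - 1e-9 into one role after clustering; a graph of
  identical nodes yields a single role.
- **Overshoot tolerance.** `q_max > 1 + 1e-9` counts as an overshoot;
  sink-adjacent trajectories can exceed stationarity by O(1e-5) sliver
  transients that are genuine but uninformative.

# Small-system behaviour of the strong-response threshold

On a three-node chain `A -> B -> C` (C a pure sink) with the input on `A`,
the middle node overshoots: its closed-form peak ratio is
`q_max,B = 1.1587` at `tau = 0.85` (and at most about 1.10 as
`tau -> 1`). A scan over all three-node chain weightings, including back
edges, shows 1.1587 is the maximum attainable: with only three nodes,
teleportation and sink redistribution give the middle node stationary mass
`pi_B ~ 0.34`, and no transient can reach 5/3 of it. The strong-response
cutoff `q_max > 5/3` is therefore meaningful at connectome scale (where
stationary masses are of order 1e-2 to 1e-3) but cannot be exercised on
three nodes; the test suite asserts the overshoot and the closed-form value
on the chain, and exercises the 5/3 cutoff on the 60-node feed-forward
fixture, where a six-node upstream input typically yields about 20 strong
responders whose peak times order upstream < middle < downstream.

# Problem sizes

The default test and acceptance conditions are: recovery and screening
fixtures at n = 40-60 with 50 Markov times and 20-member ensembles over 20
seeds each; exhaustive-enumeration cross-checks at n <= 8; the full-scale
generator (n = 279) for descriptor statistics and the pair enumerator. The
complete synthetic suite runs in a few minutes on one CPU. The "paper mode"
settings (200 times, ell = 100) and the full 38781-pair double screen are
supported by the same functions with checkpointing and deterministic
per-task seeds, and scale linearly in pairs.

# Known limitations

- Diffusion is a linear proxy: no synaptic signs, thresholds, or spiking;
  conclusions concern flow structure, not physiology.
- The RMST formulation here (max-link relaxation with a k-th-neighbour
  density term) is one member of the relaxed-spanning-tree family and is
  the module's main approximation; `k` and `gamma` are exposed.
- The quantile scorer is a generic conditional-quantile method; a Bayesian
  joint-quantile fit would pool information across levels and may rank
  near-ties differently.
- Plateau/dip selection depends on grid density: plateaux shorter than two
  grid points are invisible by construction.
- The generator plants block-wise structure only; tests on it cannot speak
  to degree heterogeneity or spatial wiring effects in real data.
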