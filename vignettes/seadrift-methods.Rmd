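---
title: "Methods: larval dispersal networks and coalescent species delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: larval dispersal networks and coalescent species delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seadrift)
```

seadrift models how passive pelagic larvae connect the islands of an
archipelago, and whether the resulting lineages have split into distinct
species. It chains four stages — synthetic seascape generation, Lagrangian
particle tracking, connectivity network analysis, and single-threshold GMYC
species delimitation — each usable on its own. This vignette explains the
models, the defaults, and the choices made where the underlying methods
leave room.

## Synthetic seascapes

Real dispersal studies drive their particle simulations with assimilated
ocean-model currents (e.g. daily HYCOM fields) over a digitized coastline.
Those inputs are external data; `make_archipelago()` and
`make_current_field()` generate stand-ins with the statistical structure the
downstream analysis relies on, so that every stage can be exercised and
tested without downloads.

**Coastlines.** Islands are placed as non-overlapping discs on a regular
lon/lat grid (default coastal resolution in the examples, 0.02–0.05
degrees, is coarser than a real 0.005-degree coastal product purely to keep
examples fast; the code is resolution-agnostic). Coastal cells are the ocean
cells 8-adjacent to land, so each island presents a closed shoreline
reachable from every direction. Each coastal cell carries a substrate label
(`rock`, `sand`, `both`) drawn from a configurable mix;
`substrate_summary()` tallies counts, shoreline kilometres (defaulting to
the great-circle length of one cell side at the island's mean latitude) and
percentages per island.

**Currents.** Velocities derive from a streamfunction: a sum of Gaussian
gyre bumps plus a linear term for a mean background flow, on a plane whose
metric is fixed at the grid mid-latitude. Sampling the streamfunction at
cell centers and taking its *discrete* central-difference curl makes the
discrete divergence vanish identically at interior cells, because central
difference operators commute; this is what the divergence test asserts at
1e-10. The discrete curl differs from the analytic curl by O(h^2), which is
immaterial at the tested resolutions. Near a gyre core the azimuthal speed
grows linearly with radius (solid-body-like rotation), so circles around the
center are analytic streamlines — the oracle used to bound the integrator's
error. Optional Gaussian noise (seeded) makes the field time-varying;
with noise off the field is steady and exactly non-divergent.

What the generator does **not** emulate: bathymetry, tides, wind stress,
mesoscale eddy life cycles, and the seasonal cycle of real boundary
currents. Passing tests therefore demonstrate the correctness of the
machinery (integration, landing bookkeeping, aggregation), not oceanographic
realism of any particular run.

## Lagrangian particle tracking

Particles are released from the centroids of coastal cells with rocky
substrate (`rock` or `both`), every 12 hours through an August–December
spawning season by default (`schedule_releases()`; simulation time 0 is
Jan 1 of year 1, years are 365 days, so the default season spans 153 days
and 10 cells over one season give 3060 releases). `season = NULL` releases
around the whole year for short synthetic records.

`advect()` integrates the drift with fourth-order Runge-Kutta (default step
1 h), bilinear spatial and linear temporal interpolation of the gridded
velocities, converting m/s to degrees/h with the local metric (longitude
scaled by cos latitude). The integrator was chosen for its cheap, easily
bounded error: against the analytic oracles a 4-day constant-flow
trajectory matches the closed form to well below 0.1% and gyre streamline
radii are conserved to better than 0.5%.

**Landing rule.** A particle lands on its first *entry* into a coastal cell
other than the one it currently occupies, or into any land cell (landing
into land is attributed to the nearest coastal cell). Entry semantics
matter: releases start inside a coastal cell, so a naive "in a coastal cell
= landed" rule would terminate every particle at its origin. Self-recruitment
(leaving and re-entering the natal cell or island) is recorded; summaries of
effective dispersal exclude same-cell landings. A release cell walled in by
land lands at the first step via the land-cell branch. Particles drifting
beyond the current-field domain expire with an `out_of_domain` flag rather
than raising an error, and every particle expires at its maximum pelagic
larval duration (PLD; the study defaults are 4 and 30 days, spanning
short-lived lecithotrophic larvae and multi-week planktotrophic ones).

## Connectivity matrices

`cell_connectivity()` is a pure tally: landed particles over released
particles for each ordered cell pair. `island_connectivity()` aggregates to
a directed island matrix whose entry (I, J) is the arithmetic mean, over
source cells of island I, of each cell's total probability of landing
anywhere on island J — a *mean* connectivity matrix. Pooling by release
counts instead of averaging is available behind `method = "pooled"`; the
mean is the default because it weights each shore segment equally regardless
of how many cells represent it. Row sums of the cell matrix cannot exceed 1
(a particle lands at most once), an invariant the tests check.

Matrices are stored as delimited text with island labels on the first row
and column, rows = source, and an em dash on the diagonal. The package ships
two such fixtures for the Cape Verde keyhole-limpet system,
`table2_4day.csv` and `table3_30day.csv` (one obvious typographic slip in
the 4-day source table, a comma decimal separator in one cell, is corrected
to its unambiguous value). The writer defaults to full double precision so
round-trips are exact; `format = "paper"` reproduces the `%.2E`
presentation.

## Network analysis: percolation pruning and leading-eigenvector clustering

The directed island matrix is symmetrized (arithmetic mean of the two
directions by default; `max` and `min` are exposed because the
directed-to-undirected step is a modelling choice with no single
convention), then pruned at the **percolation threshold**: the largest
weight tau such that keeping only edges with weight >= tau leaves the
network connected. This retains only the strongest links while keeping one
network rather than fragments; the variant that prunes just past the
threshold is available (`prune_rule = "past"`).

Community detection is Newman's leading-eigenvector method on the weighted
modularity matrix `B = A - k k' / 2m`: recursive bisection by the sign
pattern of the leading eigenvector, with each split fine-tuned by
Kernighan–Lin style single-vertex sweeps and a final partition-level
refinement (single-vertex moves and community merges). The fine-tuning
stage is part of the method as originally published and is retained because
plain sign-splitting demonstrably misses optima even on toy graphs. Zero
eigenvector components join the positive side, for determinism. Modularity
is reported for the partition on the *pruned weighted* graph; whether to
evaluate Q on the pruned, full, or binarized graph is genuinely
open in this kind of analysis, so all three graphs can be built explicitly
and the partition records which variant produced it.

On graphs small enough for exhaustive search, the implementation is tested
against the true maximum-modularity partition over all set partitions. Two
caveats are documented deliberately: (i) modularity maximization is NP-hard
and the spectral heuristic can miss the optimum on dense graphs *without*
community structure (measured at roughly 4–17% of structureless
Erdős–Rényi weight matrices); the randomized agreement suite therefore uses
planted-block graphs with noise — the regime the pipeline actually operates
in, and where agreement was 100/100 across independent seeds; (ii) on the
packaged Cape Verde matrices the pipeline's partition *is* the global
optimum of its graph (verified exhaustively over all 21,147 partitions of
the 9 islands), and it groups the islands into three clusters at Q = 0.42
(4-day) and 0.48 (30-day). The published figure captions for this system
report Q = 0.38 with three clusters and Q = 0.34 with two; no partition of
the island-level matrices under any exposed symmetrization/pruning variant
attains those values, so the original analysis evidently operated on
cell-level data that the printed island tables do not contain. The package
reports what the printed data yield.

**Significance.** The permutation test shuffles edge weights among the
existing edges (topology fixed), re-runs the clustering, and reports the
add-one p-value `(1 + #(Q* >= Q_obs)) / (B + 1)` under a fixed seed
(default B = 10000). A null that also randomizes topology would conflate
weight structure with degree structure; fixing the topology isolates the
question "are the strong links placed non-randomly?".

## GMYC species delimitation

The single-threshold general mixed Yule-coalescent model assumes an
ultrametric tree whose branching events switch character at a threshold
time: older nodes are diversification (between-species) events, younger
nodes are within-species coalescences. Both processes contribute
waiting-time rates of the generalized form `b = lambda * n^p`: for the
diversification class `n` is the number of species-level lineages; for the
coalescent class the polynomial argument is `sum_j n_j (n_j - 1)` over the
clusters crossing the interval. The scaling exponents `p` let each class
deviate from its pure form (p = 1 Yule, p = 1 coalescent scaling) and
absorb, e.g., density-dependent slowdowns.

Implementation choices:

* **Intervals.** Waiting times are the internode gaps between successive
  branching events, root to tips (n - 2 of them for n tips). Each interval's
  density factor uses the rate of the class of the event at its *older*
  end — the backward-time convention natural for the coalescent, under
  which the event closing a cluster interval always sees the cluster with
  at least two lineages (the forward convention would assign a first
  within-cluster split a zero rate). Tied or zero gaps are perturbed to a
  strict decrease of 1e-9 times the tree height.
* **Candidates.** Thresholds are enumerated as "the k oldest nodes
  diversify", k = 1..n-1, equivalent to cutting between consecutive node
  heights. k = n-1 makes every event diversification and reduces the
  likelihood *exactly* to the single-process null, so the fitted
  log-likelihood can never fall below the null's — the nesting the
  likelihood-ratio test relies on.
* **Optimization.** For fixed exponents the two rate constants have
  closed-form profile maxima (`lambda_hat = events / exposure`), so only
  (p_div, p_coal) are optimized, by multi-start L-BFGS-B inside (-5, 5)
  with lambdas clamped to (1e-10, 1e6). Profiling the lambdas reaches the
  same optimum as a 4-parameter quasi-Newton search but is faster and
  removes the worst ridges from the objective.
* **Entities.** The winning threshold's k + 1 crossing lineages are the
  delimited entities: multi-tip clusters plus singletons.
* **LRT.** `D = 2 (lnL_GMYC - lnL_null)` against chi-square with df = 3 by
  default (threshold + extra rate + extra exponent); df = 2 is exposed
  because published implementations disagree, and every result records the
  df used. On simulated single-population coalescent trees the empirical
  type-I error at alpha = 0.05 sits near 0.07 with df = 3 — acceptably
  close to nominal for a statistic whose regularity conditions (a
  boundary/changepoint parameter) are not classical.

`simulate_gmyc_tree()` provides the ground truth for recovery testing: a
Yule backbone grown with per-lineage rate lambda (the waiting time while k
lineages exist is Exp(lambda k), stopping after the k = n draw, so the
expected root height is `sum_{k=2..n} 1/(lambda k)` — the closed form the
simulator test uses), with standard coalescent subtrees grafted at the tips
and rescaled so the deepest within-species node sits a configurable factor
(default 20) below the shallowest species split. With that separation the
fitter recovers 8 planted species with correct membership in all 50 seeded
replicates used by the acceptance suite. Simulated trees are deliberately
idealized: no gene-tree discordance, no sampling imbalance beyond the
configured tips per species, no rate variation — so recovery results bound
implementation correctness, not performance on hard empirical trees.

## Biogeographic statistics

`nested_lrt()` compares two nested models from their printed negative
log-likelihoods (for example a range-evolution model with and without a
founder-event jump parameter at speciation, df = 1 for the single added
parameter): `D = 2 (negLnL_null - negLnL_alt)`, chi-square upper tail
computed in full double precision. `richness_correlation()` is the Pearson
correlation between per-island species counts and a substrate availability
measure, with the two-sided t test on `t = r sqrt(df / (1 - r^2))`,
df = n - 2; two-sided is the default because directionality of a
richness-habitat association is not given a priori.

## Problem sizes and reproducibility

Every stochastic component takes an explicit integer seed and is
bit-reproducible; `run_pipeline()` writes a JSON manifest (full
configuration echo, seed, package version, wall time) sufficient to
reproduce a run. The test and acceptance workloads use deliberately modest
problem sizes — toy archipelagos of 2–9 islands on coarse grids, hundreds
of particles, 100-graph exhaustive suites at up to 8 nodes, 50 recovery and
200 calibration replicates for GMYC at 20–40 tips — sizes at which the
exhaustive oracles (brute-force tallies, full partition enumeration,
closed forms) are computable and the whole suite runs in minutes.

## Known limitations

* The seascape is an idealized f-plane with circular islands; shoreline
  geometry effects (bays, headlands, retention zones) are absent.
* Particles are strictly passive: no larval swimming, vertical migration,
  behaviour or mortality.
* Landing is resolved at the integration step (default 1 h); a particle
  could in principle cross a very thin coastal ring within a step at
  extreme speeds and coarse coastal grids.
* The leading-eigenvector heuristic is not an exact modularity maximizer on
  unstructured dense graphs (see above).
* GMYC assumes a single, global threshold time; incomplete lineage sorting
  at uneven depths (the multiple-threshold variant) is out of scope, as is
  tree inference itself — trees are inputs.
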