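---
title: "Distance-dependent consensus thresholding for group connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-dependent consensus thresholding for group connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupnet)
```

## The model

A cohort is a set of T weighted, symmetric, nonnegative N x N structural
connectivity matrices `A_s` on a common parcellation, together with node
metadata: centroid coordinates (mm), a hemisphere label (L/R) and optionally
a cognitive-system label. The consensus matrix `C_ij` is the fraction of
subjects expressing edge {i, j} (`A_ijs > 0`); every entry is a multiple of
1/T. Connection probability, weight, and therefore consensus all decay with
the Euclidean distance between region centroids. This is the central
empirical fact the package is organized around: any uniform consensus
threshold preferentially retains short edges, because short edges are the
consistent ones.

Four group-construction methods are implemented behind
`build_group_network()`:

* **simple** — retain every expressed edge with its mean weight over
  expressing subjects. Maximal density; strongly over-expresses weak,
  inconsistent edges.
* **tau_fixed** — retain `C_ij >= tau` (default 0.5) uniformly. Density is
  whatever the threshold happens to give; strongly short-range biased.
* **tau_avg** — per edge class, retain the most consistent edges until the
  class's retained count equals the class's mean subject-level edge count
  (`round(mean_s #edges_s)`). Density-matched but still short-range biased.
* **distance** — per edge class, pool all subjects' expressed edge lengths
  (an edge expressed by k subjects contributes k copies), cut the pooled
  multiset into M equiprobable length bins (M = the class's mean subject
  edge count), and in each bin, among the not-yet-selected expressed pairs
  whose length falls in the bin, keep the one with maximal consensus.

Edge classes default to the intra-/inter-hemispheric partition, mirroring
the anatomical distinction between callosal and within-hemisphere
connections; `single_class_partition()` disables the split.

After edge selection, the thresholding methods assign weights in two steps
(`assign_weights()`): each edge takes its simple-average weight, then edges
are ranked by that weight and re-assigned the `(r-1)/(M-1)` quantiles of the
pooled positive subject weights. Rank order is preserved, the retained
min/max equal the pooled min/max, and the two-sample KS statistic between
group and pooled weights is bounded by `1/M + 1/P`.

## Parameters that matter

| parameter | where | default | meaning |
|---|---|---|---|
| `tau` | `tau_fixed` | 0.5 | minimum fraction of subjects expressing a retained edge |
| edge classes | `tau_avg`, `distance` | hemisphere split | thresholds computed separately per class |
| `ties` | `tau_avg` | `"match"` | how the per-class target count is hit (below) |
| `gamma` | modularity | 1.0 (sweep 0.7–2.1 by 0.1) | resolution of the configuration-model null |
| `repetitions` | Louvain | 100 | seeded restarts; best-Q partition kept |
| `n_perm` | permutation tests | 1000 | null draws; p uses the add-one estimator |

## Numerical choices

* **Quantiles.** All quantile operations (bin boundaries, weight remapping)
  use sorted-value linear interpolation at fractional position `q * (n - 1)`,
  written as `a + frac * (b - a)` so that interpolating inside a run of
  equal values is bit-exact. Consequence: for a cohort of identical subjects
  the distance method returns exactly the subject's edge set and exactly its
  weight multiset, and when M equals the pooled count with distinct weights
  the remap is the identity.
* **Density matching.** With T subjects the consensus takes at most T
  distinct levels, so thresholding at a swept consensus value can only land
  on counts that jump by the (large) number of pairs tied at each level. The
  default `ties = "match"` policy retains all edges strictly above the
  boundary level and admits boundary-level edges by decreasing simple-average
  weight until the class target is hit exactly — realizing the
  density-matched method's defining property that its binary density equals
  the typical subject's. `ties = "sweep"` instead picks the swept value
  minimizing the count error (ties toward the denser network), which can
  miss the target by half a consensus-level jump.
* **Tie-breaking.** Within a length bin: greatest consensus, then greatest
  simple-average weight, then lexicographic node-pair order. All outputs are
  deterministic functions of inputs and seed.
* **Degenerate bins.** Bins are processed short to long; an edge is
  selectable once; a bin whose candidate set is empty is skipped and counted
  in provenance (`skipped_bins`), so the achieved density can fall below the
  target by exactly that number.
* **Zero-consensus pairs** are never retainable, at any threshold.
* **Disconnected graphs.** Characteristic path length is reported as `Inf`
  with the finite-pair mean attached as an attribute (and used in the global
  z-score battery); efficiency counts disconnected pairs as 0; the diameter
  is the largest finite distance.
* **Modularity.** `Q(gamma)` uses the degree-preserving null
  `P_ij = k_i k_j / 2m` including the diagonal term, under which a single
  community has Q = 0 and two disconnected equal cliques have Q = 0.5.
  `modularity_louvain()` runs igraph's multilevel heuristic under seeded
  random node orders and refines every run with greedy single-node moves
  until no move improves Q. The refinement matters: the aggregated passes
  alone can terminate in states that are not single-move optimal, and on
  exhaustive small-graph benchmarks best-of-100 refined runs recovers the
  global optimum on all 200 seeded graphs.
* **Betweenness** follows the ordered-pair normalization
  `1 / ((N-1)(N-2))`, so the center of a 3-path scores exactly 1.
* **Weighted paths** use the reciprocal weight-to-length transform
  `L_ij = 1 / W_ij`.

## The synthetic cohort generator

`generate_cohort()` draws node centroids uniformly in two hemisphere blocks
(default 60 x 100 x 80 mm, 25 mm apart) and connects pairs independently
per subject with probability `min(1, p0 exp(-d/delta))`, optionally boosted
by `(1 + beta)` within planted systems; expressed edges get weight
`exp(-d/lambda) * LogNormal(0, sd)`. Defaults (p0 = 0.9, delta = 35 mm,
lambda = 90 mm, sd = 1) give a mean subject density near 0.10–0.15 with
heavy-tailed weights spanning orders of magnitude — the regime where
consensus thresholding is actually applied. Because subjects are i.i.d.
draws from a common distance-decaying probability, the expected consensus
equals that probability, so the consensus–distance confound exists in the
data by construction and the short-range bias of uniform thresholds is
reproducible on demand.

What the generator does *not* emulate: tractography artifacts (gyral bias,
crossing-fiber dropout), spatially autocorrelated geometry, subject-level
geometry differences (available via `jitter_sd` but off by default), or
realistic cortical shape. Tests passing on these cohorts demonstrate the
algebraic and statistical properties of the methods, not their behavior on
any particular scanner or tractography pipeline.

## Evaluation battery

`compare_local_measures()` computes two-sample KS statistics between the
group network's nodal (or edge-length) distribution and each subject's;
`paired_ks_test()` contrasts two methods across subjects with a two-sided
paired Wilcoxon signed-rank test, Bonferroni corrected over measures (the
test family is small and the statistics are paired by subject, which a rank
test handles without distributional assumptions).
`zscore_global_measures()` centers each global statistic of the group
network on the subject-level distribution. `rsn_density_matrix()` and
`rsn_correlation()` aggregate connection density within/between
cognitive-system labels and correlate group against subject-average over
the upper triangle plus diagonal.

`within_between_permutation_test()` compares two group networks on the
difference of their within-system minus between-system mean densities; the
null independently permutes the node order of each network and re-aggregates
under the fixed labels. Two properties of this null deserve emphasis:

* It is **exactly calibrated only under a node-exchangeable generating
  process**. When the two networks share subjects or even just share
  distance-structured geometry, their label-pair density profiles are
  positively correlated, the shared component cancels in the observed
  difference, and the independently-permuted null is over-dispersed — the
  test is then conservative (p stochastically larger than uniform), which is
  the safe direction for claiming a difference. The calibration check in the
  test suite therefore uses spatially flat cohorts and independent subject
  draws for the two networks, where the nominal 5% level is the correct
  expectation; measured rejection rates at alpha = 0.05 fall at 0.046–0.06
  over 500 seeded runs.
* P-values use the add-one estimator `(1 + #{null >= obs}) / (1 + n_perm)`
  and are never exactly zero.

`hub_rank_comparison()` rank-transforms each hub measure within each network
(average ranks for ties), takes per-node rank differences, aggregates them
by system and z-scores the system means against a null that permutes the
node-to-system assignment. A spatial rotation null is not possible without
surface geometry, so label permutation is used and should be read as testing
"is this system's shift larger than a random set of nodes of the same
size?". The participation coefficient's partition is computed once, with a
shared seed substream for both networks, so comparing a network with itself
is exactly null. Node-level significance (`hub_node_significance()`)
permutes the rank-difference vector across nodes and controls FDR by
Benjamini–Hochberg.

## Problem sizes used in the test suite

The package's own checks run at sizes chosen to make every property visible
while staying desk-sized: cohorts of N = 200 nodes, T = 20 subjects for the
distribution-level benchmarks (20 seeded replicates), N = 60, T = 10 for
permutation calibration (500 runs at 200 permutations each), and exhaustive
oracles (all set partitions; Floyd–Warshall; walk-counting betweenness) on
200 random connected graphs with up to 8 nodes. At these sizes the full
suite runs in minutes on one CPU.

## Known limitations

* The method requires **sparse** subject matrices: on fully weighted inputs
  (probabilistic tractography, functional connectivity) every consensus
  entry is 1 and consensus thresholding degenerates; threshold subject
  matrices first, or use a different aggregation principle.
* Hemisphere labels must be L/R; midline or subcortical structures need a
  user-chosen convention before import.
* Weight-based (as opposed to consensus-based) thresholding of the simple
  average is deliberately out of scope.
* Euclidean centroid distance is a first-order proxy for curvilinear fiber
  length; they correlate strongly but are not identical.
* The permutation nulls permute node identity, not space: they do not
  respect spatial autocorrelation of real cortical maps.
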