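# groupnet

Group-representative structural brain networks via distance-dependent
consensus thresholding.

## The problem

Structural connectomes are usually studied as group-representative networks:
a single sparse network aggregated from a cohort of T subject-level weighted
connectivity matrices (streamline densities between N parcellated brain
regions). The standard recipe is *consensus thresholding* — build the
consensus matrix

    C_ij = (1/T) * #{ subjects s : A_ijs > 0 }

and retain the connections with `C_ij >= tau`. The trouble is that both
connection probability and connection consensus decay with inter-areal
Euclidean distance: short-range connections are reproduced in almost every
subject, long-range ones in few. A single threshold applied uniformly over
all node pairs therefore over-retains short connections and prunes the
long-distance connections that drive integrative network properties
(efficiency, short path length, inter-system connectivity). The resulting
group network is more clustered, more modular and less efficient than any
subject it claims to represent.

## The method

`groupnet` implements a distance-dependent consensus threshold alongside
three comparison methods:

| method      | rule |
|-------------|------|
| `simple`    | keep every edge expressed in at least one subject, weighted by its mean over expressing subjects |
| `tau_fixed` | keep edges with `C_ij >= tau` (default 0.5), one threshold for all pairs |
| `tau_avg`   | per edge class (intra-/inter-hemispheric), choose the consensus threshold whose retained edge count equals the class's mean subject-level edge count |
| `distance`  | per edge class, pool the subjects' edge lengths (with multiplicity), cut them into M equiprobable length bins where M is the class's mean subject edge count, and keep in each bin the candidate edge with the greatest consensus (ties: greatest mean weight, then pair order) |

Because the distance method fills every length percentile bin, the group
network reproduces the pooled subject edge-length distribution by
construction while still preferring the most consistently expressed edge at
every distance. After edge selection, the three thresholding methods assign
weights in two steps: each retained edge first takes its mean weight over
expressing subjects, then the M retained edges are re-assigned, in rank
order, the `(r-1)/(M-1)` quantiles of the pooled positive subject weights
(linear interpolation), so the group weight distribution matches the pooled
subject weight distribution.

The package also provides the standard comparison battery: nodal and global
graph statistics (degree, strength, clustering, betweenness with ordered-pair
normalization, efficiency, characteristic path length, diameter, modularity
`Q(gamma)` maximized by repeated seeded Louvain with node-move refinement,
participation coefficient, degree assortativity), two-sample KS comparisons
of group-vs-subject distributions, z-scored global measures,
within/between cognitive-system (RSN) density analysis with a
node-permutation null, and hub rank-redistribution analysis — plus a seeded
synthetic cohort generator whose connection probability and weight decay
exponentially with distance, reproducing the consensus–distance confound the
method addresses.

## Worked example

```r
library(groupnet)

cohort <- generate_cohort(reference_config("small"), seed = 7)
cohort
#> gn_cohort: 10 subjects, 60 nodes; mean subject density 0.1385

d <- euclidean_distances(cohort$nodes)
pooled <- unlist(lapply(cohort$matrices, edge_lengths, dist = d))

for (m in c("simple", "tau_fixed", "tau_avg", "distance")) {
  g <- build_group_network(m, cohort, dist = d)
  cat(sprintf("%-9s  edges %4d   mean length %5.1f mm   KS vs pooled %.3f\n",
              m, nrow(g$edges), mean(edge_lengths(g, d)),
              ks_statistic(edge_lengths(g, d), pooled)))
}
#> simple     edges 1074   mean length  64.0 mm   KS vs pooled 0.195
#> tau_fixed  edges  109   mean length  26.5 mm   KS vs pooled 0.498
#> tau_avg    edges  245   mean length  39.9 mm   KS vs pooled 0.208
#> distance   edges  245   mean length  51.4 mm   KS vs pooled 0.006
```

The pooled subject edge length averages 51.3 mm. The two density-matched
methods retain the same number of edges (245, the mean subject edge count),
but the uniform threshold's edges average 39.9 mm — a 22% short-range bias —
while the distance method's average 51.4 mm and its edge-length KS statistic
against the pooled subject distribution is 0.006 versus 0.208. Global
statistics of the distance-method network sit near the center of the
subject-level distribution:

```r
g <- build_group_network("distance", cohort, dist = d)
z <- zscore_global_measures(g, cohort, reps = 20, seed = 1)
#>        measure   group subject_mean       z
#>        n_edges 245.000      245.200 -0.0129
#> clustering_bin   0.194        0.194 -0.0519
#> efficiency_bin   0.225        0.229 -0.0979
#> modularity_bin   0.357        0.341  0.7056
```

## Command line

The same pipeline is scriptable through the installed `groupnet` executable
(or `Rscript -e 'groupnet::gn_main(...)'`):

```sh
groupnet simulate --preset small --seed 1 --out-dir cohort/
groupnet build --method distance --matrices cohort/ --nodes cohort/nodes.tsv \
               --out group.tsv --seed 1
groupnet measures --net group.tsv --nodes cohort/nodes.tsv --seed 1 \
               --out measures.json
groupnet evaluate --group group.tsv --matrices cohort/ \
               --nodes cohort/nodes.tsv --seed 1 --out report.json
```

Inputs are plain text: one N x N delimited matrix per subject and a node
table TSV (`name, x, y, z, hemisphere[, system]`, coordinates in mm). Every
run writes a provenance JSON (options, seed, package version) next to its
outputs, and identical seeds give byte-identical outputs.

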