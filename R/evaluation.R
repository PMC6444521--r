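# Group-vs-subject comparison battery: two-sample KS statistics of nodal
# distributions, z-scored global measures, within/between cognitive-system
# density analysis with permutation nulls, and hub rank-redistribution.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The maximum absolute difference between the empirical cumulative
#' distribution functions of the two samples; handles ties exactly.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return scalar in `[0, 1]`.
#' @export
ks_statistic <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    gn_stop("ks_statistic: both samples must be nonempty")
  sa <- sort(sample_a)
  sb <- sort(sample_b)
  grid <- sort(unique(c(sa, sb)))
  fa <- findInterval(grid, sa) / length(sa)
  fb <- findInterval(grid, sb) / length(sb)
  max(abs(fa - fb))
}

local_measure_values <- function(net, measure, dist = NULL,
                                 weighted = FALSE) {
  switch(measure,
    degree = degree_strength(net, weighted = FALSE),
    strength = degree_strength(net, weighted = TRUE),
    clustering = clustering(net, weighted = weighted),
    betweenness = betweenness_centrality(net, weighted = weighted),
    edge_length = {
      if (is.null(dist)) gn_stop("edge_length measure needs `dist`")
      edge_lengths(net, dist)
    },
    gn_stop("unknown local measure '%s'", measure))
}

#' KS comparison of local measures: group network vs each subject
#'
#' For each measure and each subject, computes the two-sample KS statistic
#' between the group network's nodal distribution (edge-length distribution
#' for `edge_length`) and the subject's.
#'
#' @param group a `gn_group`.
#' @param cohort the `gn_cohort`.
#' @param measures subset of degree, strength, clustering, betweenness,
#'   edge_length.
#' @param dist Euclidean distance matrix (needed for `edge_length`).
#' @param weighted compute clustering/betweenness on weights.
#' @return data frame with columns `measure`, `subject`, `ks`.
#' @export
compare_local_measures <- function(group, cohort,
                                   measures = c("degree", "strength",
                                                "clustering", "betweenness",
                                                "edge_length"),
                                   dist = NULL, weighted = FALSE) {
  measures <- match.arg(measures, several.ok = TRUE)
  if ("edge_length" %in% measures && is.null(dist))
    dist <- euclidean_distances(cohort$nodes)
  out <- list()
  for (m in measures) {
    gv <- local_measure_values(group, m, dist = dist, weighted = weighted)
    ks <- vapply(cohort$matrices, function(a) {
      sv <- local_measure_values(a, m, dist = dist, weighted = weighted)
      if (!length(sv) || !length(gv)) return(NA_real_)
      ks_statistic(gv, sv)
    }, 0)
    out[[m]] <- data.frame(measure = m, subject = cohort$subject_ids,
                           ks = unname(ks), row.names = NULL)
  }
  do.call(rbind, out) -> res
  rownames(res) <- NULL
  res
}

#' Paired comparison of per-subject KS statistics between two methods
#'
#' For each measure, a two-sided paired Wilcoxon signed-rank test across
#' subjects on the KS statistics of method A vs method B, Bonferroni
#' corrected over measures. A single-subject cohort yields no test
#' (p = NA, flagged).
#'
#' @param ks_a,ks_b data frames from [compare_local_measures()] for the two
#'   methods (same cohort, same measures).
#' @return data frame with columns `measure`, `mean_ks_a`, `mean_ks_b`,
#'   `p_value`, `p_bonferroni`.
#' @export
paired_ks_test <- function(ks_a, ks_b) {
  stopifnot(identical(ks_a$measure, ks_b$measure),
            identical(ks_a$subject, ks_b$subject))
  measures <- unique(ks_a$measure)
  res <- lapply(measures, function(m) {
    a <- ks_a$ks[ks_a$measure == m]
    b <- ks_b$ks[ks_b$measure == m]
    p <- if (length(a) < 2 || all(a == b)) NA_real_ else
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                          exact = FALSE)$p.value)
    data.frame(measure = m, mean_ks_a = mean(a), mean_ks_b = mean(b),
               p_value = p)
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(1, res$p_value * length(measures))
  res
}

#' Z-scored global measures: group network against the subject distribution
#'
#' z = (x_group - mean_subjects) / sd_subjects for each global statistic in
#' [global_measures()]. A z-score near 0 means the group network sits at the
#' center of the subject-level distribution. Measures with zero subject
#' variance return NA (flagged by a warning).
#'
#' @param group a `gn_group`.
#' @param cohort a `gn_cohort` with T >= 2 subjects.
#' @param gamma,reps,seed passed to [global_measures()] for modularity.
#' @param modularity include the modularity entries (slowest).
#' @return data frame with columns `measure`, `group`, `subject_mean`,
#'   `subject_sd`, `z`.
#' @export
zscore_global_measures <- function(group, cohort, gamma = 1, reps = 20,
                                   seed = 1, modularity = TRUE) {
  if (length(cohort$matrices) < 2)
    gn_stop("z-scoring requires at least two subjects")
  gm <- global_measures(group, gamma = gamma, reps = reps, seed = seed,
                        modularity = modularity)
  sm <- vapply(seq_along(cohort$matrices), function(s) {
    suppressWarnings(
      global_measures(cohort$matrices[[s]], gamma = gamma, reps = reps,
                      seed = substream_seed(seed, paste0("subject", s)),
                      modularity = modularity))
  }, numeric(length(gm)))
  mu <- rowMeans(sm)
  sdv <- apply(sm, 1, stats::sd)
  if (any(sdv == 0, na.rm = TRUE))
    gn_warn("zero subject variance for: %s",
            paste(names(gm)[which(sdv == 0)], collapse = ", "))
  z <- ifelse(sdv > 0, (gm - mu) / sdv, NA_real_)
  data.frame(measure = names(gm), group = unname(gm), subject_mean = mu,
             subject_sd = sdv, z = unname(z), row.names = NULL)
}

# Per-system-pair possible pair counts given a label vector.
system_pair_counts <- function(labels) {
  systems <- sort(unique(labels))
  ns <- table(factor(labels, systems))
  s <- length(systems)
  possible <- outer(as.numeric(ns), as.numeric(ns))
  diag(possible) <- as.numeric(ns) * (as.numeric(ns) - 1) / 2
  dimnames(possible) <- list(systems, systems)
  possible
}

# Edge counts aggregated by system pair; edges as a 2-col pair matrix.
system_edge_counts <- function(edges, labels) {
  systems <- sort(unique(labels))
  s <- length(systems)
  la <- match(labels[edges[, 1L]], systems)
  lb <- match(labels[edges[, 2L]], systems)
  lo <- pmin(la, lb); hi <- pmax(la, lb)
  counts <- matrix(0, s, s, dimnames = list(systems, systems))
  tab <- table(factor(lo + (hi - 1L) * s, levels = seq_len(s * s)))
  counts[] <- as.numeric(tab)
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  counts
}

#' Inter-system (RSN) connection density matrix
#'
#' Entry (a, b) is the number of edges joining systems a and b divided by
#' the number of possible such pairs; diagonal entries use n_a (n_a - 1) / 2
#' possible pairs. `weighted = TRUE` averages weights instead of counting.
#'
#' @param net a `gn_group` or symmetric matrix.
#' @param nodes a `gn_nodes` table with a `system` column.
#' @param weighted mean connection weight instead of binary density.
#' @return symmetric S x S matrix; diagonal entries of systems with < 2
#'   nodes are NA (flagged).
#' @export
rsn_density_matrix <- function(net, nodes, weighted = FALSE) {
  if (is.null(nodes$system)) gn_stop("node table has no `system` column")
  labels <- nodes$system
  w <- as_weight_matrix(net)
  pairs <- upper_pairs(nrow(w))
  wv <- pair_values(w, pairs)
  possible <- system_pair_counts(labels)
  if (weighted) {
    e <- pairs
    systems <- rownames(possible)
    la <- match(labels[e[, 1L]], systems); lb <- match(labels[e[, 2L]], systems)
    lo <- pmin(la, lb); hi <- pmax(la, lb)
    s <- length(systems)
    idx <- lo + (hi - 1L) * s
    sums <- matrix(0, s, s, dimnames = dimnames(possible))
    sums[] <- as.numeric(tapply(wv, factor(idx, seq_len(s * s)), sum,
                                default = 0))
    sums[lower.tri(sums)] <- t(sums)[lower.tri(sums)]
    dens <- sums / possible
  } else {
    edges <- pairs[wv > 0, , drop = FALSE]
    dens <- system_edge_counts(edges, labels) / possible
  }
  dens[possible == 0] <- NA_real_
  dens
}

#' Average of subject-level system density matrices
#'
#' @param cohort a `gn_cohort` whose nodes carry system labels.
#' @param weighted as in [rsn_density_matrix()].
#' @return S x S matrix, the elementwise mean over subjects.
#' @export
subject_average_rsn_density <- function(cohort, weighted = FALSE) {
  mats <- lapply(cohort$matrices, rsn_density_matrix, nodes = cohort$nodes,
                 weighted = weighted)
  Reduce(`+`, mats) / length(mats)
}

#' Pearson correlation of two system-density matrices
#'
#' Computed over the S(S+1)/2 upper-triangle-plus-diagonal entries.
#'
#' @param group_density,subject_avg_density S x S matrices.
#' @return scalar Pearson r (NA with a warning if either side is constant).
#' @export
rsn_correlation <- function(group_density, subject_avg_density) {
  stopifnot(identical(dim(group_density), dim(subject_avg_density)))
  keep <- upper.tri(group_density, diag = TRUE)
  a <- group_density[keep]; b <- subject_avg_density[keep]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    gn_warn("rsn_correlation undefined: zero variance")
    return(NA_real_)
  }
  stats::cor(a, b)
}

# Mean within-system minus mean between-system density from an edge list and
# a label vector (binary densities; NA-safe for singleton systems).
within_between_stat <- function(edges, labels, possible) {
  dens <- system_edge_counts(edges, labels) / possible
  dens[possible == 0] <- NA_real_
  within <- mean(diag(dens), na.rm = TRUE)
  between <- mean(dens[upper.tri(dens)], na.rm = TRUE)
  c(within = within, between = between)
}

#' Permutation test of within/between-system density differences
#'
#' Observed statistic: (mean within-system density of net_a - net_b) minus
#' (mean between-system density of net_a - net_b). The null permutes the
#' node order of each network independently (equivalently, relabels nodes),
#' re-aggregates with the fixed system labels, and recomputes the statistic.
#' P-values use the add-one estimator, so they are never exactly zero.
#'
#' @param net_a,net_b `gn_group` objects or symmetric matrices on the same
#'   node set.
#' @param nodes a `gn_nodes` table with system labels.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed (substream "permutation").
#' @param alternative `"greater"` (observed >= null) or `"two_sided"`.
#' @return list with `observed`, `null` (length n_perm), `p`,
#'   `within_a`, `within_b`, `between_a`, `between_b`.
#' @export
within_between_permutation_test <- function(net_a, net_b, nodes,
                                            n_perm = 1000, seed = 1,
                                            alternative = c("greater",
                                                            "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 100)
  if (is.null(nodes$system)) gn_stop("node table has no `system` column")
  labels <- nodes$system
  n <- nrow(nodes)
  ea <- if (inherits(net_a, "gn_group")) net_a$edges else
    new_group_network(net_a, "tmp")$edges
  eb <- if (inherits(net_b, "gn_group")) net_b$edges else
    new_group_network(net_b, "tmp")$edges
  possible <- system_pair_counts(labels)
  stat <- function(pa, pb) {
    wa <- within_between_stat(cbind(pa[ea[, 1L]], pa[ea[, 2L]]), labels,
                              possible)
    wb <- within_between_stat(cbind(pb[eb[, 1L]], pb[eb[, 2L]]), labels,
                              possible)
    (wa["within"] - wb["within"]) - (wa["between"] - wb["between"])
  }
  id <- seq_len(n)
  obs_parts_a <- within_between_stat(ea, labels, possible)
  obs_parts_b <- within_between_stat(eb, labels, possible)
  observed <- unname(stat(id, id))
  null <- with_seed(substream_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(r) {
      unname(stat(sample.int(n), sample.int(n)))
    }, 0)
  })
  p <- if (alternative == "greater") {
    (1 + sum(null >= observed)) / (1 + n_perm)
  } else {
    (1 + sum(abs(null) >= abs(observed))) / (1 + n_perm)
  }
  list(observed = observed, null = null, p = p,
       within_a = unname(obs_parts_a["within"]),
       within_b = unname(obs_parts_b["within"]),
       between_a = unname(obs_parts_a["between"]),
       between_b = unname(obs_parts_b["between"]),
       n_perm = n_perm, seed = seed, alternative = alternative)
}

hub_measure_values <- function(net, measure, weighted = FALSE,
                               partition = NULL, louvain_seed = 1,
                               louvain_reps = 20) {
  switch(measure,
    degree = degree_strength(net, weighted = weighted),
    betweenness = betweenness_centrality(net, weighted = weighted),
    clustering = clustering(net, weighted = weighted),
    participation = {
      if (is.null(partition))
        partition <- modularity_louvain(
          if (weighted) as_weight_matrix(net)
          else (as_weight_matrix(net) > 0) + 0,
          gamma = 1, seed = louvain_seed, repetitions = louvain_reps)
      participation(net, partition, weighted = weighted)
    },
    gn_stop("unknown hub measure '%s'", measure))
}

#' Hub rank-redistribution between two group networks
#'
#' Each measure is rank-transformed within each network (average ranks for
#' ties); the per-node difference rank_a - rank_b shows where hubs move when
#' switching construction method. Per-system mean differences are z-scored
#' against a null that permutes the node-to-system assignment. When the null
#' is degenerate (all permuted means equal the observed, e.g. comparing a
#' network to itself) the z is 0.
#'
#' @param net_a,net_b `gn_group` objects or symmetric matrices.
#' @param nodes a `gn_nodes` table with system labels.
#' @param measures subset of betweenness, degree, clustering, participation.
#' @param n_perm label permutations for the system null.
#' @param seed integer seed.
#' @param weighted compute measures on weights.
#' @param louvain_reps Louvain restarts for the participation partition.
#' @return list with `rank_diff` (N x length(measures) matrix),
#'   `system_z` (S x length(measures) matrix), `system_mean` (observed
#'   per-system means).
#' @export
hub_rank_comparison <- function(net_a, net_b, nodes,
                                measures = c("betweenness", "degree",
                                             "clustering", "participation"),
                                n_perm = 1000, seed = 1, weighted = FALSE,
                                louvain_reps = 20) {
  measures <- match.arg(measures, several.ok = TRUE)
  if (is.null(nodes$system)) gn_stop("node table has no `system` column")
  labels <- nodes$system
  systems <- sort(unique(labels))
  n <- nrow(nodes)
  rank_diff <- vapply(measures, function(m) {
    # the same Louvain substream is used for both networks so that comparing
    # a network with itself is exactly null
    va <- hub_measure_values(net_a, m, weighted = weighted,
                             louvain_seed = substream_seed(seed, "hub_part"),
                             louvain_reps = louvain_reps)
    vb <- hub_measure_values(net_b, m, weighted = weighted,
                             louvain_seed = substream_seed(seed, "hub_part"),
                             louvain_reps = louvain_reps)
    rank(va) - rank(vb)
  }, numeric(n))
  rank_diff <- matrix(rank_diff, nrow = n,
                      dimnames = list(nodes$name, measures))
  sys_mean <- apply(rank_diff, 2, function(d)
    tapply(d, factor(labels, systems), mean))
  sys_mean <- matrix(sys_mean, nrow = length(systems),
                     dimnames = list(systems, measures))
  null_means <- with_seed(substream_seed(seed, "hub_null"), {
    lapply(seq_len(n_perm), function(r) {
      pl <- labels[sample.int(n)]
      apply(rank_diff, 2, function(d) tapply(d, factor(pl, systems), mean))
    })
  })
  null_arr <- array(unlist(null_means),
                    dim = c(length(systems), length(measures), n_perm))
  mu <- apply(null_arr, c(1, 2), mean)
  sdv <- apply(null_arr, c(1, 2), stats::sd)
  z <- ifelse(sdv > 0, (sys_mean - mu) / sdv,
              ifelse(sys_mean == mu, 0, NA_real_))
  dimnames(z) <- list(systems, measures)
  list(rank_diff = rank_diff, system_mean = sys_mean, system_z = z,
       n_perm = n_perm, seed = seed)
}

#' Node-level significance of rank differences
#'
#' For each node, a permutation p-value for its rank difference under random
#' reassignment of the rank-difference vector across nodes (two-sided,
#' add-one estimator), adjusted by Benjamini-Hochberg FDR.
#'
#' @param rank_diff numeric vector of per-node rank differences (one
#'   measure), e.g. a column of `hub_rank_comparison()$rank_diff`.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param fdr target false-discovery rate.
#' @return data frame with `diff`, `p`, `p_fdr`, `significant`.
#' @export
hub_node_significance <- function(rank_diff, n_perm = 1000, seed = 1,
                                  fdr = 0.05) {
  n <- length(rank_diff)
  null <- with_seed(substream_seed(seed, "hub_node"), {
    replicate(n_perm, sample(rank_diff))
  })
  p <- vapply(seq_len(n), function(i) {
    (1 + sum(abs(null[i, ]) >= abs(rank_diff[i]))) / (1 + n_perm)
  }, 0)
  p_fdr <- stats::p.adjust(p, "BH")
  data.frame(node = names(rank_diff) %||% seq_len(n),
             diff = unname(rank_diff), p = p, p_fdr = p_fdr,
             significant = p_fdr <= fdr, row.names = NULL)
}
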