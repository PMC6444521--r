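# Fixture builders shared across test files, plus a memoized battery of
# benchmark cohorts for the slower distribution-level checks.

toy_nodes <- function(x, y = 0, z = 0, hemisphere = NULL, system = NULL) {
  n <- length(x)
  df <- data.frame(name = paste0("n", seq_len(n)),
                   x = x, y = rep_len(y, n), z = rep_len(z, n),
                   hemisphere = hemisphere %||%
                     rep(c("L", "R"), length.out = n),
                   stringsAsFactors = FALSE)
  if (!is.null(system)) df$system <- system
  groupnet::as_node_table(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cohort from explicit per-subject edge lists. `edges` is a list (one entry
# per subject) of data.frames/matrices with columns i, j[, w] (default w = 1).
cohort_from_edges <- function(nodes, edges) {
  n <- nrow(nodes)
  mats <- lapply(edges, function(e) {
    e <- as.matrix(e)
    m <- matrix(0, n, n)
    w <- if (ncol(e) >= 3) e[, 3] else rep(1, nrow(e))
    m[e[, 1:2, drop = FALSE]] <- w
    m[e[, 2:1, drop = FALSE]] <- w
    m
  })
  groupnet::new_cohort(mats, nodes)
}

# A cohort of t identical copies of one synthetic subject (distinct edge
# lengths almost surely, since centroids are continuous).
identical_subject_cohort <- function(n = 60, t = 5, seed = 11) {
  cfg <- groupnet::synthetic_config(n_nodes = n, t_subjects = 1)
  one <- groupnet::generate_cohort(cfg, seed = seed)
  groupnet::new_cohort(rep(one$matrices, t), one$nodes)
}

# Memoized battery over seeded benchmark cohorts: summary statistics used by
# the density-match, edge-length-fidelity and weight-remap checks. Heavy
# objects are discarded; only scalars are kept.
.gn_battery_env <- new.env(parent = emptyenv())
benchmark_battery <- function(n_cohorts = 20) {
  key <- paste0("battery_", n_cohorts)
  if (!is.null(.gn_battery_env[[key]])) return(.gn_battery_env[[key]])
  cfg <- groupnet::reference_config("default")
  rows <- lapply(seq_len(n_cohorts), function(s) {
    co <- groupnet::generate_cohort(cfg, seed = 1000 + s)
    d <- groupnet::euclidean_distances(co$nodes)
    classes <- groupnet::hemisphere_partition(co$nodes)
    cls_pairs <- table(classes$class)
    g_simple <- groupnet::build_group_network("simple", co)
    g_avg <- groupnet::build_group_network("tau_avg", co, dist = d)
    g_dist <- groupnet::build_group_network("distance", co, dist = d)
    pooled_len <- groupnet:::pooled_edge_lengths(co, d)
    pooled_w <- groupnet:::pooled_subject_weights(co)
    targets <- groupnet:::class_targets(co, classes)
    ks_w <- function(g) {
      gw <- g$weights[g$edges]
      groupnet::ks_statistic(gw, pooled_w)
    }
    rank_ok <- function(g) {
      # remapped weights are nondecreasing along the simple-average rank order
      w1 <- groupnet::simple_average(co)$weights[g$edges]
      w2 <- g$weights[g$edges]
      ord <- order(w1, g$edges[, 1], g$edges[, 2])
      all(diff(w2[ord]) >= 0)
    }
    list(
      seed = 1000 + s,
      targets = targets,
      cls_pairs = cls_pairs,
      achieved_avg = unlist(g_avg$params$achieved),
      achieved_dist = unlist(g_dist$params$achieved),
      skipped_dist = unlist(g_dist$params$skipped_bins),
      edges_simple = nrow(g_simple$edges),
      edges_avg = nrow(g_avg$edges),
      edges_dist = nrow(g_dist$edges),
      ks_len_avg = groupnet::ks_statistic(
        groupnet::edge_lengths(g_avg, d), pooled_len),
      ks_len_dist = groupnet::ks_statistic(
        groupnet::edge_lengths(g_dist, d), pooled_len),
      mean_len_avg = mean(groupnet::edge_lengths(g_avg, d)),
      mean_len_dist = mean(groupnet::edge_lengths(g_dist, d)),
      mean_len_pooled = mean(pooled_len),
      ks_w_avg = ks_w(g_avg), ks_w_dist = ks_w(g_dist),
      ks_w_bound_avg = 1 / nrow(g_avg$edges) + 1 / length(pooled_w),
      ks_w_bound_dist = 1 / nrow(g_dist$edges) + 1 / length(pooled_w),
      rank_ok = rank_ok(g_avg) && rank_ok(g_dist))
  })
  .gn_battery_env[[key]] <- rows
  rows
}
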