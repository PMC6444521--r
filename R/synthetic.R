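# Seeded synthetic cohorts with the spatial statistics that drive consensus
# thresholding: connection probability and weight decay with Euclidean
# distance, so edge consensus across subjects itself decays with distance.

#' Synthetic cohort configuration
#'
#' Defines a cohort of `t_subjects` i.i.d. subjects on a shared geometry:
#' `n_nodes` centroids drawn uniformly in two hemisphere blocks of extent
#' `block_extent` (mm) separated by `hemisphere_gap` (mm) along x. The
#' population edge probability is
#' `pi_ij = min(1, p0 * exp(-d_ij / delta)) * (1 + beta * same_system)`
#' (truncated at 1), and each subject expresses each edge independently with
#' that probability. Expressed edges get weight
#' `w_ij = exp(-d_ij / lambda) * LogNormal(0, weight_sd)`: positive,
#' heavy-tailed, distance-decaying, loosely emulating streamline densities.
#'
#' @param n_nodes number of nodes (>= 4, split evenly across hemispheres).
#' @param t_subjects number of subjects (>= 1).
#' @param block_extent length-3 extent of each hemisphere block in mm.
#' @param hemisphere_gap gap between the two blocks along x, mm.
#' @param p0 base connection probability at distance 0.
#' @param delta distance-decay scale of connection probability, mm.
#' @param lambda distance-decay scale of connection weight, mm.
#' @param weight_sd sd of the lognormal weight noise (log scale).
#' @param n_systems number of planted cognitive systems (0 = none; labels
#'   are assigned round-robin).
#' @param beta within-system connection-probability boost (fractional).
#' @param jitter_sd per-subject centroid jitter sd in mm (0 = identical
#'   geometry for all subjects).
#' @return list of class `gn_config`.
#' @export
synthetic_config <- function(n_nodes = 200, t_subjects = 20,
                             block_extent = c(60, 100, 80),
                             hemisphere_gap = 25,
                             p0 = 0.9, delta = 35, lambda = 90,
                             weight_sd = 1.0, n_systems = 0, beta = 0,
                             jitter_sd = 0) {
  stopifnot(n_nodes >= 4, n_nodes %% 2 == 0, t_subjects >= 1,
            length(block_extent) == 3, all(block_extent > 0),
            hemisphere_gap >= 0, p0 > 0, p0 <= 1, delta > 0, lambda > 0,
            weight_sd >= 0, n_systems >= 0, beta >= 0, jitter_sd >= 0)
  structure(list(n_nodes = n_nodes, t_subjects = t_subjects,
                 block_extent = block_extent, hemisphere_gap = hemisphere_gap,
                 p0 = p0, delta = delta, lambda = lambda,
                 weight_sd = weight_sd, n_systems = n_systems, beta = beta,
                 jitter_sd = jitter_sd),
            class = "gn_config")
}

#' Named reference configurations
#'
#' * `small`: N = 60, T = 10 — unit-test scale.
#' * `default`: N = 200, T = 20 — the standard benchmarking cohort; mean
#'   subject density around 0.10.
#' * `modular`: `default` plus 7 planted systems with within-system boost
#'   beta = 0.5, loosely emulating 7 resting-state networks.
#'
#' @param name preset name.
#' @return a `gn_config`.
#' @export
reference_config <- function(name = c("small", "default", "modular")) {
  name <- match.arg(name)
  switch(name,
    small = synthetic_config(n_nodes = 60, t_subjects = 10, n_systems = 5),
    default = synthetic_config(n_nodes = 200, t_subjects = 20),
    modular = synthetic_config(n_nodes = 200, t_subjects = 20,
                               n_systems = 7, beta = 0.5))
}

#' Generate node metadata for a synthetic cohort
#'
#' Half the nodes are placed uniformly in the left block (negative x), half
#' mirrored on the right; system labels (if any) are assigned round-robin so
#' systems are spatially interleaved and hemispherically balanced.
#'
#' @param config a `gn_config`.
#' @param seed integer seed.
#' @return a `gn_nodes` table.
#' @export
generate_nodes <- function(config, seed = 1) {
  n <- config$n_nodes
  half <- n %/% 2
  ext <- config$block_extent
  gap <- config$hemisphere_gap
  with_seed(substream_seed(seed, "nodes"), {
    xs_l <- -(gap / 2 + stats::runif(half, 0, ext[1]))
    xs_r <- gap / 2 + stats::runif(half, 0, ext[1])
    ys <- stats::runif(n, -ext[2] / 2, ext[2] / 2)
    zs <- stats::runif(n, -ext[3] / 2, ext[3] / 2)
    df <- data.frame(
      name = sprintf("n%03d", seq_len(n)),
      x = c(xs_l, xs_r), y = ys, z = zs,
      hemisphere = rep(c("L", "R"), each = half),
      stringsAsFactors = FALSE)
    if (config$n_systems > 0)
      df$system <- sprintf("sys%02d",
                           rep_len(seq_len(config$n_systems), n))
    as_node_table(df, context = "synthetic nodes")
  })
}

#' Generate a synthetic subject cohort
#'
#' Subjects draw edges independently from a common population probability
#' `pi_ij` that decays exponentially with inter-node distance, so the
#' expected consensus equals `pi_ij` and decays with distance — the
#' statistical structure that makes uniform consensus thresholds
#' short-range-biased.
#'
#' @param config a `gn_config`.
#' @param seed integer seed (cohort is a deterministic function of
#'   config + seed).
#' @param nodes optional pre-generated `gn_nodes` (defaults to
#'   [generate_nodes()] with the same seed).
#' @return a `gn_cohort`.
#' @export
generate_cohort <- function(config, seed = 1, nodes = NULL) {
  if (is.null(nodes)) nodes <- generate_nodes(config, seed = seed)
  n <- nrow(nodes)
  d <- euclidean_distances(nodes)
  pairs <- upper_pairs(n)
  dv <- d[pairs]
  pi_v <- pmin(1, config$p0 * exp(-dv / config$delta))
  if (config$n_systems > 0 && config$beta > 0) {
    same <- nodes$system[pairs[, 1L]] == nodes$system[pairs[, 2L]]
    pi_v <- pmin(1, pi_v * (1 + config$beta * same))
  }
  mean_pi <- mean(pi_v)
  if (mean_pi <= 0 || mean_pi >= 1)
    gn_stop("degenerate configuration: expected density %.3f", mean_pi)
  w_scale <- exp(-dv / config$lambda)
  mats <- with_seed(substream_seed(seed, "cohort"), {
    lapply(seq_len(config$t_subjects), function(s) {
      dv_s <- dv
      if (config$jitter_sd > 0) {
        xyz <- as.matrix(nodes[, c("x", "y", "z")]) +
          matrix(stats::rnorm(3 * n, 0, config$jitter_sd), n, 3)
        ds <- as.matrix(stats::dist(xyz))
        dv_s <- ds[pairs]
      }
      expressed <- stats::runif(length(pi_v)) < pi_v
      noise <- if (config$weight_sd > 0)
        stats::rlnorm(length(pi_v), 0, config$weight_sd) else 1
      wv <- ifelse(expressed,
                   exp(-dv_s / config$lambda) * noise, 0)
      matrix_from_pairs(wv, pairs, n)
    })
  })
  new_cohort(mats, nodes,
             subject_ids = sprintf("sub%03d", seq_len(config$t_subjects)))
}

#' Write a synthetic cohort to disk in the package's text formats
#'
#' One TSV matrix per subject (`<id>.tsv`) plus `nodes.tsv`.
#'
#' @param cohort a `gn_cohort`.
#' @param dir output directory (created if needed).
#' @return character vector of matrix paths, invisibly; the node table is at
#'   `file.path(dir, "nodes.tsv")`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(unclass(cohort$nodes)),
                     file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- vapply(seq_along(cohort$matrices), function(s) {
    p <- file.path(dir, paste0(cohort$subject_ids[s], ".tsv"))
    write_group_network(cohort$matrices[[s]], p)
    p
  }, "")
  invisible(paths)
}
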