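# Graph statistics for binary and weighted undirected networks: degree,
# strength, clustering, shortest-path measures, betweenness, assortativity,
# edge lengths. Path computations are delegated to igraph; normalizations
# follow the conventions stated in the documentation of each function.

as_weight_matrix <- function(net) {
  w <- if (inherits(net, "gn_group")) net$weights else net
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  w
}

net_igraph <- function(w, weighted = FALSE) {
  igraph::graph_from_adjacency_matrix(
    w, mode = "undirected", diag = FALSE,
    weighted = if (weighted) TRUE else NULL)
}

#' Node degree and strength; total weight
#'
#' Degree counts a node's connections on the binarized matrix; strength sums
#' its connection weights. `total_weight()` returns 2m = sum of all degrees
#' (or strengths): twice the edge count (or total weight) because each
#' undirected edge is counted from both endpoints.
#'
#' @param net a `gn_group` or symmetric matrix.
#' @param weighted if TRUE use weights (strength), else binary degree.
#' @return numeric vector of length N (`degree_strength`) or a scalar
#'   (`total_weight`).
#' @export
degree_strength <- function(net, weighted = FALSE) {
  w <- as_weight_matrix(net)
  a <- if (weighted) w else (w > 0) + 0
  rowSums(a)
}

#' @rdname degree_strength
#' @export
total_weight <- function(net, weighted = FALSE) {
  sum(degree_strength(net, weighted = weighted))
}

#' Clustering coefficient
#'
#' Binary clustering of node i is `c_i = 2 t_i / (k_i (k_i - 1))`, with t_i
#' the number of triangles around i; nodes with degree < 2 get 0. The
#' weighted variant (`weighted = TRUE`) replaces the triangle count by the
#' sum of geometric means of the triangle's (max-normalized) weights, keeping
#' the binary-degree denominator.
#'
#' @param net a `gn_group` or symmetric matrix.
#' @param weighted use the geometric-mean weighted triangle form.
#' @return numeric vector of length N in `[0, 1]`.
#' @export
clustering <- function(net, weighted = FALSE) {
  w <- as_weight_matrix(net)
  b <- (w > 0) + 0
  k <- rowSums(b)
  t_i <- if (weighted) {
    wn <- (w / max(w, 1e-300))^(1 / 3)
    diag(wn %*% wn %*% wn) / 2
  } else {
    diag(b %*% b %*% b) / 2
  }
  cc <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  unname(cc)
}

#' @rdname clustering
#' @export
mean_clustering <- function(net, weighted = FALSE) {
  mean(clustering(net, weighted = weighted))
}

#' Shortest-path matrix
#'
#' Binary paths count hops; weighted paths first map each positive weight to
#' a length via the reciprocal transform `L_ij = 1 / W_ij`, so strong
#' connections are short. Disconnected pairs have infinite distance.
#'
#' @param net a `gn_group` or symmetric matrix.
#' @param weighted use the reciprocal weight-to-length transform.
#' @return symmetric N x N matrix of path lengths, zero diagonal, `Inf` for
#'   disconnected pairs.
#' @export
shortest_paths_matrix <- function(net, weighted = FALSE) {
  w <- as_weight_matrix(net)
  if (weighted) {
    g <- net_igraph(w, weighted = TRUE)
    ew <- igraph::E(g)$weight
    if (any(ew <= 0)) gn_stop("zero or negative weight under 1/W transform")
    d <- igraph::distances(g, weights = 1 / ew)
  } else {
    g <- net_igraph(w, weighted = FALSE)
    d <- igraph::distances(g)
  }
  unname(d)
}

#' Global path-based summaries
#'
#' `path_length()` is the mean shortest-path length over distinct pairs; if
#' any pair is disconnected it returns `Inf` and carries the mean over
#' finite pairs in attribute `"finite_mean"`. `diameter_length()` is the
#' largest finite distance. `efficiency()` is the mean inverse distance,
#' with disconnected pairs contributing 0.
#'
#' @param d a shortest-path matrix from [shortest_paths_matrix()].
#' @return scalar.
#' @export
path_length <- function(d) {
  v <- d[upper.tri(d)]
  out <- mean(v)
  if (!is.finite(out)) {
    fin <- v[is.finite(v)]
    out <- Inf
    attr(out, "finite_mean") <- if (length(fin)) mean(fin) else NA_real_
  }
  out
}

#' @rdname path_length
#' @export
diameter_length <- function(d) {
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  max(v)
}

#' @rdname path_length
#' @export
efficiency <- function(d) {
  v <- d[upper.tri(d)]
  mean(ifelse(is.finite(v), 1 / v, 0))
}

#' Betweenness centrality
#'
#' The fraction of all shortest paths between ordered pairs (h, j), h != i
#' != j, that pass through node i, normalized by (N-1)(N-2) so values lie in
#' `[0, 1]`.
#'
#' @param net a `gn_group` or symmetric matrix.
#' @param weighted use reciprocal-weight path lengths.
#' @return numeric vector of length N.
#' @export
betweenness_centrality <- function(net, weighted = FALSE) {
  w <- as_weight_matrix(net)
  n <- nrow(w)
  if (n < 3) return(rep(0, n))
  if (weighted) {
    g <- net_igraph(w, weighted = TRUE)
    b <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  } else {
    g <- net_igraph(w, weighted = FALSE)
    b <- igraph::betweenness(g)
  }
  # igraph counts each unordered pair once; the ordered-pair sum is twice that
  unname(2 * b / ((n - 1) * (n - 2)))
}

#' Degree assortativity
#'
#' Pearson correlation of the endpoint degrees over the network's edges,
#' computed from the edge list (each edge contributing its degree pair once,
#' symmetrized). Regular graphs have zero degree variance and return NaN
#' with a warning.
#'
#' @param net a `gn_group` or symmetric matrix.
#' @param weighted correlate endpoint strengths instead of degrees.
#' @return scalar in `[-1, 1]`, or NaN for degree-regular graphs.
#' @export
degree_assortativity <- function(net, weighted = FALSE) {
  w <- as_weight_matrix(net)
  pairs <- upper_pairs(nrow(w))
  e <- pairs[pair_values(w, pairs) > 0, , drop = FALSE]
  if (nrow(e) < 1L) gn_stop("assortativity needs at least one edge")
  k <- degree_strength(w, weighted = weighted)
  ji <- k[e[, 1L]]; ki <- k[e[, 2L]]
  num <- mean(ji * ki) - mean((ji + ki) / 2)^2
  den <- mean((ji^2 + ki^2) / 2) - mean((ji + ki) / 2)^2
  if (den == 0) {
    gn_warn("assortativity undefined: endpoint degrees have zero variance")
    return(NaN)
  }
  num / den
}

#' Edge-length multiset of a network
#'
#' @param net a `gn_group` or symmetric matrix.
#' @param dist Euclidean distance matrix aligned with the node order.
#' @return numeric vector of Euclidean lengths, one per retained edge.
#' @export
edge_lengths <- function(net, dist) {
  w <- as_weight_matrix(net)
  pairs <- upper_pairs(nrow(w))
  e <- pairs[pair_values(w, pairs) > 0, , drop = FALSE]
  dist[e]
}

#' Global measure battery
#'
#' Computes the scalar statistics used to compare group networks with
#' subjects: binary edge count, total weight, mean binary/weighted
#' clustering, binary/weighted efficiency, characteristic path length
#' (finite-pair mean), diameter, binary/weighted modularity (best-of-reps
#' Louvain at `gamma`), and degree assortativity.
#'
#' @param net a `gn_group` or symmetric matrix.
#' @param gamma modularity resolution parameter.
#' @param reps Louvain repetitions.
#' @param seed seed for the Louvain substream.
#' @param modularity include modularity (the slowest entry).
#' @return named numeric vector.
#' @export
global_measures <- function(net, gamma = 1, reps = 20, seed = 1,
                            modularity = TRUE) {
  w <- as_weight_matrix(net)
  db <- shortest_paths_matrix(w, weighted = FALSE)
  dw <- shortest_paths_matrix(w, weighted = TRUE)
  lb <- path_length(db); lw <- path_length(dw)
  out <- c(
    n_edges = sum(w[upper.tri(w)] > 0),
    total_weight = sum(w[upper.tri(w)]),
    clustering_bin = mean_clustering(w, weighted = FALSE),
    clustering_wei = mean_clustering(w, weighted = TRUE),
    efficiency_bin = efficiency(db),
    efficiency_wei = efficiency(dw),
    path_length_bin = if (is.finite(lb)) lb else attr(lb, "finite_mean"),
    path_length_wei = if (is.finite(lw)) lw else attr(lw, "finite_mean"),
    diameter_bin = diameter_length(db),
    diameter_wei = diameter_length(dw),
    assortativity_bin = suppressWarnings(
      degree_assortativity(w, weighted = FALSE))
  )
  if (modularity) {
    out["modularity_bin"] <- modularity_louvain(
      (w > 0) + 0, gamma = gamma, seed = seed, repetitions = reps)$q
    out["modularity_wei"] <- modularity_louvain(
      w, gamma = gamma, seed = seed, repetitions = reps)$q
  }
  out
}
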