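# Community detection: resolution-parameterized modularity, seeded
# best-of-repetitions Louvain, gamma sweep, and the participation
# coefficient.

#' Modularity of a partition
#'
#' Q(gamma) = 1/(2m) * sum over same-community ordered pairs (including
#' i = j in the null term) of `A_ij - gamma * k_i k_j / (2m)`, the
#' degree-preserving (configuration) null. With this convention the
#' single-community partition has Q = 0 at gamma = 1, and two disconnected
#' equal cliques partitioned into themselves give Q = 0.5.
#'
#' @param net a `gn_group` or symmetric (binary or weighted) matrix.
#' @param membership integer community assignment, length N.
#' @param gamma resolution parameter (> 0 scales the null's contribution).
#' @return scalar Q.
#' @export
modularity_value <- function(net, membership, gamma = 1) {
  w <- as_weight_matrix(net)
  k <- rowSums(w)
  two_m <- sum(k)
  if (two_m <= 0) gn_stop("modularity undefined: network has no edges")
  same <- outer(membership, membership, `==`)
  sum((w - gamma * outer(k, k) / two_m) * same) / two_m
}

# Greedy node-move refinement: repeatedly move single nodes (including into
# a fresh singleton community) while any move increases Q(gamma). Uses the
# standard O(1) modularity gain for a move, so a sweep is O(n^2). Guarantees
# the returned partition is locally optimal under single-node moves, which
# the aggregated Louvain passes alone do not.
refine_partition <- function(w, mem, gamma, tol = 1e-12) {
  n <- nrow(w)
  k <- rowSums(w)
  two_m <- sum(k)
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      ci <- mem[i]
      conn <- rowsum(w[, i], mem)           # weight from i into each community
      kc <- rowsum(k, mem)                  # total degree per community
      s_ci <- conn[as.character(ci), 1]
      k_ci <- kc[as.character(ci), 1] - k[i]
      cand <- c(setdiff(rownames(conn), as.character(ci)), ".new")
      best_gain <- tol
      best_d <- NULL
      for (d in cand) {
        s_d <- if (d == ".new") 0 else conn[d, 1]
        k_d <- if (d == ".new") 0 else kc[d, 1]
        gain <- (2 / two_m) *
          ((s_d - s_ci) - gamma * k[i] * (k_d - k_ci) / two_m)
        if (gain > best_gain) { best_gain <- gain; best_d <- d }
      }
      if (!is.null(best_d)) {
        mem[i] <- if (best_d == ".new") max(mem) + 1L else as.integer(best_d)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  mem
}

#' Louvain modularity maximization with repetitions
#'
#' Runs the Louvain heuristic `repetitions` times under randomly permuted
#' node orders (seeded), refines each result with greedy single-node moves
#' until no move improves Q, and returns the partition with the largest
#' Q(gamma).
#' Community labels are relabeled to contiguous 1..K in order of first
#' appearance; the stored Q is recomputed from the assignment by
#' [modularity_value()].
#'
#' @param net a `gn_group` or symmetric matrix; weights are used as-is
#'   (binarize beforehand for binary modularity).
#' @param gamma resolution parameter, > 0.
#' @param seed integer seed for the node-order substream.
#' @param repetitions number of restarts (>= 1).
#' @return list of class `gn_partition` with `membership`, `q`, `gamma`,
#'   `n_communities`.
#' @export
modularity_louvain <- function(net, gamma = 1, seed = 1, repetitions = 100) {
  stopifnot(gamma > 0, repetitions >= 1)
  w <- as_weight_matrix(net)
  n <- nrow(w)
  if (sum(w) <= 0) gn_stop("modularity undefined: network has no edges")
  best_q <- -Inf
  best_mem <- NULL
  with_seed(substream_seed(seed, "louvain"), {
    for (r in seq_len(repetitions)) {
      perm <- sample.int(n)
      wp <- w[perm, perm, drop = FALSE]
      g <- net_igraph(wp, weighted = TRUE)
      cl <- igraph::cluster_louvain(g, resolution = gamma)
      mem <- integer(n)
      mem[perm] <- igraph::membership(cl)
      mem <- refine_partition(w, mem, gamma)
      q <- modularity_value(w, mem, gamma = gamma)
      if (q > best_q) { best_q <- q; best_mem <- mem }
    }
  })
  mem <- match(best_mem, unique(best_mem))  # contiguous 1..K
  structure(list(membership = mem, q = best_q, gamma = gamma,
                 n_communities = length(unique(mem))),
            class = "gn_partition")
}

#' Sweep the modularity resolution parameter
#'
#' @param net a `gn_group` or symmetric matrix.
#' @param gammas numeric grid (default 0.7 to 2.1 in steps of 0.1).
#' @param repetitions Louvain restarts per gamma.
#' @param seed master seed; each gamma gets its own substream.
#' @return list of `gn_partition`, one per gamma.
#' @export
modularity_sweep <- function(net, gammas = seq(0.7, 2.1, by = 0.1),
                             repetitions = 100, seed = 1) {
  out <- lapply(seq_along(gammas), function(i) {
    modularity_louvain(net, gamma = gammas[i],
                       seed = substream_seed(seed, sprintf("gamma%02d", i)),
                       repetitions = repetitions)
  })
  names(out) <- sprintf("gamma_%.1f", gammas)
  out
}

#' Participation coefficient
#'
#' `p_i = 1 - sum_s (kappa_is / k_i)^2`, where kappa_is is the weight of
#' node i's connections into module s. Values near 1 mean connections are
#' spread across many modules; 0 means all connections stay in one module.
#' Isolated nodes (k_i = 0) get 0.
#'
#' @param net a `gn_group` or symmetric matrix.
#' @param partition a `gn_partition` or integer membership vector.
#' @param weighted use weights (strength) rather than the binarized matrix.
#' @return numeric vector of length N in `[0, 1]`.
#' @export
participation <- function(net, partition, weighted = FALSE) {
  w <- as_weight_matrix(net)
  mem <- if (inherits(partition, "gn_partition")) partition$membership
         else as.integer(partition)
  stopifnot(length(mem) == nrow(w))
  a <- if (weighted) w else (w > 0) + 0
  k <- rowSums(a)
  mods <- sort(unique(mem))
  kappa <- vapply(mods, function(s) rowSums(a[, mem == s, drop = FALSE]),
                  numeric(nrow(a)))
  p <- 1 - rowSums((kappa / pmax(k, 1e-300))^2)
  unname(ifelse(k > 0, p, 0))
}
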