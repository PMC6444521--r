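# Group-representative network construction: consensus matrix, simple
# average, uniform / density-matched / distance-dependent consensus
# thresholds, and the two-step weight assignment.

#' Connection consensus across subjects
#'
#' Entry (i, j) is the fraction of subjects in which edge \{i, j\} is
#' expressed (weight > 0). Every entry is a multiple of 1/T.
#'
#' @param cohort a `gn_cohort`.
#' @return symmetric N x N matrix in `[0, 1]` with attribute `n_subjects`.
#' @export
compute_consensus <- function(cohort) {
  stopifnot(inherits(cohort, "gn_cohort"))
  t_sub <- length(cohort$matrices)
  C <- Reduce(`+`, lapply(cohort$matrices, function(m) (m > 0) + 0)) / t_sub
  attr(C, "n_subjects") <- t_sub
  C
}

#' Simple-average group network
#'
#' Each connection's weight is its mean over the subjects that express it
#' (zero-weight subjects are ignored); the edge set is every pair expressed
#' in at least one subject. This is the densest of the four group methods.
#'
#' @param cohort a `gn_cohort`.
#' @return a `gn_group` with method `"simple"`.
#' @export
simple_average <- function(cohort) {
  stopifnot(inherits(cohort, "gn_cohort"))
  sums <- Reduce(`+`, cohort$matrices)
  counts <- Reduce(`+`, lapply(cohort$matrices, function(m) (m > 0) + 0))
  w <- ifelse(counts > 0, sums / pmax(counts, 1), 0)
  new_group_network(w, method = "simple",
                    params = list(n_subjects = length(cohort$matrices)),
                    nodes = cohort$nodes)
}

# Pooled positive subject-level connection weights (each undirected edge
# counted once per expressing subject), sorted ascending.
pooled_subject_weights <- function(cohort) {
  up <- upper.tri(cohort$matrices[[1L]])
  w <- unlist(lapply(cohort$matrices, function(m) {
    v <- m[up]; v[v > 0]
  }), use.names = FALSE)
  sort(w)
}

# Pooled subject-level edge lengths with per-subject multiplicity, restricted
# to the pair indices in `keep` (logical over upper_pairs order). The
# multiplicity convention (an edge expressed by k subjects contributes k
# copies) is isolated here.
pooled_edge_lengths <- function(cohort, dist, keep = NULL) {
  pairs <- upper_pairs(nrow(cohort$nodes))
  if (!is.null(keep)) pairs <- pairs[keep, , drop = FALSE]
  len <- dist[pairs]
  unlist(lapply(cohort$matrices, function(m) {
    len[m[pairs] > 0]
  }), use.names = FALSE)
}

#' Uniform consensus threshold
#'
#' Retains every pair whose consensus satisfies `C_ij >= tau` (inclusive).
#' Pairs expressed in no subject (consensus 0) are never retained, even at
#' `tau = 0`.
#'
#' @param consensus consensus matrix from [compute_consensus()].
#' @param tau scalar threshold in `[0, 1]`, or a named vector with one value
#'   per class when `classes` is given.
#' @param classes optional `gn_classes` partition for class-wise thresholds.
#' @return integer matrix of retained pairs (columns `i`, `j`).
#' @export
uniform_threshold_edges <- function(consensus, tau, classes = NULL) {
  if (any(tau < 0 | tau > 1)) gn_stop("tau must lie in [0, 1]")
  n <- nrow(consensus)
  pairs <- upper_pairs(n)
  cv <- pair_values(consensus, pairs)
  if (is.null(classes)) {
    keep <- cv > 0 & cv >= tau
  } else {
    cls <- classes$class
    tv <- if (length(tau) == 1L) stats::setNames(rep(tau, length(unique(cls))),
                                                unique(cls)) else tau
    keep <- cv > 0 & cv >= tv[cls]
  }
  pairs[keep, , drop = FALSE]
}

# Per-class target edge count: round(mean subject edge count in the class).
class_targets <- function(cohort, classes) {
  pairs <- classes$pairs
  cls <- classes$class
  counts_per_subject <- vapply(cohort$matrices, function(m) {
    expressed <- m[pairs] > 0
    vapply(split(expressed, cls), sum, 0)
  }, numeric(length(unique(cls))))
  if (is.null(dim(counts_per_subject)))
    counts_per_subject <- matrix(counts_per_subject, nrow = 1,
                                 dimnames = list(unique(cls)))
  round(rowMeans(counts_per_subject))
}

#' Density-matched consensus threshold (tau = Avg)
#'
#' Chooses, separately per edge class, the consensus threshold whose retained
#' edge count matches the class's mean subject-level edge count. Two tie
#' policies are available:
#'
#' * `ties = "match"` (default): all edges with consensus strictly above the
#'   boundary level are retained, and the boundary-consensus edges are ranked
#'   by simple-average weight (then lexicographic pair order) and admitted
#'   until the target count is hit exactly. With T subjects the consensus
#'   takes only T distinct levels, so without this rule the achievable counts
#'   are coarse; this policy realizes the density-matched method's defining
#'   property that its binary density equals the typical subject's.
#' * `ties = "sweep"`: sweep the distinct consensus values in the class and
#'   retain `C_ij >= tau` for the value minimizing the absolute count error;
#'   count-error ties resolve toward the denser network.
#'
#' @param consensus consensus matrix.
#' @param cohort the `gn_cohort` the consensus was computed from.
#' @param classes a `gn_classes` partition (e.g. [hemisphere_partition()]).
#' @param ties `"match"` or `"sweep"`.
#' @return list with `edges` (pair matrix), `tau` (named per-class boundary
#'   consensus), `target` and `achieved` (named per-class counts).
#' @export
density_matched_tau <- function(consensus, cohort, classes,
                                ties = c("match", "sweep")) {
  ties <- match.arg(ties)
  pairs <- classes$pairs
  cls <- classes$class
  cv <- pair_values(consensus, pairs)
  targets <- class_targets(cohort, classes)
  wv <- pair_values(simple_average(cohort)$weights, pairs)
  keep <- logical(nrow(pairs))
  taus <- achieved <- stats::setNames(numeric(length(targets)), names(targets))
  for (k in names(targets)) {
    in_k <- which(cls == k)
    pos <- in_k[cv[in_k] > 0]
    target <- targets[[k]]
    if (!length(pos)) {
      gn_warn("class '%s' has no expressed edges", k)
      taus[k] <- NA_real_; achieved[k] <- 0
      next
    }
    if (ties == "sweep") {
      vals <- sort(unique(cv[pos]), decreasing = TRUE)
      counts <- vapply(vals, function(v) sum(cv[pos] >= v), 0)
      err <- abs(counts - target)
      best <- which(err == min(err))
      best <- best[which.max(counts[best])]  # tie -> denser
      taus[k] <- vals[best]
      sel <- pos[cv[pos] >= vals[best]]
    } else {
      m_k <- min(target, length(pos))
      ord <- pos[order(-cv[pos], -wv[pos],
                       pairs[pos, 1L], pairs[pos, 2L])]
      sel <- ord[seq_len(m_k)]
      taus[k] <- if (m_k > 0) cv[sel[m_k]] else NA_real_
    }
    keep[sel] <- TRUE
    achieved[k] <- length(sel)
  }
  list(edges = pairs[keep, , drop = FALSE], tau = taus,
       target = targets, achieved = achieved)
}

#' Percentile bins of the pooled subject edge-length distribution
#'
#' For each edge class, subjects' expressed-edge lengths are pooled (with
#' per-subject multiplicity) and divided into M equiprobable bins, where M is
#' the class's mean subject-level edge count. Bin boundaries are the j/M
#' quantiles (sorted-value linear interpolation) of the pooled multiset.
#'
#' @param cohort a `gn_cohort`.
#' @param dist Euclidean distance matrix from [euclidean_distances()].
#' @param classes a `gn_classes` partition.
#' @return named list (per class) of objects with fields `m`, `boundaries`
#'   (length m + 1), `pooled_lengths`, `degenerate` (all lengths equal).
#' @export
distance_binning <- function(cohort, dist, classes) {
  cls <- classes$class
  targets <- class_targets(cohort, classes)
  out <- list()
  for (k in names(targets)) {
    keep <- cls == k
    pooled <- sort(pooled_edge_lengths(cohort, dist, keep))
    m_k <- targets[[k]]
    if (!length(pooled) || m_k < 1L) {
      gn_warn("class '%s' has no expressed edges; empty binning", k)
      out[[k]] <- list(class = k, m = 0L, boundaries = numeric(0),
                       pooled_lengths = pooled, degenerate = TRUE)
      next
    }
    bounds <- sorted_quantile(pooled, seq(0, 1, length.out = m_k + 1L))
    out[[k]] <- list(class = k, m = as.integer(m_k), boundaries = bounds,
                     pooled_lengths = pooled,
                     degenerate = isTRUE(min(pooled) == max(pooled)))
  }
  out
}

#' Distance-dependent consensus edge selection
#'
#' Within each edge class, length bins are processed in order of increasing
#' distance. Each bin's candidates are the not-yet-selected pairs of that
#' class, expressed in at least one subject, whose Euclidean length falls in
#' the bin's (closed) interval. The candidate with the greatest consensus is
#' selected; ties are broken by the greatest simple-average weight, residual
#' ties by lexicographic pair order. Bins with no candidates are skipped (and
#' counted), so the achieved edge count can fall below M.
#'
#' @param consensus consensus matrix.
#' @param binning output of [distance_binning()].
#' @param simple the simple-average `gn_group` (tie-break weights).
#' @param dist Euclidean distance matrix.
#' @param classes the `gn_classes` partition the binning was built with.
#' @return list with `edges` (pair matrix), `skipped` (named per-class count
#'   of empty bins), `achieved` (named per-class edge counts).
#' @export
distance_dependent_edges <- function(consensus, binning, simple, dist,
                                     classes) {
  pairs <- classes$pairs
  cls <- classes$class
  cv <- pair_values(consensus, pairs)
  wv <- pair_values(simple$weights, pairs)
  lv <- dist[pairs]
  keep <- logical(nrow(pairs))
  skipped <- achieved <- stats::setNames(integer(length(binning)),
                                         names(binning))
  for (k in names(binning)) {
    b <- binning[[k]]
    if (b$m < 1L) next
    cand <- which(cls == k & cv > 0)
    if (!length(cand)) { skipped[k] <- b$m; next }
    ord <- cand[order(lv[cand])]
    len_sorted <- lv[ord]
    selected <- logical(length(ord))
    for (bin in seq_len(b$m)) {
      lo <- b$boundaries[bin]; hi <- b$boundaries[bin + 1L]
      start <- findInterval(lo, len_sorted, left.open = TRUE) + 1L
      end <- findInterval(hi, len_sorted)
      if (start > end) { skipped[k] <- skipped[k] + 1L; next }
      slice <- start:end
      open <- slice[!selected[slice]]
      if (!length(open)) { skipped[k] <- skipped[k] + 1L; next }
      idx <- ord[open]
      best <- open[order(-cv[idx], -wv[idx],
                         pairs[idx, 1L], pairs[idx, 2L])][1L]
      selected[best] <- TRUE
    }
    sel <- ord[selected]
    keep[sel] <- TRUE
    achieved[k] <- length(sel)
  }
  list(edges = pairs[keep, , drop = FALSE], skipped = skipped,
       achieved = achieved)
}

#' Two-step weight assignment from the pooled subject weight distribution
#'
#' Step 1 gives every retained edge its simple-average weight. Step 2 ranks
#' the retained edges by that weight (ties broken by lexicographic pair
#' order) and reassigns rank r the value at quantile (r-1)/(M-1) of the
#' sorted pooled positive subject-level weights, by linear interpolation at
#' fractional position q (P-1). The remapped weights preserve rank order and
#' match the pooled distribution: min/max equal the pooled min/max, and the
#' two-sample KS statistic against the pooled weights is at most 1/M + 1/P.
#'
#' @param edges pair matrix of retained edges.
#' @param cohort the `gn_cohort`.
#' @param simple the simple-average `gn_group`.
#' @return a `gn_group` with method `"reweighted"` (callers typically wrap it
#'   with their own provenance).
#' @export
assign_weights <- function(edges, cohort, simple) {
  n <- nrow(cohort$nodes)
  m_e <- nrow(edges)
  if (m_e == 0L)
    return(new_group_network(matrix(0, n, n), method = "reweighted",
                             params = list(m = 0L), nodes = cohort$nodes))
  w1 <- simple$weights[edges]
  if (any(w1 <= 0))
    gn_stop("assign_weights: %d retained edge(s) have no expressing subject",
            sum(w1 <= 0))
  pooled <- pooled_subject_weights(cohort)
  p_n <- length(pooled)
  rank_order <- order(w1, edges[, 1L], edges[, 2L])
  q <- if (m_e == 1L) 0.5 else (seq_len(m_e) - 1) / (m_e - 1)
  remapped <- sorted_quantile(pooled, q)
  w2 <- numeric(m_e)
  w2[rank_order] <- remapped
  w <- matrix(0, n, n)
  w[edges] <- w2
  w[edges[, c(2L, 1L), drop = FALSE]] <- w2
  dimnames(w) <- list(cohort$nodes$name, cohort$nodes$name)
  new_group_network(w, method = "reweighted",
                    params = list(m = m_e, pooled_n = p_n),
                    nodes = cohort$nodes)
}

#' Group-network container
#'
#' @param weights symmetric nonnegative N x N matrix, zero diagonal.
#' @param method method name.
#' @param params provenance list (thresholds, bin counts, seeds, densities).
#' @param nodes optional `gn_nodes` used to set dimnames.
#' @return object of class `gn_group`: list with `weights`, `edges` (pair
#'   matrix of positive-weight pairs), `method`, `params`.
#' @export
new_group_network <- function(weights, method, params = list(), nodes = NULL) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (!is.null(nodes)) dimnames(weights) <- list(nodes$name, nodes$name)
  pairs <- upper_pairs(nrow(weights))
  pos <- pair_values(weights, pairs) > 0
  structure(list(weights = weights, edges = pairs[pos, , drop = FALSE],
                 method = method, params = params),
            class = "gn_group")
}

#' @export
print.gn_group <- function(x, ...) {
  n <- nrow(x$weights)
  cat(sprintf("gn_group [%s]: %d nodes, %d edges (density %.4f)\n",
              x$method, n, nrow(x$edges),
              nrow(x$edges) / (n * (n - 1) / 2)))
  invisible(x)
}

#' Build a group-representative network
#'
#' Dispatches to one of the four construction methods:
#' \describe{
#'   \item{`simple`}{retain every edge expressed in at least one subject,
#'     weighted by its mean over expressing subjects.}
#'   \item{`tau_fixed`}{uniform consensus threshold (default `tau = 0.5`),
#'     applied identically in every class.}
#'   \item{`tau_avg`}{class-wise consensus threshold matched to the mean
#'     subject edge count ([density_matched_tau()]).}
#'   \item{`distance`}{distance-dependent consensus threshold: per class,
#'     percentile length bins of the pooled subject edge lengths, one
#'     highest-consensus edge per bin ([distance_dependent_edges()]).}
#' }
#' The three thresholding methods receive weights via the two-step pooled
#' remapping ([assign_weights()]); the simple method keeps its averages.
#'
#' @param method one of `"simple"`, `"tau_fixed"`, `"tau_avg"`, `"distance"`.
#' @param cohort a `gn_cohort`.
#' @param tau threshold for `tau_fixed`.
#' @param classes a `gn_classes` partition; default [hemisphere_partition()]
#'   for `tau_avg` and `distance`, single-class for `tau_fixed`.
#' @param ties tie policy for `tau_avg` (see [density_matched_tau()]).
#' @param dist optional precomputed Euclidean distance matrix.
#' @param seed integer recorded in provenance (the builders are themselves
#'   deterministic).
#' @return a `gn_group` with fully populated provenance in `$params`.
#' @export
build_group_network <- function(method = c("simple", "tau_fixed", "tau_avg",
                                           "distance"),
                                cohort, tau = 0.5, classes = NULL,
                                ties = "match", dist = NULL, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "gn_cohort"))
  n <- nrow(cohort$nodes)
  if (method == "simple") {
    g <- simple_average(cohort)
    g$params$seed <- seed
    return(g)
  }
  consensus <- compute_consensus(cohort)
  simple <- simple_average(cohort)
  if (is.null(classes))
    classes <- if (method == "tau_fixed") single_class_partition(n)
               else hemisphere_partition(cohort$nodes)
  params <- list(seed = seed, n_subjects = length(cohort$matrices))
  if (method == "tau_fixed") {
    edges <- uniform_threshold_edges(consensus, tau, classes = classes)
    params$tau <- tau
  } else if (method == "tau_avg") {
    dm <- density_matched_tau(consensus, cohort, classes, ties = ties)
    edges <- dm$edges
    params$tau <- as.list(dm$tau)
    params$target <- as.list(dm$target)
    params$achieved <- as.list(dm$achieved)
    params$ties <- ties
  } else {
    if (is.null(dist)) dist <- euclidean_distances(cohort$nodes)
    binning <- distance_binning(cohort, dist, classes)
    dd <- distance_dependent_edges(consensus, binning, simple, dist, classes)
    edges <- dd$edges
    params$m <- lapply(binning, function(b) b$m)
    params$skipped_bins <- as.list(dd$skipped)
    params$achieved <- as.list(dd$achieved)
  }
  cls_tab <- table(classes$class)
  cls_of_edge <- classes$class[match(paste(edges[, 1L], edges[, 2L]),
                                     paste(classes$pairs[, 1L],
                                           classes$pairs[, 2L]))]
  params$density_per_class <-
    as.list(table(factor(cls_of_edge, names(cls_tab))) / as.numeric(cls_tab))
  g <- assign_weights(edges, cohort, simple)
  g$method <- method
  g$params <- c(params, g$params[setdiff(names(g$params), names(params))])
  g
}
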