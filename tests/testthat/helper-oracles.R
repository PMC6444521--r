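# Independent brute-force oracles used to validate the graph measures.
# These deliberately avoid igraph and the package's own code paths.

# Floyd-Warshall shortest paths on a length matrix (Inf = no edge, 0 diag).
oracle_distances <- function(len) {
  d <- len
  n <- nrow(d)
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# Betweenness on a binary adjacency matrix via walk counting: the number of
# shortest h-j paths equals the number of length-D(h,j) walks, and the number
# passing through i is sigma(h,i) * sigma(i,j) when distances are additive.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  len <- ifelse(adj > 0, 1, Inf); diag(len) <- 0
  d <- oracle_distances(len)
  maxd <- max(d[is.finite(d)])
  pow <- vector("list", max(maxd, 1))
  pow[[1]] <- adj
  if (maxd >= 2)
    for (r in 2:maxd) pow[[r]] <- pow[[r - 1]] %*% adj
  sigma <- function(h, j) {
    if (h == j) return(1)
    if (!is.finite(d[h, j])) return(0)
    pow[[d[h, j]]][h, j]
  }
  b <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (h in seq_len(n)) for (j in seq_len(n)) {
      if (h == j || h == i || j == i) next
      if (!is.finite(d[h, j])) next
      if (is.finite(d[h, i]) && is.finite(d[i, j]) &&
          d[h, i] + d[i, j] == d[h, j])
        acc <- acc + sigma(h, i) * sigma(i, j) / sigma(h, j)
    }
    b[i] <- acc / ((n - 1) * (n - 2))
  }
  b
}

# All set partitions of n labeled elements as restricted growth strings.
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive maximum of Q(gamma) over all partitions (n <= 8).
oracle_best_modularity <- function(w, gamma = 1) {
  k <- rowSums(w)
  two_m <- sum(k)
  b <- w - gamma * outer(k, k) / two_m
  best <- -Inf
  for (p in oracle_partitions(nrow(w))) {
    q <- sum(b * outer(p, p, `==`)) / two_m
    if (q > best) best <- q
  }
  best
}

# Pearson correlation of endpoint degrees over the (symmetrized) edge list.
oracle_edge_pearson <- function(adj) {
  k <- rowSums(adj > 0)
  e <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  x <- c(k[e[, 1]], k[e[, 2]])
  y <- c(k[e[, 2]], k[e[, 1]])
  stats::cor(x, y)
}

# Random connected undirected binary graph on n nodes.
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
    a <- a + t(a)
    len <- ifelse(a > 0, 1, Inf); diag(len) <- 0
    if (all(is.finite(oracle_distances(len)))) return(a)
  }
}
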