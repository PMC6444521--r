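# Shared internal helpers: canonical edge enumeration, seed substreams,
# small numeric utilities.

#' Enumerate unordered node pairs
#'
#' Returns the canonical enumeration of unordered node pairs \{i, j\}, i < j,
#' as a two-column integer matrix. The ordering is column-major over the upper
#' triangle, i.e. (1,2), (1,3), (2,3), (1,4), ... This is the edge order used
#' internally wherever per-pair vectors (consensus values, class labels,
#' lengths) are aligned.
#'
#' @param n number of nodes.
#' @return integer matrix with columns `i`, `j` and `n*(n-1)/2` rows.
#' @export
upper_pairs <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- cbind(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]))
  m[order(m[, "i"], m[, "j"]), , drop = FALSE] -> m
  # reorder to lexicographic (i, then j): makes tie-breaking rules read
  # directly off row order
  m
}

# Extract the upper-triangle vector of a symmetric matrix in the order given
# by upper_pairs(nrow(mat)).
pair_values <- function(mat, pairs = upper_pairs(nrow(mat))) {
  mat[cbind(pairs[, 1L], pairs[, 2L])]
}

# Rebuild a symmetric matrix (zero diagonal) from per-pair values.
matrix_from_pairs <- function(values, pairs, n) {
  m <- matrix(0, n, n)
  m[cbind(pairs[, 1L], pairs[, 2L])] <- values
  m[cbind(pairs[, 2L], pairs[, 1L])] <- values
  m
}

#' Derive a named seed substream from a master seed
#'
#' One global seed is forked into named substreams (e.g. "simulation",
#' "louvain", "permutation") so that pipeline stages are independently
#' reproducible: changing the number of Louvain repetitions does not perturb
#' the permutation null, and vice versa.
#'
#' @param seed master integer seed.
#' @param stream character stream name.
#' @return an integer seed below 2^31, deterministic in `(seed, stream)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Symmetry check with tolerance.
is_symmetric_tol <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

# Linear-interpolation quantile of a *sorted* numeric vector at probabilities
# p, using fractional position p*(n-1) (the type-7 convention). Kept explicit
# because bin boundaries and weight remapping both depend on this exact rule.
sorted_quantile <- function(x_sorted, p) {
  n <- length(x_sorted)
  if (n == 1L) return(rep(x_sorted, length(p)))
  pos <- p * (n - 1)
  lo <- pmin(floor(pos), n - 1)
  frac <- pos - lo
  a <- x_sorted[lo + 1L]
  b <- x_sorted[pmin(lo + 2L, n)]
  # a + frac*(b-a) is exact when a == b or frac == 0, which keeps
  # rank-remapping onto a distribution's own values bit-exact
  a + frac * (b - a)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded internals (Louvain restarts, permutation nulls) never
# perturb user-level randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

gn_stop <- function(...) stop(sprintf(...), call. = FALSE)
gn_warn <- function(...) warning(sprintf(...), call. = FALSE)
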