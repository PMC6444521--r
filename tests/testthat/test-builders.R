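# Consensus computation, the four construction methods, binning, and the
# two-step weight assignment.

test_that("consensus counts the fraction of expressing subjects", {
  nodes <- toy_nodes(x = 1:3, hemisphere = rep("L", 3))
  co <- cohort_from_edges(nodes, list(
    cbind(1, 2), cbind(1, 2), rbind(c(1, 3)), rbind(c(1, 3))))
  C <- compute_consensus(co)
  expect_equal(C[1, 2], 0.5)   # 2 of 4
  expect_equal(C[1, 3], 0.5)
  expect_equal(C[2, 3], 0)

  co3 <- cohort_from_edges(nodes, list(cbind(1, 2), cbind(2, 3), cbind(1, 2)))
  expect_equal(compute_consensus(co3)[1, 2], 2 / 3)  # pattern (1,0,1)

  all_in <- cohort_from_edges(nodes, rep(list(cbind(1, 2)), 3))
  expect_equal(compute_consensus(all_in)[1, 2], 1)
  expect_true(is_sym <- isSymmetric(compute_consensus(all_in)))
})

test_that("simple average ignores non-expressing subjects", {
  nodes <- toy_nodes(x = 1:3, hemisphere = rep("L", 3))
  co <- cohort_from_edges(nodes, list(
    cbind(1, 2, 2), cbind(1, 2, 4), cbind(1, 3, 9)))
  g <- simple_average(co)
  expect_equal(g$weights[1, 2], 3)        # mean of 2 and 4, third ignored
  expect_equal(g$weights[1, 3], 9)
  expect_equal(g$weights[2, 3], 0)
  expect_equal(nrow(g$edges), 2)          # absent pair not in edge set

  single <- cohort_from_edges(nodes, list(cbind(1, 2, 7)))
  expect_equal(unname(simple_average(single)$weights),
               unname(single$matrices[[1]]))
})

test_that("uniform threshold is inclusive and never retains zero consensus", {
  nodes <- toy_nodes(x = 1:3, hemisphere = rep("L", 3))
  co <- cohort_from_edges(nodes, list(cbind(1, 2), rbind(c(1, 2), c(1, 3))))
  C <- compute_consensus(co)
  e50 <- uniform_threshold_edges(C, 0.5)
  expect_equal(nrow(e50), 2)              # C = 0.5 retained at tau = 0.5
  e0 <- uniform_threshold_edges(C, 0)
  expect_equal(nrow(e0), 2)               # zero-consensus pair excluded
  e1 <- uniform_threshold_edges(C, 1)
  expect_equal(unname(e1), cbind(1L, 2L))
  expect_error(uniform_threshold_edges(C, 1.2), "tau")
})

test_that("threshold retention is monotone in tau", {
  co <- generate_cohort(synthetic_config(n_nodes = 30, t_subjects = 6),
                        seed = 3)
  C <- compute_consensus(co)
  key <- function(e) paste(e[, 1], e[, 2])
  prev <- NULL
  for (tau in c(0, 0.25, 0.5, 0.75, 1)) {
    e <- uniform_threshold_edges(C, tau)
    if (!is.null(prev)) expect_true(all(key(e) %in% prev))
    prev <- key(e)
  }
})

test_that("density-matched sweep picks the count closest to target", {
  # consensus multiset {1 x3, 2/3 x2, 1/3 x4} on one class; T = 3
  nodes <- toy_nodes(x = 1:5, hemisphere = rep("L", 5))
  full <- rbind(c(1, 2), c(1, 3), c(1, 4))       # C = 1
  two <- rbind(c(1, 5), c(2, 3))                  # C = 2/3
  one <- rbind(c(2, 4), c(2, 5), c(3, 4), c(3, 5))  # C = 1/3
  co <- cohort_from_edges(nodes, list(
    rbind(full, two, one[1:2, ]),
    rbind(full, two, one[3:4, ]),
    full))
  C <- compute_consensus(co)
  cls <- single_class_partition(5)
  dm <- density_matched_tau(C, co, cls, ties = "sweep")
  expect_equal(unname(dm$tau["all"]), 2 / 3)
  expect_equal(unname(dm$achieved["all"]), 5)
  expect_equal(unname(dm$target["all"]), 6)

  # default policy tops up at the boundary level to hit the target exactly
  dm2 <- density_matched_tau(C, co, cls, ties = "match")
  expect_equal(unname(dm2$achieved["all"]), 6)
  expect_equal(nrow(dm2$edges), 6)
})

test_that("sweep ties between equidistant counts resolve toward density", {
  # achievable counts 3 (tau=1) and 7 (tau=0.5); target 5 -> denser wins
  nodes <- toy_nodes(x = 1:5, hemisphere = rep("L", 5))
  both <- rbind(c(1, 2), c(1, 3), c(1, 4))
  half <- rbind(c(1, 5), c(2, 3), c(2, 4), c(2, 5))
  co <- cohort_from_edges(nodes, list(rbind(both, half), both))
  dm <- density_matched_tau(compute_consensus(co), co,
                            single_class_partition(5), ties = "sweep")
  expect_equal(unname(dm$tau["all"]), 0.5)
  expect_equal(unname(dm$achieved["all"]), 7)
})

test_that("quantile binning follows the sorted-value interpolation rule", {
  pooled <- c(1, 1, 2, 4, 7, 7)
  bounds <- groupnet:::sorted_quantile(sort(pooled), seq(0, 1, length.out = 3))
  expect_equal(bounds, c(1, 3, 7))        # median split at (2+4)/2
  expect_equal(pooled[pooled >= bounds[1] & pooled <= bounds[2]], c(1, 1, 2))
  expect_equal(pooled[pooled > bounds[2] & pooled <= bounds[3]], c(4, 7, 7))
})

test_that("distance binning partitions pooled lengths into M quantile bins", {
  co <- generate_cohort(synthetic_config(n_nodes = 40, t_subjects = 5),
                        seed = 9)
  d <- euclidean_distances(co$nodes)
  classes <- hemisphere_partition(co$nodes)
  bins <- distance_binning(co, d, classes)
  targets <- groupnet:::class_targets(co, classes)
  for (k in names(bins)) {
    b <- bins[[k]]
    expect_equal(b$m, unname(targets[k]))
    expect_length(b$boundaries, b$m + 1)
    expect_true(!is.unsorted(b$boundaries))
    expect_equal(b$boundaries[1], min(b$pooled_lengths))
    expect_equal(b$boundaries[b$m + 1], max(b$pooled_lengths))
    # every pooled length falls inside some bin
    expect_true(all(b$pooled_lengths >= b$boundaries[1] &
                      b$pooled_lengths <= b$boundaries[b$m + 1]))
  }
})

test_that("identical subjects give one distinct length per bin", {
  co <- identical_subject_cohort(n = 20, t = 4, seed = 2)
  d <- euclidean_distances(co$nodes)
  classes <- single_class_partition(20)
  bins <- distance_binning(co, d, classes)
  b <- bins[["all"]]
  subject_len <- sort(unique(edge_lengths(co$matrices[[1]], d)))
  expect_equal(b$m, length(subject_len))
  # boundaries strictly interleave the distinct subject lengths
  inner <- b$boundaries[2:b$m]
  expect_true(all(inner > subject_len[-length(subject_len)] &
                    inner < subject_len[-1]))
})

test_that("distance-dependent selection matches the hand-enumerated toy", {
  # nodes at x = 0, 1, 3, 7; subject edge sets give pooled lengths
  # [1,7,1,4,2,7] -> M = 2; bin1 picks (1,2) with C = 2/3, bin2 picks (1,4)
  nodes <- toy_nodes(x = c(0, 1, 3, 7), hemisphere = rep("L", 4))
  co <- cohort_from_edges(nodes, list(
    rbind(c(1, 2), c(1, 4)),
    rbind(c(1, 2), c(3, 4)),
    rbind(c(2, 3), c(1, 4))))
  d <- euclidean_distances(nodes)
  classes <- single_class_partition(4)
  C <- compute_consensus(co)
  bins <- distance_binning(co, d, classes)
  expect_equal(bins[["all"]]$m, 2)
  dd <- distance_dependent_edges(C, bins, simple_average(co), d, classes)
  expect_equal(unname(dd$edges), rbind(c(1L, 2L), c(1L, 4L)))
  expect_equal(unname(dd$skipped["all"]), 0L)
})

test_that("bin ties with equal consensus and weight break lexicographically", {
  # two candidates of identical length, consensus and mean weight
  nodes <- toy_nodes(x = c(0, 1, 0, 1), y = c(0, 0, 5, 5),
                     hemisphere = rep("L", 4))
  co <- cohort_from_edges(nodes, list(rbind(c(1, 2, 1), c(3, 4, 1))))
  d <- euclidean_distances(nodes)
  classes <- single_class_partition(4)
  C <- compute_consensus(co)
  # force a single bin: M = target = 2, but both edges have length 1 ->
  # degenerate boundaries; first bin takes the lexicographically smaller pair
  bins <- distance_binning(co, d, classes)
  dd <- distance_dependent_edges(C, bins, simple_average(co), d, classes)
  expect_true(any(dd$edges[, 1] == 1 & dd$edges[, 2] == 2))
})

test_that("identical-subject cohorts are recovered exactly by all methods", {
  co <- identical_subject_cohort(n = 30, t = 3, seed = 5)
  d <- euclidean_distances(co$nodes)
  subject_edges <- which(upper.tri(co$matrices[[1]]) &
                           co$matrices[[1]] > 0, arr.ind = TRUE)
  key <- function(e) sort(paste(e[, 1], e[, 2]))
  for (m in c("tau_fixed", "tau_avg", "distance")) {
    g <- build_group_network(m, co, dist = d)
    expect_equal(key(g$edges), key(subject_edges), label = m)
  }
})

test_that("two-step weight assignment interpolates the pooled distribution", {
  # simple-average weights [1, 5, 9]; pooled sorted weights [2, 4, 6, 8]
  nodes <- toy_nodes(x = 1:4, hemisphere = rep("L", 4))
  co <- cohort_from_edges(nodes, list(
    rbind(c(1, 2, 2), c(1, 3, 4), c(1, 4, 6), c(2, 3, 8))))
  simple <- new_group_network(
    matrix(0, 4, 4), method = "simple")
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1; w[1, 3] <- w[3, 1] <- 5; w[1, 4] <- w[4, 1] <- 9
  simple$weights <- w
  edges <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  g <- assign_weights(edges, co, simple)
  expect_equal(g$weights[edges], c(2, 5, 8))

  # M = P with distinct pooled weights: remap is the identity onto pooled
  co1 <- cohort_from_edges(nodes, list(
    rbind(c(1, 2, 3), c(1, 3, 1), c(1, 4, 4), c(2, 3, 2))))
  s1 <- simple_average(co1)
  g1 <- assign_weights(s1$edges, co1, s1)
  expect_equal(sort(g1$weights[g1$edges]), c(1, 2, 3, 4))
  # and rank order is preserved exactly
  expect_equal(g1$weights[g1$edges], s1$weights[s1$edges])

  # M = 1 -> pooled median
  gm <- assign_weights(rbind(c(1L, 2L)), co1, s1)
  expect_equal(gm$weights[1, 2], 2.5)

  # empty edge set -> empty network
  ge <- assign_weights(upper_pairs(4)[0, , drop = FALSE], co1, s1)
  expect_true(all(ge$weights == 0))

  # edge without expressing subject -> error
  expect_error(assign_weights(rbind(c(2L, 4L)), co1, s1), "expressing")
})

test_that("identical-subject remap returns the subject's own weights", {
  co <- identical_subject_cohort(n = 24, t = 5, seed = 8)
  s <- simple_average(co)
  g <- assign_weights(s$edges, co, s)
  expect_equal(g$weights[g$edges], co$matrices[[1]][g$edges],
               tolerance = 1e-12)
})

test_that("build_group_network dispatches and records provenance", {
  co <- generate_cohort(synthetic_config(n_nodes = 30, t_subjects = 2),
                        seed = 4)
  C <- compute_consensus(co)
  g <- build_group_network("tau_fixed", co, tau = 0.5, seed = 1)
  both <- which(upper.tri(C) & C >= 0.5, arr.ind = TRUE)
  expect_equal(nrow(g$edges), nrow(both))
  expect_equal(g$params$tau, 0.5)

  expect_error(build_group_network("bogus", co), "arg")

  co6 <- generate_cohort(synthetic_config(n_nodes = 40, t_subjects = 6),
                         seed = 6)
  d <- euclidean_distances(co6$nodes)
  dens <- sapply(c("simple", "tau_fixed", "tau_avg", "distance"),
                 function(m) nrow(build_group_network(m, co6, dist = d)$edges))
  expect_true(all(dens["simple"] >= dens))

  # consensus positivity: every retained edge is expressed somewhere
  C6 <- compute_consensus(co6)
  for (m in c("simple", "tau_fixed", "tau_avg", "distance")) {
    g6 <- build_group_network(m, co6, dist = d)
    expect_true(all(C6[g6$edges] > 0), label = m)
  }

  # determinism: identical inputs give identical outputs
  g_a <- build_group_network("distance", co6, dist = d, seed = 9)
  g_b <- build_group_network("distance", co6, dist = d, seed = 9)
  expect_identical(g_a$weights, g_b$weights)
})

test_that("tau_avg and distance match the mean subject density per class", {
  co <- generate_cohort(synthetic_config(n_nodes = 60, t_subjects = 8),
                        seed = 12)
  d <- euclidean_distances(co$nodes)
  classes <- hemisphere_partition(co$nodes)
  targets <- groupnet:::class_targets(co, classes)
  g_avg <- build_group_network("tau_avg", co, dist = d)
  g_dist <- build_group_network("distance", co, dist = d)
  for (k in names(targets)) {
    expect_equal(g_avg$params$achieved[[k]], unname(targets[k]))
    slack <- g_dist$params$skipped_bins[[k]]
    expect_lte(abs(g_dist$params$achieved[[k]] - targets[k]), slack)
  }
})
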