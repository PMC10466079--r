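test_that("profile standardization zeroes means, unit-scales, drops constants", {
  Z1 <- standardize_profiles(matrix(c(1, 2, 3), 1, 3,
                                    dimnames = list("f", NULL)))
  expect_equal(as.numeric(Z1), (c(1, 2, 3) - 2) / 1)
  X <- rbind(a = c(5, 5, 5), b = c(1, 3, 5), c = c(2, 0, 4))
  Z <- standardize_profiles(X)
  expect_identical(rownames(Z), c("b", "c"))
  expect_identical(attr(Z, "dropped"), "a")
  set.seed(6)
  R <- matrix(rnorm(60), 10, 6)
  ZR <- standardize_profiles(R)
  expect_equal(rowMeans(ZR), rep(0, 10), tolerance = 1e-12)
  expect_equal(apply(ZR, 1, sd), rep(1, 10), tolerance = 1e-12)
})

test_that("fuzzy c-means memberships are simplex-valued with a monotone objective", {
  set.seed(17)
  X <- matrix(rnorm(200), 50, 4)
  cl <- fuzzy_cmeans(X, k = 3, seed = 5)
  expect_equal(rowSums(cl$membership), rep(1, 50), tolerance = 1e-9)
  expect_true(all(cl$membership >= 0 & cl$membership <= 1))
  expect_true(all(diff(cl$objective) <= 1e-9))
  expect_error(fuzzy_cmeans(X, k = 50), "smaller than the number")
  expect_error(fuzzy_cmeans(X, k = 3, m = 1), "exceed 1")
})

test_that("well-separated profile groups are recovered with confident memberships", {
  sim <- simulate_profiles(n_per_cluster = 30, k = 2, n_conditions = 5,
                           separation = 10, noise = 1, seed = 21)
  Z <- sim$X
  cl <- fuzzy_cmeans(Z, k = 2, seed = 4)
  expect_true(all(apply(cl$membership, 1, max) > 0.9))
  # label-permutation-aware agreement with the ground truth
  agree <- max(mean(cl$cluster == sim$labels),
               mean(cl$cluster == 3 - sim$labels))
  expect_equal(agree, 1)
  # independent implementation agrees on the centers (label-matched)
  ec <- e1071::cmeans(Z, centers = 2, m = 2)
  ours <- cl$centers[order(cl$centers[, 1]), ]
  theirs <- ec$centers[order(ec$centers[, 1]), ]
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-2)
})

test_that("a feature coincident with a center gets membership one", {
  # the singularity rule itself: a zero distance wins the whole membership
  D2 <- rbind(c(0, 4), c(1, 9), c(0, 0))
  U <- proteopipe:::cmeans_membership(D2, m = 2)
  expect_equal(U[1, ], c(1, 0))
  expect_equal(U[3, ], c(0.5, 0.5))  # ties split evenly
  expect_equal(rowSums(U), rep(1, 3))
  # end to end: a tight clump pins its center and saturates membership
  set.seed(2)
  X <- rbind(matrix(0, 5, 3), matrix(rnorm(30, 10), 10, 3))
  cl <- fuzzy_cmeans(X, k = 2, seed = 2, tol = 1e-10, max_iter = 1000)
  at_zero <- which(rowSums(abs(X)) == 0)
  centered_on_zero <- which.min(rowSums(cl$centers^2))
  expect_lt(sum(cl$centers[centered_on_zero, ]^2), 1e-3)
  expect_true(all(cl$membership[at_zero, centered_on_zero] > 1 - 1e-3))
})

test_that("the hard-assignment limit is approached as m tends to 1", {
  sim <- simulate_profiles(n_per_cluster = 20, k = 3, n_conditions = 4,
                           separation = 8, noise = 0.5, seed = 33)
  cl <- fuzzy_cmeans(sim$X, k = 3, m = 1.05, seed = 6)
  expect_true(all(apply(cl$membership, 1, max) > 0.999))
})

test_that("network loading thresholds, merges orientations and strips prefixes", {
  path <- tempfile()
  writeLines(c("protein1 protein2 combined_score",
               "9606.TP53 9606.MDM2 900",
               "9606.MDM2 9606.TP53 500",
               "9606.TP53 9606.EGFR 300",
               "9606.EGFR 9606.KRAS 450",
               "9606.KRAS 9606.KRAS 999"), path)
  g <- load_network(path, score_threshold = 400)
  expect_equal(nrow(g$edges), 2L)  # low-score dropped, self-loop dropped
  tp53_mdm2 <- g$edges[g$edges$from == "MDM2", ]
  expect_equal(tp53_mdm2$combined_score, 900L)  # max over orientations
  expect_setequal(g$nodes, c("TP53", "MDM2", "EGFR", "KRAS"))
  writeLines(c("A B"), path)
  expect_error(load_network(path), "malformed network line")
})

test_that("node set equals the union of kept edge endpoints", {
  set.seed(41)
  nodes <- sprintf("N%02d", 1:15)
  edges <- t(combn(nodes, 2))
  keep <- sample(nrow(edges), 40)
  sc <- sample(100:1000, 40)
  path <- tempfile()
  writeLines(c("protein1 protein2 combined_score",
               paste(edges[keep, 1], edges[keep, 2], sc)), path)
  thr <- 400
  g <- load_network(path, thr)
  expect_setequal(g$nodes,
                  unique(c(edges[keep, ][sc >= thr, 1],
                           edges[keep, ][sc >= thr, 2])))
})

test_that("induced subnetworks equal the brute-force edge filter", {
  set.seed(43)
  nodes <- sprintf("N%02d", 1:12)
  pairs <- t(combn(nodes, 2))
  keep <- sample(nrow(pairs), 30)
  path <- tempfile()
  writeLines(c("protein1 protein2 combined_score",
               paste(pairs[keep, 1], pairs[keep, 2],
                     sample(400:1000, 30))), path)
  g <- load_network(path)
  expect_equal(nrow(induced_subnetwork(g, character())$edges), 0L)
  full <- induced_subnetwork(g, g$nodes)
  expect_identical(full$edges, g$edges)
  sub_nodes <- sample(nodes, 6)
  sub <- induced_subnetwork(g, tolower(sub_nodes))  # case-insensitive
  manual <- g$edges[g$edges$from %in% sub_nodes &
                      g$edges$to %in% sub_nodes, ]
  expect_equal(sub$edges, manual, ignore_attr = TRUE)
  # isolated queried nodes are retained; extraction is idempotent
  expect_setequal(sub$nodes, intersect(g$nodes, sub_nodes))
  expect_identical(induced_subnetwork(sub, sub_nodes)$edges, sub$edges)
})
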