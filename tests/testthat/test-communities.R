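two_cliques <- function() {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1
  diag(W) <- 0
  W
}

test_that("signed quality reproduces the two-clique Newman value", {
  W <- two_cliques()
  expect_equal(signed_quality(W, c(1, 1, 1, 2, 2, 2), gamma = 1), 0.5,
               tolerance = 1e-12)
})

test_that("all-singleton partitions give the closed-form null-only value", {
  set.seed(31)
  W <- random_signed_graph(8)
  gamma <- 1.7
  Wp <- pmax(W, 0); diag(Wp) <- 0
  Wn <- pmax(-W, 0); diag(Wn) <- 0
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  expected <- -gamma * (sum(sp^2 / vp) / vp - sum(sn^2 / vn) / (vp + vn))
  expect_equal(signed_quality(W, 1:8, gamma), expected, tolerance = 1e-12)
})

test_that("signed quality matches the brute-force definition and permutes", {
  set.seed(32)
  for (rep in 1:10) {
    W <- random_signed_graph(7)
    lab <- sample(1:3, 7, replace = TRUE)
    gamma <- runif(1, 0.2, 3)
    expect_equal(signed_quality(W, lab, gamma),
                 brute_signed_quality(W, lab, gamma), tolerance = 1e-12)
    p <- sample(7)
    expect_equal(signed_quality(W[p, p], lab[p], gamma),
                 signed_quality(W, lab, gamma), tolerance = 1e-12)
  }
  expect_error(signed_quality(-abs(random_signed_graph(5)), rep(1, 5)), "m\\+")
  expect_error(signed_quality(W, 1:3), "length")
})

test_that("on all-positive graphs the quality is Newman-Girvan modularity", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (rep in 1:5) {
    W <- abs(random_signed_graph(12))
    lab <- sample(1:3, 12, replace = TRUE)
    gamma <- runif(1, 0.5, 2)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    qig <- igraph::modularity(g, lab, weights = igraph::E(g)$weight,
                              resolution = gamma)
    expect_equal(signed_quality(W, lab, gamma), qig, tolerance = 1e-12)
  }
})

test_that("Louvain recovers planted signed blocks and reports exact quality", {
  W <- matrix(-0.2, 10, 10)
  W[1:5, 1:5] <- 0.8; W[6:10, 6:10] <- 0.8
  diag(W) <- 0
  for (s in 1:25) {
    part <- louvain_signed(W, gamma = 1, seed = s)
    expect_equal(adjusted_rand_index(part$labels, rep(1:2, each = 5)), 1)
    expect_equal(part$quality, signed_quality(W, part$labels, 1),
                 tolerance = 1e-15)
  }
})

test_that("best-of-seeds Louvain reaches the enumerated optimum on 6 nodes", {
  set.seed(34)
  parts <- all_partitions(6)
  hits <- 0
  for (g in 1:20) {
    W <- random_signed_graph(6)
    qstar <- max(vapply(parts, function(l) signed_quality(W, l, 1), numeric(1)))
    qbest <- max(vapply(1:20, function(s) louvain_signed(W, 1, seed = s)$quality,
                        numeric(1)))
    if (qbest >= qstar - 1e-12) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("z-Rand matches an exhaustive permutation-model oracle", {
  l1 <- c(1, 1, 1, 2, 2, 3, 3, 3)
  l2 <- c(1, 2, 1, 2, 3, 3, 1, 2)
  ch2 <- function(x) x * (x - 1) / 2
  wstat <- function(a, b) sum(ch2(table(a, b)))
  ws <- vapply(all_perms(1:8), function(p) wstat(l1, l2[p]), numeric(1))
  z_oracle <- (wstat(l1, l2) - mean(ws)) / sqrt(mean(ws^2) - mean(ws)^2)
  expect_equal(zrand_score(l1, l2), z_oracle, tolerance = 1e-10)

  # label invariance, symmetry, positivity for identical partitions
  expect_equal(zrand_score(l1, c(2, 2, 2, 3, 3, 1, 1, 1)),
               zrand_score(l1, l1))
  expect_gt(zrand_score(l1, l1), 0)
  expect_equal(zrand_score(l1, l2), zrand_score(l2, l1), tolerance = 1e-12)
  expect_warning(z <- zrand_score(rep(1, 8), rep(1, 8)), "single community")
  expect_true(is.na(z))
})

test_that("adjusted Rand index behaves at its reference points", {
  l <- rep(1:4, each = 5)
  expect_equal(adjusted_rand_index(l, c(3, 4, 1, 2)[l]), 1)
  set.seed(35)
  r <- replicate(50, adjusted_rand_index(sample(l), l))
  expect_lt(abs(mean(r)), 0.05)  # ~0 under independence
})

test_that("consensus recovers planted blocks and degenerates gracefully", {
  set.seed(36)
  lab <- rep(1:5, each = 6)
  W <- outer(lab, lab, `==`) * 0.6 - 0.1
  W <- W + matrix(rnorm(900, sd = 0.05), 30, 30)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  cons <- consensus_partition(W, gamma = 1, n_reps = 40, seed = 4L)
  expect_equal(adjusted_rand_index(cons$partition, lab), 1)
  expect_equal(cons$n_communities, 5)
  expect_gt(cons$zrand_mean, 0)
  expect_gte(cons$zrand_var, 0)

  # unanimous runs: zero z-Rand variance and the common partition returned
  W2 <- two_cliques() - 0.5 * (1 - two_cliques())
  diag(W2) <- 0
  cons2 <- consensus_partition(W2, gamma = 1, n_reps = 10, seed = 1L)
  expect_equal(adjusted_rand_index(cons2$partition, c(1, 1, 1, 2, 2, 2)), 1)
  expect_equal(cons2$zrand_var, 0)

  # determinism
  consA <- consensus_partition(W, gamma = 1, n_reps = 20, seed = 9L)
  consB <- consensus_partition(W, gamma = 1, n_reps = 20, seed = 9L)
  expect_identical(consA, consB)
})

test_that("gamma sweep covers the grid and tracks resolution", {
  expect_length(eval(formals(gamma_sweep)$gammas), 60)  # default 0.1..6.0 grid
  # low gamma on an all-positive graph collapses to one community
  set.seed(37)
  Wpos <- abs(random_signed_graph(12)) + 0.05
  sw0 <- gamma_sweep(Wpos, gammas = 0.01, n_reps = 5, seed = 2L)
  expect_equal(sw0$n_communities, 1)

  # nested hierarchy: communities do not decrease with gamma
  lab2 <- rep(1:2, each = 8)
  lab4 <- rep(1:4, each = 4)
  W <- outer(lab2, lab2, `==`) * 0.3 + outer(lab4, lab4, `==`) * 0.5 - 0.15
  diag(W) <- 0
  sw <- gamma_sweep(W, gammas = c(0.6, 1, 2, 4), n_reps = 20, seed = 3L)
  expect_equal(nrow(sw), 4)
  expect_true(all(diff(sw$n_communities) >= 0))
})

test_that("community degree maps sum to the full degree and match arithmetic", {
  set.seed(38)
  nodes <- toy_nodes(3, 4)
  fc <- compute_fc(matrix(rnorm(7 * 50), 7))
  part <- c(1L, 1L, 2L, 2L)
  maps <- community_degree_maps(fc, part, nodes)
  expect_equal(dim(maps), c(3, 2))
  expect_equal(unname(maps[, 1]), unname(rowSums(fc[1:3, 4:5])),
               tolerance = 1e-12)
  full <- weighted_degree(fc, seed_set = 4:7, target_set = 1:3)
  expect_equal(unname(rowSums(maps)), unname(full), tolerance = 1e-12)
  one <- community_degree_maps(fc, rep(1L, 4), nodes)
  expect_equal(unname(one[, 1]), unname(full), tolerance = 1e-12)
  expect_error(community_degree_maps(fc, c(1L, 1L), nodes), "cover")
})
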