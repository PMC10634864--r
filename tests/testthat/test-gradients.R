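chain_similarity <- function(n, tau = 5) {
  s <- exp(-abs(outer(1:n, 1:n, `-`)) / tau)
  diag(s) <- 1
  s
}

test_that("the first gradient of a 1D chain is monotone in chain position", {
  emb <- diffusion_embedding(chain_similarity(30), n_components = 3,
                             sparsity = 0.7)
  rho <- cor(emb$scores[, 1], 1:30, method = "spearman")
  expect_equal(abs(rho), 1)
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))  # descending
})

test_that("a two-block similarity is separated by the gradient's sign", {
  lab <- rep(1:2, each = 10)
  s <- outer(lab, lab, `==`) * 0.8 + 0.1
  diag(s) <- 1
  emb <- diffusion_embedding(s, n_components = 2, sparsity = 0)
  g1 <- emb$scores[, 1]
  expect_true(all(sign(g1[lab == 1]) == sign(g1[1])))
  expect_true(all(sign(g1[lab == 2]) == -sign(g1[1])))
})

test_that("embedding matches a dense eigendecomposition oracle at 1e-8", {
  set.seed(41)
  sim <- cor(matrix(rnorm(40 * 20), 40, 20))
  sparsity <- 0.6; alpha <- 0.5
  emb <- diffusion_embedding(sim, n_components = 5, sparsity = sparsity,
                             alpha = alpha)

  # independent construction of the same normalised Markov operator
  L <- sim
  for (i in 1:20) {
    thr <- quantile(L[i, ], sparsity)
    L[i, L[i, ] < thr] <- 0
  }
  A <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    A[i, j] <- sum(L[i, ] * L[j, ]) /
      sqrt(sum(L[i, ]^2) * sum(L[j, ]^2))
  }
  A[A < 0] <- 0; diag(A) <- 1
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  M <- W / rowSums(W)              # Markov operator
  e <- eigen(M)                    # dense non-symmetric eigensolver
  ord <- order(Re(e$values), decreasing = TRUE)
  lam <- Re(e$values)[ord]
  expect_equal(lam[1], 1, tolerance = 1e-10)
  expect_equal(emb$eigenvalues, lam[2:6], tolerance = 1e-8)
  for (k in 1:5) {
    v <- Re(e$vectors[, ord[k + 1]])
    s <- emb$scores[, k]
    # same direction up to sign and scale
    v_fit <- v * as.numeric(crossprod(v, s) / crossprod(v))
    expect_lt(max(abs(s - v_fit)) / max(abs(s)), 1e-8)
  }
})

test_that("score columns are orthogonal in the embedding inner product", {
  emb <- diffusion_embedding(chain_similarity(25), n_components = 4,
                             sparsity = 0.6)
  # reconstruct the stationary weights of the embedding's Markov operator
  s <- chain_similarity(25)
  for (i in 1:25) {
    thr <- quantile(s[i, ], 0.6)
    s[i, s[i, ] < thr] <- 0
  }
  nrm <- sqrt(rowSums(s^2))
  A <- tcrossprod(s / nrm); A[A < 0] <- 0; diag(A) <- 1
  d <- rowSums(A)
  W <- A / outer(sqrt(d), sqrt(d))^(2 * 0.5)
  dw <- rowSums(W)
  G <- crossprod(emb$scores, dw * emb$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("embedding is equivariant under node permutation (up to sign)", {
  set.seed(42)
  sim <- cor(matrix(rnorm(36 * 18), 36, 18))
  e1 <- diffusion_embedding(sim, n_components = 2, sparsity = 0.6)
  p <- sample(18)
  e2 <- diffusion_embedding(sim[p, p], n_components = 2, sparsity = 0.6)
  for (k in 1:2) {
    r <- cor(e1$scores[p, k], e2$scores[, k])
    expect_equal(abs(r), 1, tolerance = 1e-8)
  }
})

test_that("disconnected affinity graphs are rejected with a component count", {
  s <- matrix(-1, 10, 10)
  s[1:5, 1:5] <- 1; s[6:10, 6:10] <- 1
  expect_error(diffusion_embedding(s, sparsity = 0.5), "2 components")
})

test_that("alignment flips the sign when needed and reports r", {
  emb <- diffusion_embedding(chain_similarity(30), n_components = 2,
                             sparsity = 0.7)
  self <- align_and_compare(emb, emb$scores[, 1])
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_false(self$flipped)
  neg <- align_and_compare(emb, -emb$scores[, 1])
  expect_equal(neg$r, 1, tolerance = 1e-12)
  expect_true(neg$flipped)
  expect_equal(neg$scores, -emb$scores[, 1], ignore_attr = TRUE)
})

test_that("pole degree maps match hand sums and swap under sign flip", {
  nodes <- toy_nodes(4, 2)
  fc <- diag(6)
  blk <- matrix(c(.1, .2, .3, .4, .5, .6, .7, .8), 4, 2)
  fc[1:4, 5:6] <- blk; fc[5:6, 1:4] <- t(blk)
  scores <- c(-1, -1, 1, 1)
  pd <- pole_degree(fc, scores, nodes)
  expect_equal(unname(pd$negative), colSums(blk[1:2, ]), tolerance = 1e-12)
  expect_equal(unname(pd$positive), colSums(blk[3:4, ]), tolerance = 1e-12)
  expect_equal(pd$n_zero, 0)
  # flip swaps poles; poles sum to the full cortex-seeded brainstem degree
  pd2 <- pole_degree(fc, -scores, nodes)
  expect_equal(pd2$negative, pd$positive)
  expect_equal(pd2$positive, pd$negative)
  total <- weighted_degree(fc, seed_set = 1:4, target_set = 5:6)
  expect_equal(pd$negative + pd$positive, total, tolerance = 1e-12)
  expect_error(pole_degree(fc, c(1, 2, 3, 4), nodes), "negatively-scored")
  expect_message(pole_degree(fc, c(-1, 0, 1, 1), nodes), "zero-scored")
})

test_that("a bimodal planted gradient places most nodes at the extremes", {
  g_bi <- tanh(3 * seq(-1, 1, length.out = 80))
  spec <- synth_spec(n_cortex = 80, n_brainstem = 20, n_subjects = 6,
                     n_timepoints = 240, gradient_loading = g_bi, seed = 23L)
  geom <- make_geometry(spec)
  fc <- group_average(lapply(sample_timeseries(spec, geom), compute_fc))
  res <- residualize_profiles(fc, geom$nodes)
  emb <- diffusion_embedding(profile_similarity(res, "cortex"))
  s <- emb$scores[, 1]
  expect_gt(mean(abs(s) > 0.5 * max(abs(s))), 0.6)
  expect_gte(abs(cor(s, g_bi, method = "spearman")), 0.95)
})
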