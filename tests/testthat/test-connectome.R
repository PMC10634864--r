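test_that("compute_fc reproduces hand-computed Pearson values", {
  ts <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 3, 2, 4))
  fc <- compute_fc(ts)
  expect_equal(diag(fc), c(a = 1, b = 1, c = 1))
  expect_equal(fc["a", "b"], -1, tolerance = 1e-12)
  expect_equal(fc["a", "c"], 0.8, tolerance = 1e-12)  # hand Pearson
  expect_equal(fc, t(fc))
  expect_equal(compute_fc(rbind(x = 1:4, y = 1:4))["x", "y"], 1)
})

test_that("compute_fc rejects bad input, naming the node", {
  expect_error(compute_fc(rbind(a = 1:4, flat = rep(2, 4))), "flat")
  expect_error(compute_fc(rbind(a = 1:4, b = c(1, NA, 2, 3))), "missing")
  expect_error(compute_fc(rbind(a = 1:2, b = 2:3)), "3 timepoints")
})

test_that("compute_fc is invariant to affine rescaling of a row", {
  set.seed(1)
  ts <- matrix(rnorm(5 * 30), 5)
  fc1 <- compute_fc(ts)
  ts[3, ] <- 2.5 * ts[3, ] - 7
  expect_equal(compute_fc(ts), fc1, tolerance = 1e-12)
})

test_that("group_average is the element-wise mean and checks shapes", {
  m1 <- matrix(c(1, .1, .1, 1), 2); m2 <- matrix(c(1, .2, .2, 1), 2)
  m3 <- matrix(c(1, .6, .6, 1), 2)
  expect_equal(group_average(list(m1))[1, 2], 0.1)
  expect_equal(group_average(list(m1, -m1))[1, 2], 0)
  expect_equal(group_average(list(m1, m2, m3))[1, 2], 0.3)
  expect_error(group_average(list(m1, matrix(0, 3, 3))), "shape")
  # commutes with a joint node permutation
  set.seed(2)
  fcs <- replicate(3, compute_fc(matrix(rnorm(4 * 20), 4)), simplify = FALSE)
  p <- sample(4)
  g <- group_average(fcs)
  gp <- group_average(lapply(fcs, function(m) m[p, p]))
  expect_equal(gp, g[p, p], ignore_attr = TRUE)
})

test_that("tSNR follows its definition and the size association behaves", {
  row <- c(8, 10, 12)  # mean 10, sample sd 2
  ts <- rbind(a = row, b = 2 * row)
  expect_equal(compute_tsnr(ts), c(a = 5, b = 5))
  expect_warning(out <- compute_tsnr(rbind(a = row, flat = c(3, 3, 3))),
                 "zero temporal sd")
  expect_true(is.na(out["flat"]))

  nodes <- toy_nodes(1, 5)
  nodes$size_voxels <- c(99L, 10L, 20L, 30L, 40L, 50L)
  tsnr <- c(0, 1, 2, 3, 4, 5)
  expect_equal(size_association(tsnr, nodes)$rho, 1)
  flat <- size_association(rep(2, 6), nodes)
  expect_equal(flat$rho, 0)
  expect_equal(flat$p, 1)
})

test_that("distance profile finds planted decay and splits blocks correctly", {
  w <- small_world()
  n <- nrow(w$nodes)
  d <- as.matrix(dist(as.matrix(w$nodes[, c("x", "y", "z")])))
  planted <- exp(-d / 50); diag(planted) <- 1
  prof <- fc_distance_profile(planted, w$nodes)
  expect_true(all(vapply(prof, `[[`, numeric(1), "r") < 0))
  nc <- sum(w$nodes$structure == "cortex")
  nb <- n - nc
  expect_equal(nrow(prof$within_cortex$data), choose(nc, 2))
  expect_equal(nrow(prof$within_brainstem$data), choose(nb, 2))
  expect_equal(nrow(prof$cortex_brainstem$data), nc * nb)

  # distance-independent FC: r compatible with 0
  set.seed(4)
  flat <- compute_fc(matrix(rnorm(n * 400), n))
  r0 <- fc_distance_profile(flat, w$nodes)$within_cortex$r
  expect_lt(abs(r0), 0.1)
})

test_that("block comparison matches Welch's t-test and handles degeneracy", {
  nodes <- toy_nodes(3, 3)
  fc <- diag(6)
  fc[1:3, 4:6] <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3)  # A entries
  fc[4:6, 1:3] <- t(fc[1:3, 4:6])
  fc[4, 5] <- fc[5, 4] <- 2; fc[4, 6] <- fc[6, 4] <- 4; fc[5, 6] <- fc[6, 5] <- 6
  res <- compare_fc_blocks(fc, nodes)
  a <- as.numeric(fc[1:3, 4:6]); b <- c(2, 4, 6)
  tt <- t.test(a, b)  # independent Welch implementation
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)

  const <- diag(6); const[upper.tri(const)] <- 0.3
  const[lower.tri(const)] <- t(const)[lower.tri(const)]
  res0 <- compare_fc_blocks(const, nodes)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  sep <- const
  sep[1:3, 4:6] <- 1 + 1e-6 * matrix(seq_len(9), 3)
  sep[4:6, 1:3] <- t(sep[1:3, 4:6])
  expect_lt(compare_fc_blocks(sep, nodes)$p, 1e-6)
})

test_that("split-half reliability meets its contracts", {
  w <- small_world()
  expect_error(split_half_reliability(w$ts[1:5], w$nodes), "even number")

  out <- split_half_reliability(w$ts, w$nodes, n_reps = 12, seed = 2L)
  expect_equal(nrow(out), 12)
  expect_named(out, c("fc", "bs_to_ctx_degree", "ctx_to_bs_degree"))

  # identical subjects: every correlation is exactly 1
  same <- rep(w$ts[1], 4)
  out1 <- split_half_reliability(same, w$nodes, n_reps = 5, seed = 1L)
  expect_equal(as.matrix(out1), matrix(1, 5, 3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # pure-noise subjects share no signal: mean between-half FC correlation ~ 0
  set.seed(6)
  noise <- lapply(1:8, function(s) {
    structure(list(subject_id = paste0("n", s),
                   values = matrix(rnorm(30 * 300), 30), tr = 1),
              class = "subject_ts")
  })
  nn <- toy_nodes(20, 10)
  out0 <- split_half_reliability(noise, nn, n_reps = 40, seed = 3L)
  expect_lt(abs(mean(out0$fc)), 0.1)
})
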