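# Signed-modularity community detection with consensus clustering.
#
# Quality function (asymmetric signed modularity): with W = W+ - W-,
# s_i± = row sums, v± = sum_ij w_ij± (= 2 m±), null p±_ij = s_i± s_j± / v±,
#
#   Q(gamma) = (1/v+) sum_ij (w+_ij - gamma p+_ij) delta(s_i, s_j)
#            - (1/(v+ + v-)) sum_ij (w-_ij - gamma p-_ij) delta(s_i, s_j)
#
# over all ordered pairs with zero weight diagonal (the null diagonal terms
# are retained; they are partition-independent). Positive within-community
# weights are rewarded, negative ones penalised, and on an all-positive graph
# Q reduces exactly to Newman-Girvan modularity at resolution gamma.

signed_parts <- function(W) {
  check_symmetric(W, "W")
  W <- W - diag(diag(W))
  Wp <- pmax(W, 0)
  Wn <- pmax(-W, 0)
  sp <- rowSums(Wp)
  sn <- rowSums(Wn)
  vp <- sum(sp)
  vn <- sum(sn)
  if (vp <= 0) stop("graph has no positive weights (m+ = 0)", call. = FALSE)
  list(W = W, Wp = Wp, Wn = Wn, sp = sp, sn = sn, vp = vp, vn = vn)
}

# generalised modularity matrix B such that Q = sum_ij B_ij delta(s_i, s_j)
modularity_matrix <- function(W, gamma) {
  g <- signed_parts(W)
  B <- (g$Wp - gamma * outer(g$sp, g$sp) / g$vp) / g$vp
  if (g$vn > 0) {
    B <- B - (g$Wn - gamma * outer(g$sn, g$sn) / g$vn) / (g$vp + g$vn)
  }
  (B + t(B)) / 2
}

#' Signed modularity of a partition
#'
#' @param W symmetric signed weight matrix (diagonal ignored).
#' @param labels community assignment per node.
#' @param gamma resolution parameter (default 1).
#' @return the quality value Q.
#' @export
signed_quality <- function(W, labels, gamma = 1) {
  if (length(labels) != nrow(W)) {
    stop("partition length does not match graph", call. = FALSE)
  }
  B <- modularity_matrix(W, gamma)
  delta <- outer(labels, labels, `==`)
  sum(B[delta])
}

#' Louvain community detection for signed graphs
#'
#' Greedy two-phase Louvain (local node moves followed by graph aggregation)
#' maximising [signed_quality()]. Node visitation order is reshuffled from the
#' seed each pass; among equal-gain moves a node keeps its current community.
#'
#' @param W symmetric signed weight matrix.
#' @param gamma resolution parameter.
#' @param seed integer seed controlling the visitation order.
#' @return Object of class `stem_partition`: list with `labels` (1..k),
#'   `gamma`, and `quality` (exact [signed_quality()] of the labels).
#' @export
louvain_signed <- function(W, gamma = 1, seed = 1L) {
  B <- modularity_matrix(W, gamma)
  labels <- louvain_matrix_cpp(B, as.integer(seed))
  structure(list(labels = labels, gamma = gamma,
                 quality = signed_quality(W, labels, gamma)),
            class = "stem_partition")
}

partition_labels <- function(p) {
  if (inherits(p, "stem_partition")) p$labels else as.integer(p)
}

pair_counts <- function(l1, l2) {
  k1 <- max(l1); k2 <- max(l2)
  ct <- tabulate((l2 - 1L) * k1 + l1, nbins = k1 * k2)
  ct <- matrix(ct, k1, k2)
  n <- length(l1)
  ch2 <- function(x) x * (x - 1) / 2
  list(n = n, M = ch2(n),
       M1 = sum(ch2(rowSums(ct))), M2 = sum(ch2(colSums(ct))),
       w = sum(ch2(ct)),
       a3 = sum(rowSums(ct)^3), b3 = sum(colSums(ct)^3))
}

#' z-scored Rand index between two partitions
#'
#' The pair-counting Rand statistic w (number of node pairs co-assigned in
#' both partitions) standardised by its mean and variance under the
#' hypergeometric model that fixes both partitions' group sizes
#' (Traud-Kelsic-Mucha-Porter).
#'
#' @param p1,p2 partitions (label vectors or `stem_partition` objects) of
#'   equal length.
#' @return the z value; `NA` (with a warning) when both partitions are the
#'   degenerate single community.
#' @export
zrand_score <- function(p1, p2) {
  l1 <- partition_labels(p1)
  l2 <- partition_labels(p2)
  if (length(l1) != length(l2)) stop("partition lengths differ", call. = FALSE)
  pc <- pair_counts(match(l1, unique(l1)), match(l2, unique(l2)))
  n <- pc$n; M <- pc$M; M1 <- pc$M1; M2 <- pc$M2
  if (M1 == M && M2 == M) {
    warning("both partitions are a single community; z-Rand undefined")
    return(NA_real_)
  }
  mu <- M1 * M2 / M
  C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * pc$a3
  C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * pc$b3
  v <- M / 16 -
    (4 * M1 - 2 * M)^2 * (4 * M2 - 2 * M)^2 / (256 * M^2) +
    C1 * C2 / (16 * n * (n - 1) * (n - 2)) +
    ((4 * M1 - 2 * M)^2 - 4 * C1 - 4 * M) *
      ((4 * M2 - 2 * M)^2 - 4 * C2 - 4 * M) /
      (64 * n * (n - 1) * (n - 2) * (n - 3))
  if (v <= 0) {
    warning("z-Rand variance non-positive; returning NA")
    return(NA_real_)
  }
  (pc$w - mu) / sqrt(v)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions (up to
#' relabelling), ~0 for independent ones.
#'
#' @inheritParams zrand_score
#' @return the ARI value.
#' @export
adjusted_rand_index <- function(p1, p2) {
  l1 <- partition_labels(p1)
  l2 <- partition_labels(p2)
  if (length(l1) != length(l2)) stop("partition lengths differ", call. = FALSE)
  pc <- pair_counts(match(l1, unique(l1)), match(l2, unique(l2)))
  expected <- pc$M1 * pc$M2 / pc$M
  maxw <- (pc$M1 + pc$M2) / 2
  if (maxw == expected) return(1)
  (pc$w - expected) / (maxw - expected)
}

agreement_matrix <- function(label_mat) {
  # label_mat: n_reps x n; returns fraction of runs co-assigning each pair
  n <- ncol(label_mat)
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(label_mat))) {
    l <- label_mat[r, ]
    A <- A + outer(l, l, `==`)
  }
  A <- A / nrow(label_mat)
  diag(A) <- 0
  A
}

#' Consensus partition over repeated Louvain runs
#'
#' Runs [louvain_signed()] `n_reps` times, builds the pairwise co-assignment
#' (agreement) matrix, thresholds it at the mean agreement expected under a
#' permutation null (labels of each run randomly permuted across nodes), and
#' iteratively re-clusters the thresholded agreement matrix (as a positive
#' graph at gamma = 1) until all runs agree. Also summarises partition
#' stability as the mean and variance of the pairwise z-Rand score across the
#' runs.
#'
#' @param W symmetric signed weight matrix.
#' @param gamma resolution parameter.
#' @param n_reps number of Louvain repetitions (default 250).
#' @param seed integer seed.
#' @param n_null label permutations used for the agreement threshold
#'   (default 100).
#' @param max_iter consensus iteration cap (default 100).
#' @return Object of class `consensus_result`: list with `partition`
#'   (`stem_partition`), `n_reps`, `zrand_mean`, `zrand_var`, `n_communities`.
#' @export
consensus_partition <- function(W, gamma = 1, n_reps = 250L, seed = 1L,
                                n_null = 100L, max_iter = 100L) {
  n_reps <- check_count(n_reps, "n_reps", min = 2L)
  n <- nrow(W)
  seeds <- derive_seeds(seed, n_reps + n_null + max_iter * n_reps)
  run_louvain <- function(M, g, sd) louvain_matrix_cpp(M, sd)

  B <- modularity_matrix(W, gamma)
  labels <- t(vapply(seq_len(n_reps),
                     function(r) run_louvain(B, gamma, seeds[r]),
                     integer(n)))

  # pairwise z-Rand stability across runs
  zr <- c()
  pairs <- utils::combn(n_reps, 2)
  zr <- vapply(seq_len(ncol(pairs)), function(j) {
    suppressWarnings(zrand_score(labels[pairs[1, j], ], labels[pairs[2, j], ]))
  }, numeric(1))
  zrand_mean <- mean(zr, na.rm = TRUE)
  zrand_var <- var(zr[!is.na(zr)])
  if (length(zr[!is.na(zr)]) < 2) zrand_var <- 0

  null_threshold <- function(label_mat, sds) {
    acc <- 0
    for (i in seq_along(sds)) {
      r <- ((i - 1L) %% nrow(label_mat)) + 1L
      perm <- with_seed(sds[i], sample(label_mat[r, ]))
      acc <- acc + mean(outer(perm, perm, `==`)[upper.tri(diag(length(perm)))])
    }
    acc / length(sds)
  }

  cur <- labels
  iter <- 0L
  seed_pos <- n_reps
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("consensus failed to converge in ", max_iter,
           " iterations (", nrow(unique(cur)), " distinct partitions remain)",
           call. = FALSE)
    }
    if (nrow(unique(cur)) == 1L) break
    A <- agreement_matrix(cur)
    tau <- null_threshold(cur, seeds[seed_pos + seq_len(n_null)])
    A[A <= tau] <- 0
    if (all(A == 0)) {
      # no above-chance agreement at all: everything in one community
      cur <- matrix(1L, 1L, n)
      break
    }
    BA <- modularity_matrix(A, 1)
    cur <- t(vapply(seq_len(n_reps), function(r) {
      run_louvain(BA, 1, seeds[seed_pos + n_null + (iter - 1L) * n_reps + r])
    }, integer(n)))
  }
  final <- cur[1, ]
  part <- structure(list(labels = final, gamma = gamma,
                         quality = signed_quality(W, final, gamma)),
                    class = "stem_partition")
  structure(list(partition = part, n_reps = n_reps,
                 zrand_mean = zrand_mean, zrand_var = zrand_var,
                 n_communities = length(unique(final))),
            class = "consensus_result")
}

#' Resolution sweep of consensus community detection
#'
#' One [consensus_partition()] per resolution value (default: the 60-value
#' grid 0.1, 0.2, ..., 6.0), tabulating the number of communities and the
#' z-Rand stability summaries. Stable scales show a high z-Rand mean and a low
#' variance.
#'
#' @param W symmetric signed weight matrix.
#' @param gammas resolution grid.
#' @param n_reps Louvain repetitions per resolution (default 250).
#' @param seed integer seed.
#' @param ... passed to [consensus_partition()].
#' @return data frame (gamma, n_communities, zrand_mean, zrand_var) with the
#'   per-gamma `consensus_result`s in attribute `"results"`.
#' @export
gamma_sweep <- function(W, gammas = seq(0.1, 6.0, by = 0.1), n_reps = 250L,
                        seed = 1L, ...) {
  if (length(gammas) == 0) stop("`gammas` is empty", call. = FALSE)
  seeds <- derive_seeds(seed, length(gammas))
  results <- lapply(seq_along(gammas), function(i) {
    consensus_partition(W, gamma = gammas[i], n_reps = n_reps,
                        seed = seeds[i], ...)
  })
  out <- data.frame(
    gamma = gammas,
    n_communities = vapply(results, `[[`, integer(1), "n_communities"),
    zrand_mean = vapply(results, `[[`, numeric(1), "zrand_mean"),
    zrand_var = vapply(results, `[[`, numeric(1), "zrand_var")
  )
  attr(out, "results") <- results
  out
}

#' Community-wise cortical degree maps
#'
#' For each brainstem community, the sum of every cortical region's raw FC
#' with the nuclei of that community: how each community projects onto the
#' cortex. Maps over all communities sum node-wise to the full
#' cortex-to-brainstem weighted degree.
#'
#' @param fc group-level node x node connectivity matrix.
#' @param partition brainstem partition (label vector or `stem_partition`).
#' @param nodes node table.
#' @return n_cortex x n_communities matrix, one column per community.
#' @export
community_degree_maps <- function(fc, partition, nodes) {
  check_node_table(nodes)
  labels <- partition_labels(partition)
  ic <- node_indices(nodes, "cortex")
  ib <- node_indices(nodes, "brainstem")
  if (length(labels) != length(ib)) {
    stop("partition must cover all brainstem nodes", call. = FALSE)
  }
  coms <- sort(unique(labels))
  if (any(tabulate(match(labels, coms)) == 0)) {
    stop("empty community", call. = FALSE)
  }
  out <- vapply(coms, function(c) {
    weighted_degree(fc, seed_set = ib[labels == c], target_set = ic)
  }, numeric(length(ic)))
  colnames(out) <- sprintf("community%d", coms)
  rownames(out) <- nodes$name[ic]
  out
}
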