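#' Diffusion map embedding of a similarity matrix
#'
#' Field-standard gradient recipe: each row of the similarity matrix is
#' sparsified to its strongest (1 - sparsity) fraction of entries, an affinity
#' matrix is built from the cosine similarity of the sparsified rows (clamped
#' at zero), the affinity receives anisotropic-diffusion normalisation with
#' exponent `alpha`, and the stationary Markov operator on the result is
#' eigendecomposed. Component 1 of the returned scores is the first
#' non-trivial eigenvector ("the gradient"), scaled by its eigenvalue.
#'
#' The decomposition uses the symmetric conjugate of the Markov operator, so
#' results are deterministic up to component sign; sign is canonicalised so
#' that the node with the largest absolute score is positive.
#'
#' @param sim symmetric similarity matrix.
#' @param n_components number of non-trivial components returned (default 10).
#' @param sparsity per-row fraction of entries zeroed before the affinity
#'   (default 0.9, i.e. keep the top 10 percent).
#' @param alpha anisotropic normalisation exponent (default 0.5).
#' @return Object of class `gradient_result`: list with `scores` (node x
#'   component), `eigenvalues` (descending, non-trivial), and `params`.
#' @export
diffusion_embedding <- function(sim, n_components = 10L, sparsity = 0.9,
                                alpha = 0.5) {
  check_symmetric(sim, "sim")
  n <- nrow(sim)
  n_components <- check_count(n_components, "n_components")
  if (sparsity < 0 || sparsity >= 1) {
    stop("`sparsity` must be in [0, 1)", call. = FALSE)
  }

  L <- sim
  for (i in seq_len(n)) {
    thr <- quantile(L[i, ], probs = sparsity, type = 7)
    L[i, L[i, ] < thr] <- 0
  }
  nrm <- sqrt(rowSums(L^2))
  if (any(nrm == 0)) stop("a sparsified row is all zero", call. = FALSE)
  A <- tcrossprod(L / nrm)
  A[A < 0] <- 0
  diag(A) <- 1

  comp <- connected_components(A > 0)
  if (max(comp) > 1) {
    stop("affinity graph is disconnected (", max(comp), " components)",
         call. = FALSE)
  }

  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  dw <- rowSums(W)
  S <- W / outer(sqrt(dw), sqrt(dw))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  # Markov eigenvectors, normalised so the trivial component is constant 1
  triv <- e$vectors[, 1] / sqrt(dw)
  phi <- (e$vectors / sqrt(dw)) / mean(triv)

  k <- min(n_components, n - 1L)
  idx <- 1L + seq_len(k)
  scores <- phi[, idx, drop = FALSE] * rep(lam[idx], each = n)
  # sign convention: node with largest |score| is positive
  for (j in seq_len(ncol(scores))) {
    m <- which.max(abs(scores[, j]))
    if (scores[m, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(sim)
  colnames(scores) <- sprintf("gradient%d", seq_len(k))

  structure(list(scores = scores, eigenvalues = lam[idx],
                 params = list(n_components = k, sparsity = sparsity,
                               alpha = alpha)),
            class = "gradient_result")
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

gradient_scores <- function(g, component = 1L) {
  if (inherits(g, "gradient_result")) g$scores[, component] else as.numeric(g)
}

#' Align a gradient with a reference and compare
#'
#' Diffusion-map components have arbitrary sign; this flips the gradient, if
#' needed, so that it correlates positively with the reference map, then
#' reports the Pearson correlation with a parametric or spin p-value.
#'
#' @param g1 a `gradient_result` (its first component is used unless
#'   `component` says otherwise) or a numeric score vector.
#' @param reference a second gradient or annotation map (numeric vector or
#'   `gradient_result`).
#' @param spins optional `spin_ensemble` for a spin p-value (the gradient is
#'   the rotated map).
#' @param component component of `g1` to use (default 1).
#' @return list with `r`, `p`, `p_type`, `flipped`, and the sign-aligned
#'   `scores`.
#' @export
align_and_compare <- function(g1, reference, spins = NULL, component = 1L) {
  x <- gradient_scores(g1, component)
  y <- gradient_scores(reference, 1L)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  flipped <- cor(x, y) < 0
  if (flipped) x <- -x
  res <- correlate_with_map(x, y, method = "pearson", spins = spins)
  c(res[c("r", "p", "p_type")], list(flipped = flipped, scores = x))
}

#' Brainstem degree of the two gradient poles
#'
#' Sums each brainstem nucleus' FC with all negatively-scored cortical regions
#' (negative pole) and, separately, with all positively-scored regions
#' (positive pole) of a cortical gradient. Exact zero scores are excluded and
#' counted.
#'
#' @param fc group-level node x node connectivity matrix.
#' @param gradient `gradient_result` or per-cortical-node score vector.
#' @param nodes node table.
#' @return list with `negative` and `positive` brainstem degree maps and
#'   `n_zero` (number of zero-scored cortical nodes excluded).
#' @export
pole_degree <- function(fc, gradient, nodes) {
  check_node_table(nodes)
  scores <- gradient_scores(gradient, 1L)
  ic <- node_indices(nodes, "cortex")
  ib <- node_indices(nodes, "brainstem")
  if (length(scores) != length(ic)) {
    stop("gradient must be defined on the cortical nodes", call. = FALSE)
  }
  neg <- ic[scores < 0]
  pos <- ic[scores > 0]
  n_zero <- sum(scores == 0)
  if (n_zero > 0) message(n_zero, " zero-scored cortical node(s) excluded")
  if (length(neg) == 0) stop("no negatively-scored cortical nodes", call. = FALSE)
  if (length(pos) == 0) stop("no positively-scored cortical nodes", call. = FALSE)
  list(negative = weighted_degree(fc, seed_set = neg, target_set = ib),
       positive = weighted_degree(fc, seed_set = pos, target_set = ib),
       n_zero = n_zero)
}
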