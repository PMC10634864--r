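# Independent oracles and shared fixtures, kept free of the package's own
# computation paths wherever they are used as a cross-check.

# all set partitions of n items as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  out
}

# all permutations of a vector (n <= 8)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# signed quality evaluated directly from its definition by double loop
brute_signed_quality <- function(W, labels, gamma) {
  n <- nrow(W)
  Wp <- pmax(W, 0); diag(Wp) <- 0
  Wn <- pmax(-W, 0); diag(Wn) <- 0
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  mp <- sum(Wp) / 2; mn <- sum(Wn) / 2
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] != labels[j]) next
      q <- q + (Wp[i, j] - gamma * sp[i] * sp[j] / (2 * mp)) / (2 * mp)
      if (mn > 0) {
        q <- q - (Wn[i, j] - gamma * sn[i] * sn[j] / (2 * mn)) / (2 * mp + 2 * mn)
      }
    }
  }
  q
}

random_signed_graph <- function(n) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2, -1, 1)
  W + t(W)
}

# Moran's I with inverse-distance weights
moran_i <- function(x, xyz) {
  d <- as.matrix(dist(xyz))
  w <- 1 / d
  diag(w) <- 0
  xc <- x - mean(x)
  length(x) / sum(w) * sum(w * outer(xc, xc)) / sum(xc^2)
}

# minimal valid node table for toy fixtures (nc cortex then nb brainstem)
toy_nodes <- function(nc, nb, coords = NULL) {
  n <- nc + nb
  if (is.null(coords)) coords <- matrix(seq_len(3 * n), n, 3)
  data.frame(
    node_id = 0:(n - 1L),
    name = c(sprintf("c%02d", seq_len(nc)), sprintf("b%02d", seq_len(nb))),
    structure = c(rep("cortex", nc), rep("brainstem", nb)),
    hemisphere = rep(c("L", "R"), length.out = n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    size_voxels = rep(100L, n),
    stringsAsFactors = FALSE
  )
}

# memoised small synthetic world shared by several test files
.world_cache <- new.env(parent = emptyenv())
small_world <- function() {
  if (is.null(.world_cache$w)) {
    spec <- synth_spec(n_cortex = 80, n_brainstem = 20, n_subjects = 6,
                       n_timepoints = 240, seed = 3L)
    geom <- make_geometry(spec)
    ts <- sample_timeseries(spec, geom)
    fc <- group_average(lapply(ts, compute_fc))
    .world_cache$w <- list(spec = spec, geom = geom, nodes = geom$nodes,
                           ts = ts, fc = fc)
  }
  .world_cache$w
}

# lm-based Shapley enumeration dominance oracle for small p
dominance_oracle <- function(y, X) {
  p <- ncol(X); n <- length(y)
  adjr2 <- function(S) {
    if (length(S) == 0) return(0)
    r2 <- summary(lm(y ~ X[, S, drop = FALSE]))$r.squared
    1 - (1 - r2) * (n - 1) / (n - length(S) - 1)
  }
  vapply(seq_len(p), function(i) {
    others <- setdiff(seq_len(p), i)
    mean(vapply(0:(p - 1), function(k) {
      Ss <- if (k == 0) list(integer(0)) else
        lapply(asplit(combn(others, k), 2), as.integer)
      mean(vapply(Ss, function(S) adjr2(c(S, i)) - adjr2(S), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
}
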