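# Spatial autocorrelation-preserving "spin" permutations for cortical maps.

# uniform random rotation in SO(3): QR of a Gaussian matrix with sign fix
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qrd <- qr(m)
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a spin ensemble by random sphere rotations
#'
#' For each spin, a uniform random 3D rotation is applied to the
#' left-hemisphere spherical parcel coordinates and its x-mirrored conjugate
#' to the right hemisphere; within each hemisphere, rotated parcels are
#' reassigned to original parcels by the one-to-one linear assignment
#' (Hungarian) minimising total Euclidean distance. Permutations never cross
#' hemispheres, so each spin is a hemisphere-closed bijection of the cortical
#' nodes.
#'
#' @param geometry a `stem_geometry` or a node table containing cortical
#'   sphere coordinates (`sx`, `sy`, `sz`) and `hemisphere`.
#' @param n_spins number of rotations (default 10000).
#' @param seed integer seed.
#' @return Object of class `spin_ensemble`: list with `permutations`
#'   (n_spins x n_cortex integer matrix; row k maps original slot i to source
#'   node `permutations[k, i]`), `n_spins`, `hemisphere`, `seed`.
#' @export
generate_rotations <- function(geometry, n_spins = 10000L, seed = 1L) {
  n_spins <- check_count(n_spins, "n_spins")
  nodes <- if (inherits(geometry, "stem_geometry")) geometry$nodes else geometry
  ic <- which(nodes$structure == "cortex")
  if (length(ic) == 0) stop("no cortical nodes", call. = FALSE)
  if (!all(c("sx", "sy", "sz") %in% names(nodes))) {
    stop("node table has no sphere coordinates (sx, sy, sz)", call. = FALSE)
  }
  sph <- as.matrix(nodes[ic, c("sx", "sy", "sz")])
  hemi <- nodes$hemisphere[ic]
  if (anyNA(sph)) stop("missing sphere coordinates", call. = FALSE)
  il <- which(hemi == "L")
  ir <- which(hemi == "R")
  if (length(il) == 0 || length(ir) == 0) {
    stop("both hemispheres must have cortical nodes", call. = FALSE)
  }
  xl <- sph[il, , drop = FALSE]
  xr <- sph[ir, , drop = FALSE]
  mirror <- diag(c(-1, 1, 1))

  perms <- with_seed(seed, {
    out <- matrix(NA_integer_, n_spins, length(ic))
    for (k in seq_len(n_spins)) {
      q <- random_rotation()
      qr_ <- mirror %*% q %*% mirror
      rot_l <- xl %*% t(q)
      rot_r <- xr %*% t(qr_)
      # cost[i, j] = distance from original parcel i to rotated parcel j
      cl <- sqrt(pmax(outer(rowSums(xl^2), rowSums(rot_l^2), `+`) -
                        2 * tcrossprod(xl, rot_l), 0))
      cr <- sqrt(pmax(outer(rowSums(xr^2), rowSums(rot_r^2), `+`) -
                        2 * tcrossprod(xr, rot_r), 0))
      out[k, il] <- il[solve_assignment_cpp(cl)]
      out[k, ir] <- ir[solve_assignment_cpp(cr)]
    }
    out
  })
  structure(list(permutations = perms, n_spins = n_spins,
                 hemisphere = hemi, seed = as.integer(seed)),
            class = "spin_ensemble")
}

#' Spin-test p-value for a map association
#'
#' Builds the null distribution of the statistic by permuting the first map
#' with each spin of the ensemble and recomputing its correlation with the
#' second map, then reports the permutation p-value with the add-one
#' estimator p = (1 + #exceedances) / (1 + n_spins), which is never exactly
#' zero (floor 1/(n_spins + 1)).
#'
#' @param observed_stat the observed correlation; must equal
#'   `cor(map_a, map_b, method)` to 1e-10 (guards against mixed-up inputs).
#' @param map_a the map that is rotated under the null.
#' @param map_b the fixed map.
#' @param ensemble a [generate_rotations()] result over the same cortical
#'   nodes.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param tails `"two"` (default) or `"one"` (same sign as the observed
#'   statistic).
#' @return list with `p` and `null` (length n_spins).
#' @export
spin_pvalue <- function(observed_stat, map_a, map_b, ensemble,
                        method = c("pearson", "spearman"),
                        tails = c("two", "one")) {
  method <- match.arg(method)
  tails <- match.arg(tails)
  stopifnot(inherits(ensemble, "spin_ensemble"))
  perms <- ensemble$permutations
  if (length(map_a) != ncol(perms) || length(map_b) != ncol(perms)) {
    stop("maps are not defined on the ensemble's nodes", call. = FALSE)
  }
  r_obs <- cor(map_a, map_b, method = method)
  if (!is.finite(observed_stat) || abs(observed_stat - r_obs) > 1e-10) {
    stop("`observed_stat` does not match cor(map_a, map_b); ",
         "check the argument order", call. = FALSE)
  }
  if (method == "spearman") {
    map_b <- rank(map_b)
  }
  # all permuted copies of map_a at once; one BLAS call for the null
  A <- matrix(map_a[t(perms)], nrow = ncol(perms))
  if (method == "spearman") A <- apply(A, 2, rank)
  null <- as.numeric(cor(A, map_b))
  n <- ensemble$n_spins
  exceed <- if (tails == "two") {
    sum(abs(null) >= abs(observed_stat))
  } else {
    if (observed_stat >= 0) sum(null >= observed_stat)
    else sum(null <= observed_stat)
  }
  list(p = (1 + exceed) / (1 + n), null = null)
}
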