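#' Specification for the synthetic brainstem-cortex world
#'
#' Bundles every parameter of the latent-factor generator: node counts, scan
#' layout (subjects, concatenated runs, TR), the planted structure (a global
#' "weighted degree" factor, one factor per brainstem community coupled to a
#' cortical network, and a signed cortical gradient factor), and map smoothing.
#'
#' The implied node covariance is \eqn{\Sigma = L \Lambda L' + \psi^2 I} with
#' one column of \eqn{L} per latent factor. Column 1 carries the nonnegative
#' `global_loading` on every node and induces the dominant weighted-degree
#' pattern. Columns 2..(k+1) carry community factors: brainstem nodes of
#' community c load 1, and the cortex loads a smooth Gaussian bump (peak
#' `cortical_coupling`, width `community_bump_width` in gradient units)
#' centred on the coupled network's position along the planted gradient. The
#' last column is the gradient factor with signed cortical loadings spanning
#' both poles and a low-amplitude brainstem ramp
#' (`gradient_loading_brainstem`) so the gradient is expressed in
#' cortex-brainstem connectivity and can be recovered downstream.
#'
#' Cortical network labels default to contiguous blocks along the planted
#' gradient, mirroring the ordering of intrinsic networks along the
#' unimodal-transmodal axis.
#'
#' @param n_cortex,n_brainstem node counts (defaults 400 and 58).
#' @param n_subjects number of subjects (default 20).
#' @param n_timepoints total volumes per subject (default 630, three
#'   concatenated 210-volume runs).
#' @param n_runs number of concatenated runs (default 3).
#' @param tr sampling interval in seconds (default 2.5).
#' @param n_communities number of planted brainstem communities (default 5).
#' @param community_labels integer community per brainstem node (default
#'   round-robin so every community interleaves the nucleus ordering).
#' @param cortical_network_labels integer network per cortical node, coupled
#'   1:1 to brainstem communities.
#' @param global_loading nonnegative per-node weight of the shared factor
#'   (default a fixed low-discrepancy sequence in [0.6, 1.4)).
#' @param gradient_loading signed per-cortical-node weight of the planted
#'   gradient (default an even ramp over [-1, 1]).
#' @param gradient_loading_brainstem signed per-brainstem-node weight of the
#'   gradient factor (default an even ramp over [-0.4, 0.4]).
#' @param cortical_coupling peak loading of a community factor on the cortex
#'   (default 1.0).
#' @param community_bump_width width (in gradient units) of the Gaussian
#'   cortical coupling profile of each community factor (default 0.1).
#' @param factor_sd standard deviation per latent factor, ordered (global,
#'   communities..., gradient).
#' @param noise_sd independent noise standard deviation (default 1).
#' @param smoothing_scale mm, spatial autocorrelation scale for surrogate maps.
#' @param seed integer master seed.
#' @return An object of class `synth_spec` (a validated list).
#' @export
synth_spec <- function(n_cortex = 400L,
                       n_brainstem = 58L,
                       n_subjects = 20L,
                       n_timepoints = 630L,
                       n_runs = 3L,
                       tr = 2.5,
                       n_communities = 5L,
                       community_labels = NULL,
                       cortical_network_labels = NULL,
                       global_loading = NULL,
                       gradient_loading = NULL,
                       gradient_loading_brainstem = NULL,
                       cortical_coupling = 1.0,
                       community_bump_width = 0.1,
                       factor_sd = NULL,
                       noise_sd = 1,
                       smoothing_scale = 10,
                       seed = 1L) {
  n_cortex <- check_count(n_cortex, "n_cortex")
  n_brainstem <- check_count(n_brainstem, "n_brainstem")
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2L)
  n_runs <- check_count(n_runs, "n_runs")
  n_communities <- check_count(n_communities, "n_communities")
  if (n_communities > n_brainstem) {
    stop("`n_communities` cannot exceed `n_brainstem`", call. = FALSE)
  }
  if (!is.numeric(tr) || tr <= 0) stop("`tr` must be positive", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be positive", call. = FALSE)
  }
  if (!is.numeric(smoothing_scale) || smoothing_scale <= 0) {
    stop("`smoothing_scale` must be positive", call. = FALSE)
  }

  if (is.null(community_labels)) {
    community_labels <- ((seq_len(n_brainstem) - 1L) %% n_communities) + 1L
  }
  community_labels <- as.integer(community_labels)
  if (length(community_labels) != n_brainstem) {
    stop("`community_labels` must have length n_brainstem", call. = FALSE)
  }
  if (length(unique(community_labels)) != n_communities ||
      !all(sort(unique(community_labels)) == seq_len(n_communities))) {
    stop("`community_labels` must use exactly 1..n_communities", call. = FALSE)
  }

  if (is.null(gradient_loading)) {
    gradient_loading <- seq(-1, 1, length.out = n_cortex)
  }
  if (length(gradient_loading) != n_cortex) {
    stop("`gradient_loading` must have length n_cortex", call. = FALSE)
  }
  if (is.null(gradient_loading_brainstem)) {
    gradient_loading_brainstem <- seq(-0.2, 0.2, length.out = n_brainstem)
  }
  if (length(gradient_loading_brainstem) != n_brainstem) {
    stop("`gradient_loading_brainstem` must have length n_brainstem",
         call. = FALSE)
  }

  if (is.null(cortical_network_labels)) {
    # contiguous blocks along the gradient ordering
    ord <- rank(gradient_loading, ties.method = "first")
    cortical_network_labels <-
      as.integer(ceiling(ord / (n_cortex / n_communities)))
    cortical_network_labels <- pmin(cortical_network_labels, n_communities)
  }
  cortical_network_labels <- as.integer(cortical_network_labels)
  if (length(cortical_network_labels) != n_cortex) {
    stop("`cortical_network_labels` must have length n_cortex", call. = FALSE)
  }
  if (!all(cortical_network_labels %in% seq_len(n_communities))) {
    stop("`cortical_network_labels` must be in 1..n_communities", call. = FALSE)
  }

  n_nodes <- n_cortex + n_brainstem
  if (is.null(global_loading)) {
    phi <- (sqrt(5) - 1) / 2
    global_loading <- 0.6 + 0.8 * ((seq_len(n_nodes) * phi) %% 1)
  }
  if (length(global_loading) != n_nodes) {
    stop("`global_loading` must have length n_cortex + n_brainstem",
         call. = FALSE)
  }
  if (any(global_loading < 0)) {
    stop("`global_loading` must be nonnegative", call. = FALSE)
  }

  if (is.null(factor_sd)) {
    factor_sd <- c(1.0, rep(1.0, n_communities), 0.8)
  }
  if (length(factor_sd) != n_communities + 2L || any(factor_sd < 0)) {
    stop("`factor_sd` must be nonnegative with length n_communities + 2",
         call. = FALSE)
  }

  spec <- list(
    n_cortex = n_cortex, n_brainstem = n_brainstem, n_nodes = n_nodes,
    n_subjects = n_subjects, n_timepoints = n_timepoints, n_runs = n_runs,
    tr = tr, n_communities = n_communities,
    community_labels = community_labels,
    cortical_network_labels = cortical_network_labels,
    global_loading = as.numeric(global_loading),
    gradient_loading = as.numeric(gradient_loading),
    gradient_loading_brainstem = as.numeric(gradient_loading_brainstem),
    cortical_coupling = cortical_coupling,
    community_bump_width = community_bump_width,
    factor_sd = as.numeric(factor_sd), noise_sd = noise_sd,
    smoothing_scale = smoothing_scale, seed = as.integer(seed)
  )
  class(spec) <- "synth_spec"
  spec
}

# factor-loading matrix L (n_nodes x (n_communities + 2))
loading_matrix <- function(spec) {
  n <- spec$n_nodes
  k <- spec$n_communities
  L <- matrix(0, n, k + 2L)
  ic <- seq_len(spec$n_cortex)
  ib <- spec$n_cortex + seq_len(spec$n_brainstem)
  L[, 1L] <- spec$global_loading
  g <- spec$gradient_loading
  w <- spec$community_bump_width
  for (c in seq_len(k)) {
    L[ib[spec$community_labels == c], c + 1L] <- 1
    # each community's cortical coupling is a smooth bump along the planted
    # gradient, centred on its coupled network: cortical profiles then vary
    # smoothly along the gradient (so the first cortical similarity gradient
    # is the planted one) while same-community nuclei still share one
    # distinctive cortical pattern
    ctr <- mean(g[spec$cortical_network_labels == c])
    L[ic, c + 1L] <- spec$cortical_coupling * exp(-(g - ctr)^2 / (2 * w^2))
  }
  L[ic, k + 2L] <- spec$gradient_loading
  L[ib, k + 2L] <- spec$gradient_loading_brainstem
  L
}

#' Implied node covariance of a synthetic specification
#'
#' @param spec a [synth_spec()].
#' @return The n x n covariance \eqn{L \Lambda L' + \psi^2 I}.
#' @export
implied_covariance <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  L <- loading_matrix(spec)
  S <- L %*% (spec$factor_sd^2 * t(L))
  diag(S) <- diag(S) + spec$noise_sd^2
  S
}

#' Generate node geometry and the canonical node table
#'
#' Cortical nodes are placed quasi-uniformly (a golden-angle lattice plus
#' seeded jitter) on the two hemispheric halves of a unit sphere, mirrored
#' across the midline; brainstem nodes form a compact inferior cluster of
#' centroids and carry no sphere coordinates. The returned node table defines
#' the canonical order: cortex first (alternating L/R so both hemispheres span
#' the planted gradient), then brainstem.
#'
#' @param spec a [synth_spec()].
#' @return An object of class `stem_geometry`: list with `nodes` (the node
#'   table data frame), `sphere_xyz` (n_cortex x 3 unit-sphere coordinates) and
#'   `centroid_xyz` (n_nodes x 3, mm).
#' @export
make_geometry <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  nc <- spec$n_cortex
  nb <- spec$n_brainstem
  phi <- (sqrt(5) - 1) / 2

  hemi_c <- rep(c("L", "R"), length.out = nc)
  n_l <- sum(hemi_c == "L")
  n_r <- nc - n_l

  # quasi-uniform points on the x < 0 half-sphere
  base_half <- function(n) {
    i <- seq_len(n)
    ct <- (i - 0.5) / n
    st <- sqrt(pmax(0, 1 - ct^2))
    az <- 2 * pi * ((i * phi) %% 1)
    cbind(-ct, st * cos(az), st * sin(az))
  }

  geom <- with_seed(spec$seed, {
    left <- base_half(n_l)
    right <- base_half(max(n_r, 1L))[seq_len(n_r), , drop = FALSE]
    right[, 1] <- -right[, 1]
    jitter_sphere <- function(p, keep_sign) {
      p <- p + matrix(rnorm(length(p), sd = 0.02), nrow(p), 3)
      p <- p / sqrt(rowSums(p^2))
      p[, 1] <- keep_sign * abs(p[, 1])
      p / sqrt(rowSums(p^2))
    }
    left <- jitter_sphere(left, -1)
    right <- jitter_sphere(right, +1)
    sphere <- matrix(NA_real_, nc, 3)
    sphere[hemi_c == "L", ] <- left
    sphere[hemi_c == "R", ] <- right

    bs_centroid <- cbind(rnorm(nb, 0, 4), rnorm(nb, -28, 5), rnorm(nb, -36, 9))
    size_bs <- round(exp(runif(nb, log(10), log(1500))))
    size_ctx <- round(exp(runif(nc, log(200), log(1200))))
    list(sphere = sphere, bs_centroid = bs_centroid,
         size_bs = size_bs, size_ctx = size_ctx)
  })

  centroid <- rbind(geom$sphere * 70, geom$bs_centroid)

  hemi_b <- if (nb <= 8) {
    rep("midline", nb)
  } else {
    c(rep("midline", 8), rep(c("L", "R"), length.out = nb - 8))
  }

  g <- spec$gradient_loading
  lam_lab <- c("idt", "uni", "het", "plmb")
  cyto_lab <- c("ps", "pm", "pss", "assoc1", "assoc2", "lim", "ins")
  bin_along <- function(x, labs) {
    labs[pmin(length(labs),
              ceiling(rank(x, ties.method = "first") / (length(x) / length(labs))))]
  }

  nodes <- data.frame(
    node_id = 0:(spec$n_nodes - 1L),
    name = c(sprintf("ctx_%s_%03d", hemi_c, seq_len(nc)),
             sprintf("bs_%02d", seq_len(nb))),
    structure = c(rep("cortex", nc), rep("brainstem", nb)),
    hemisphere = c(hemi_c, hemi_b),
    x = centroid[, 1], y = centroid[, 2], z = centroid[, 3],
    sx = c(geom$sphere[, 1], rep(NA_real_, nb)),
    sy = c(geom$sphere[, 2], rep(NA_real_, nb)),
    sz = c(geom$sphere[, 3], rep(NA_real_, nb)),
    size_voxels = c(geom$size_ctx, geom$size_bs),
    class_laminar = c(bin_along(g, lam_lab), rep(NA_character_, nb)),
    class_cyto = c(bin_along(g, cyto_lab), rep(NA_character_, nb)),
    network = c(sprintf("net%d", spec$cortical_network_labels),
                rep(NA_character_, nb)),
    stringsAsFactors = FALSE
  )
  check_node_table(nodes)

  structure(list(nodes = nodes, sphere_xyz = geom$sphere,
                 centroid_xyz = centroid),
            class = "stem_geometry")
}

#' Sample multi-subject synthetic time-series
#'
#' Each subject's node x time matrix is a zero-mean Gaussian draw with
#' covariance \eqn{L \Lambda L' + \psi^2 I} (see [synth_spec()]); runs are
#' independent draws concatenated in time. Draws are i.i.d. over time (no
#' temporal autocorrelation), so the effective temporal sample size equals
#' `n_timepoints`.
#'
#' @param spec a [synth_spec()].
#' @param geometry optional [make_geometry()] result; used only to attach node
#'   names to the rows.
#' @return List of `subject_ts` objects: `list(subject_id, values, tr)`.
#' @export
sample_timeseries <- function(spec, geometry = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  L <- loading_matrix(spec)
  ev_min <- spec$noise_sd^2  # Sigma = L Lambda L' + psi^2 I >= psi^2 I
  if (ev_min <= 0) stop("implied covariance is not positive definite", call. = FALSE)
  Lsd <- L * rep(spec$factor_sd, each = nrow(L))
  n <- spec$n_nodes
  run_len <- diff(floor(seq(0, spec$n_timepoints, length.out = spec$n_runs + 1)))
  nm <- if (!is.null(geometry)) geometry$nodes$name else NULL

  seeds <- derive_seeds(spec$seed + 1L, spec$n_subjects)
  lapply(seq_len(spec$n_subjects), function(s) {
    values <- with_seed(seeds[s], {
      runs <- lapply(run_len, function(t_run) {
        z <- matrix(rnorm(ncol(Lsd) * t_run), ncol(Lsd), t_run)
        Lsd %*% z + matrix(rnorm(n * t_run, sd = spec$noise_sd), n, t_run)
      })
      do.call(cbind, runs)
    })
    if (!is.null(nm)) rownames(values) <- nm
    structure(list(subject_id = sprintf("sub-%02d", s),
                   values = values, tr = spec$tr),
              class = "subject_ts")
  })
}

#' Spatially autocorrelated surrogate cortical maps
#'
#' Each map is white noise smoothed with a Gaussian kernel of scale
#' `smoothing_scale` (mm) on chordal distances over the cortical sphere
#' (radius 100 mm), then z-scored. Maps are mutually independent, which makes
#' them suitable surrogates for calibrating the spin test.
#'
#' @param geometry a [make_geometry()] result.
#' @param n_maps number of maps (>= 1).
#' @param smoothing_scale kernel scale in mm (> 0).
#' @param seed integer seed.
#' @return n_cortex x n_maps matrix; each column has mean 0 and unit sample
#'   variance.
#' @export
make_spatial_maps <- function(geometry, n_maps, smoothing_scale, seed = 1L) {
  stopifnot(inherits(geometry, "stem_geometry"))
  n_maps <- check_count(n_maps, "n_maps")
  if (!is.numeric(smoothing_scale) || smoothing_scale <= 0) {
    stop("`smoothing_scale` must be positive", call. = FALSE)
  }
  xyz <- geometry$sphere_xyz * 100
  d <- as.matrix(dist(xyz))
  kern <- exp(-d^2 / (2 * smoothing_scale^2))
  noise <- with_seed(seed, matrix(rnorm(nrow(xyz) * n_maps), nrow(xyz), n_maps))
  maps <- kern %*% noise
  out <- apply(maps, 2, function(x) (x - mean(x)) / sd(x))
  colnames(out) <- sprintf("map%03d", seq_len(n_maps))
  rownames(out) <- geometry$nodes$name[geometry$nodes$structure == "cortex"]
  out
}

#' @importFrom stats dist
NULL
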