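#' Subject-level functional connectivity
#'
#' Pearson correlation between every pair of node time-series; the functional
#' connectome of one subject.
#'
#' @param ts a `subject_ts` (list with `values`: node x time matrix) or a plain
#'   node x time matrix.
#' @return node x node correlation matrix with unit diagonal and attribute
#'   `level = "subject"`.
#' @export
compute_fc <- function(ts) {
  values <- if (inherits(ts, "subject_ts")) ts$values else ts
  if (!is.matrix(values)) stop("time-series must be a matrix", call. = FALSE)
  if (ncol(values) < 3) stop("need at least 3 timepoints", call. = FALSE)
  if (anyNA(values)) stop("time-series contain missing values", call. = FALSE)
  sds <- apply(values, 1, sd)
  if (any(sds == 0)) {
    bad <- rownames(values)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant time-series for node(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  fc <- cor(t(values))
  diag(fc) <- 1
  attr(fc, "level") <- "subject"
  fc
}

#' Group-average connectome
#'
#' Element-wise arithmetic mean of subject correlation matrices (raw r, no
#' Fisher transform).
#'
#' @param fcs list of node x node matrices of identical shape.
#' @return node x node matrix with attribute `level = "group"`.
#' @export
group_average <- function(fcs) {
  if (!is.list(fcs) || length(fcs) < 1) {
    stop("need at least one subject matrix", call. = FALSE)
  }
  dims <- vapply(fcs, dim, integer(2))
  if (any(dims != dims[, 1])) stop("matrices differ in shape", call. = FALSE)
  g <- Reduce(`+`, fcs) / length(fcs)
  attr(g, "level") <- "group"
  g
}

#' Temporal signal-to-noise ratio per node
#'
#' tSNR is the time-series mean divided by its standard deviation (sample sd,
#' n - 1 denominator), computed on series with the mean retained.
#'
#' @param raw_ts `subject_ts` or node x time matrix, mean not removed.
#' @return named numeric vector; nodes with zero sd are `NA` (with a warning).
#' @export
compute_tsnr <- function(raw_ts) {
  values <- if (inherits(raw_ts, "subject_ts")) raw_ts$values else raw_ts
  if (!is.matrix(values)) stop("time-series must be a matrix", call. = FALSE)
  m <- rowMeans(values)
  s <- apply(values, 1, sd)
  out <- m / s
  if (any(s == 0)) {
    warning(sum(s == 0), " node(s) have zero temporal sd; tSNR set to NA")
    out[s == 0] <- NA_real_
  }
  names(out) <- rownames(values)
  out
}

#' Association between brainstem tSNR and parcel size
#'
#' Spearman correlation between brainstem nodes' tSNR and their voxel counts;
#' used to check that small nuclei are not simply noisier.
#'
#' @param tsnr per-node tSNR vector in canonical node order.
#' @param nodes node table with `structure` and `size_voxels`.
#' @return list with `rho`, `p` and `n` (nodes used).
#' @export
size_association <- function(tsnr, nodes) {
  check_node_table(nodes)
  ib <- node_indices(nodes, "brainstem")
  x <- tsnr[ib]
  y <- nodes$size_voxels[ib]
  keep <- !is.na(x)
  if (any(!keep)) warning("excluding ", sum(!keep), " node(s) with undefined tSNR")
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = 0, p = 1, n = length(x)))  # degenerate ranks convention
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = floor_p(ct$p.value), n = length(x))
}

block_masks <- function(nodes) {
  ic <- node_indices(nodes, "cortex")
  ib <- node_indices(nodes, "brainstem")
  n <- nrow(nodes)
  ut <- upper.tri(matrix(0, n, n))
  cc <- matrix(FALSE, n, n); cc[ic, ic] <- TRUE
  bb <- matrix(FALSE, n, n); bb[ib, ib] <- TRUE
  cb <- matrix(FALSE, n, n); cb[ic, ib] <- TRUE; cb[ib, ic] <- TRUE
  list(within_cortex = ut & cc, within_brainstem = ut & bb,
       cortex_brainstem = ut & cb)
}

#' Distance dependence of functional connectivity
#'
#' Correlates FC with Euclidean distance between parcel centroids, separately
#' for within-cortex, within-brainstem, and cortex-brainstem pairs (upper
#' triangle, diagonal excluded).
#'
#' @param fc node x node connectivity matrix.
#' @param nodes node table with centroid columns `x`, `y`, `z`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list per block: data frame of (distance, fc) pairs plus `r` and `p`.
#' @export
fc_distance_profile <- function(fc, nodes, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_node_table(nodes)
  if (anyNA(nodes$x) || anyNA(nodes$y) || anyNA(nodes$z)) {
    stop("node table has missing centroid coordinates", call. = FALSE)
  }
  d <- as.matrix(dist(as.matrix(nodes[, c("x", "y", "z")])))
  masks <- block_masks(nodes)
  lapply(masks, function(msk) {
    dd <- d[msk]; ff <- fc[msk]
    ct <- suppressWarnings(cor.test(dd, ff, method = method))
    list(data = data.frame(distance = dd, fc = ff),
         r = unname(ct$estimate), p = floor_p(ct$p.value))
  })
}

# Welch's unequal-variance t-test, degenerate-safe: equal constant samples
# give t = 0, p = 1 rather than an error.
welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each block needs at least 2 entries", call. = FALSE)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    return(list(t = 0, df = n1 + n2 - 2, p = 1,
                mean_x = mean(x), mean_y = mean(y)))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = floor_p(2 * pt(-abs(t), df)),
       mean_x = mean(x), mean_y = mean(y))
}

#' Compare cortex-brainstem and within-brainstem FC blocks
#'
#' Welch's two-sided unequal-variance t-test on the unique off-diagonal FC
#' values of the cortex-brainstem block versus the within-brainstem block,
#' testing whether the brainstem is more strongly connected with the cortex
#' than with itself.
#'
#' @param fc node x node connectivity matrix.
#' @param nodes node table.
#' @return list with `t`, `df`, `p`, and the two block means.
#' @export
compare_fc_blocks <- function(fc, nodes) {
  check_node_table(nodes)
  masks <- block_masks(nodes)
  welch_t(fc[masks$cortex_brainstem], fc[masks$within_brainstem])
}

#' Split-half reliability of the group connectome
#'
#' Repeatedly splits subjects into two disjoint halves, builds a group-mean
#' connectome per half, and correlates between halves (Pearson): the
#' vectorised unique FC entries, the brainstem-to-cortex weighted-degree
#' vector, and the cortex-to-brainstem weighted-degree vector.
#'
#' @param all_ts list of `subject_ts` (or node x time matrices).
#' @param nodes node table.
#' @param n_reps number of random splits (default 100).
#' @param seed integer seed.
#' @return data frame with `n_reps` rows and columns `fc`, `bs_to_ctx_degree`,
#'   `ctx_to_bs_degree`.
#' @export
split_half_reliability <- function(all_ts, nodes, n_reps = 100L, seed = 1L) {
  n_reps <- check_count(n_reps, "n_reps")
  ns <- length(all_ts)
  if (ns < 4 || ns %% 2 != 0) {
    stop("split-half design requires an even number of subjects >= 4",
         call. = FALSE)
  }
  check_node_table(nodes)
  ic <- node_indices(nodes, "cortex")
  ib <- node_indices(nodes, "brainstem")
  fcs <- lapply(all_ts, compute_fc)
  ut <- upper.tri(fcs[[1]])

  halves <- with_seed(seed, {
    replicate(n_reps, sample.int(ns, ns / 2), simplify = FALSE)
  })
  res <- vapply(halves, function(h1) {
    g1 <- group_average(fcs[h1])
    g2 <- group_average(fcs[-h1])
    c(fc = cor(g1[ut], g2[ut]),
      bs_to_ctx_degree = cor(weighted_degree(g1, ic, ib),
                             weighted_degree(g2, ic, ib)),
      ctx_to_bs_degree = cor(weighted_degree(g1, ib, ic),
                             weighted_degree(g2, ib, ic)))
  }, numeric(3))
  as.data.frame(t(res))
}
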