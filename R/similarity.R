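#' Residualise brainstem-connectivity profiles
#'
#' Every node's 58-length (in general, n_brainstem-length) profile of FC with
#' the brainstem is dominated by one pattern: brainstem-to-cortex weighted
#' degree. This function removes it by ordinary least squares: each profile y
#' is regressed on the fixed degree vector d (with intercept) and replaced by
#' its residuals, which capture how a node is connected with the brainstem
#' above and beyond the dominant pattern.
#'
#' The same fixed d -- computed from the group FC as each nucleus' summed
#' connectivity across all cortical regions -- is used for every profile.
#' Residuals are produced for cortical profiles (the matrix used by all
#' downstream analyses) and, identically defined, for the brainstem nodes' own
#' brainstem profiles.
#'
#' @param fc group-level node x node connectivity matrix.
#' @param nodes node table.
#' @return Object of class `residual_profiles`: list with `values` (n_cortex x
#'   n_brainstem residual matrix), `brainstem_values` (n_brainstem x
#'   n_brainstem), and `regressor` (the degree vector d).
#' @export
residualize_profiles <- function(fc, nodes) {
  check_node_table(nodes)
  ic <- node_indices(nodes, "cortex")
  ib <- node_indices(nodes, "brainstem")
  if (length(ic) == 0 || length(ib) == 0) {
    stop("node table must contain both cortex and brainstem", call. = FALSE)
  }
  d <- weighted_degree(fc, seed_set = ic, target_set = ib)
  if (var(d) == 0) {
    stop("brainstem weighted-degree regressor is constant; regression undefined",
         call. = FALSE)
  }
  dc <- d - mean(d)
  ss <- sum(dc^2)
  resid_block <- function(block) {
    # rows = profiles; per-row OLS on (1, d)
    beta <- (block %*% dc) / ss
    fitted <- rowMeans(block) + beta %*% t(dc)
    out <- block - fitted
    dimnames(out) <- dimnames(block)
    out
  }
  structure(list(
    values = resid_block(fc[ic, ib, drop = FALSE]),
    brainstem_values = resid_block(fc[ib, ib, drop = FALSE]),
    regressor = d
  ), class = "residual_profiles")
}

#' Similarity of residual connectivity profiles
#'
#' Spearman correlation matrix over residual profiles. With
#' `axis = "brainstem"`, every pair of brainstem nuclei is compared through
#' their cortical residual profiles (columns of the residual matrix); with
#' `axis = "cortex"`, every pair of cortical regions is compared through their
#' brainstem residual profiles (rows).
#'
#' @param res a [residualize_profiles()] result (or a plain cortical x
#'   brainstem residual matrix).
#' @param axis `"brainstem"` or `"cortex"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
profile_similarity <- function(res, axis = c("brainstem", "cortex")) {
  axis <- match.arg(axis)
  values <- if (inherits(res, "residual_profiles")) res$values else res
  if (anyNA(values) || any(!is.finite(values))) {
    stop("residual matrix contains non-finite values", call. = FALSE)
  }
  m <- if (axis == "brainstem") values else t(values)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant residual profile(s); Spearman undefined for: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  s <- cor(m, method = "spearman")
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Agreement of node profiles with the dominant degree pattern
#'
#' For every node (cortex and brainstem), the Spearman correlation between its
#' raw brainstem-connectivity profile and the brainstem weighted-degree
#' pattern; the distribution's median summarises how dominant that single
#' pattern is (the study-scale figure reports median r = 0.97).
#'
#' @param fc group-level node x node connectivity matrix.
#' @param nodes node table.
#' @return list with per-node `r` (length n_nodes) and `median_r`.
#' @export
degree_pattern_agreement <- function(fc, nodes) {
  check_node_table(nodes)
  ic <- node_indices(nodes, "cortex")
  ib <- node_indices(nodes, "brainstem")
  d <- weighted_degree(fc, seed_set = ic, target_set = ib)
  profiles <- fc[, ib, drop = FALSE]
  # exclude each brainstem node's self-correlation entry (unit diagonal)
  r <- vapply(seq_len(nrow(fc)), function(i) {
    y <- profiles[i, ]
    if (i %in% ib) {
      j <- match(i, ib)
      cor(y[-j], d[-j], method = "spearman")
    } else {
      cor(y, d, method = "spearman")
    }
  }, numeric(1))
  names(r) <- rownames(fc)
  list(r = r, median_r = median(r))
}

#' @importFrom stats median
NULL
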