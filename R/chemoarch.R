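#' Multiple regression of a cortical map on receptor maps
#'
#' Ordinary least squares with intercept predicting a per-node response (e.g.
#' a community's cortical weighted-degree profile) from a set of annotation
#' maps (e.g. the 18 PET receptor/transporter densities). Response and
#' predictors are z-scored before fitting so coefficients are comparable.
#'
#' @param response per-cortical-node numeric vector.
#' @param predictors node x predictor matrix with named columns.
#' @return list with `r2_adj` (adjusted R-squared), `r2`, and `coefficients`
#'   (standardised, without intercept).
#' @export
fit_receptor_model <- function(response, predictors) {
  if (!is.matrix(predictors)) predictors <- as.matrix(predictors)
  n <- length(response)
  p <- ncol(predictors)
  if (nrow(predictors) != n) stop("length mismatch", call. = FALSE)
  if (n <= p + 1) stop("need n_nodes > n_predictors + 1", call. = FALSE)
  y <- zscore(response)
  X <- zscore(predictors)
  qx <- qr(cbind(1, X))
  if (qx$rank < p + 1) {
    dropped <- colnames(X)[qx$pivot[seq(qx$rank + 1, p + 1)] - 1L]
    stop("rank-deficient design; collinear predictor(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- lm(y ~ X)
  r2 <- summary(fit)$r.squared
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  cf <- coef(fit)[-1]
  names(cf) <- colnames(predictors)
  list(r2_adj = r2_adj, r2 = r2, coefficients = cf)
}

popcount <- function(x) {
  # number of set bits for each value in x (nonnegative integers)
  n <- 0L
  while (any(x > 0)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

#' Dominance analysis (Shapley decomposition of adjusted R-squared)
#'
#' Fits the regression of [fit_receptor_model()] on every non-empty predictor
#' subset (2^p - 1 submodels, solved on precomputed cross-product sufficient
#' statistics rather than raw data) and attributes to each predictor its
#' general (total) dominance: the average, over subset sizes and then over
#' subsets of each size, of the increase in adjusted R-squared when that
#' predictor joins the submodel. With this level-weighted (Shapley) average
#' the per-predictor dominances sum exactly to the full model's adjusted
#' R-squared, and normalising by that total gives each predictor's percent
#' contribution.
#'
#' @param response per-node numeric vector.
#' @param predictors node x predictor matrix with named columns.
#' @param max_p_exhaustive refuse more predictors than this (default 18;
#'   no sampling approximation is silently substituted).
#' @return Object of class `dominance_result`: list with `predictors`,
#'   `total_r2_adj`, `dominance` (per predictor, same units as R-squared) and
#'   `percent_contribution` (proportions summing to 1).
#' @export
dominance_analysis <- function(response, predictors, max_p_exhaustive = 18L) {
  if (!is.matrix(predictors)) predictors <- as.matrix(predictors)
  p <- ncol(predictors)
  n <- length(response)
  if (p > max_p_exhaustive) {
    stop("p = ", p, " exceeds max_p_exhaustive = ", max_p_exhaustive,
         " (exhaustive enumeration only)", call. = FALSE)
  }
  if (nrow(predictors) != n) stop("length mismatch", call. = FALSE)
  if (n <= p + 1) stop("need n_nodes > n_predictors + 1", call. = FALSE)
  nm <- colnames(predictors)
  if (is.null(nm)) nm <- sprintf("x%02d", seq_len(p))

  y <- zscore(response)
  X <- zscore(predictors)
  Rxx <- crossprod(X) / (n - 1)
  rxy <- as.numeric(crossprod(X, y)) / (n - 1)

  r2 <- all_subset_r2_cpp(Rxx, rxy)           # indexed by bitmask, [1] = empty
  masks <- seq_len(2^p) - 1L                  # 0 .. 2^p - 1
  sizes <- popcount(masks)
  # adjusted R2 with the empty model fixed at 0 so telescoping is exact
  adj <- 1 - (1 - r2) * (n - 1) / (n - sizes - 1)
  adj[1] <- 0

  dominance <- numeric(p)
  for (i in seq_len(p)) {
    bit <- 2L^(i - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    delta <- adj[without + bit + 1L] - adj[without + 1L]
    # average within each subset size, then across the p sizes (0..p-1)
    dominance[i] <- mean(tapply(delta, sizes[without + 1L], mean))
  }
  total <- adj[2^p]
  structure(list(predictors = nm, total_r2_adj = total,
                 dominance = setNames(dominance, nm),
                 percent_contribution =
                   if (total != 0) setNames(dominance / total, nm)
                   else setNames(rep(NA_real_, p), nm)),
            class = "dominance_result")
}

#' Canonical receptor/transporter map names
#'
#' The 18 PET-derived neurotransmitter receptor and transporter density maps
#' spanning nine systems (dopamine, norepinephrine, serotonin, acetylcholine,
#' glutamate, GABA, histamine, cannabinoid, opioid).
#'
#' @return character vector of length 18.
#' @export
receptor_map_names <- function() {
  c("D1", "D2", "DAT", "NET", "5-HT1A", "5-HT1B", "5-HT2A", "5-HT4", "5-HT6",
    "5-HTT", "a4b2", "M1", "VAChT", "mGluR5", "GABAA", "H3", "CB1", "MOR")
}
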