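#' Weighted degree over a seed set
#'
#' For every target node, the sum of its (signed, unthresholded) FC with all
#' seed nodes. With cortical seeds and brainstem targets this is
#' brainstem-to-cortex weighted degree (hub strength of each nucleus), and
#' conversely for cortex-to-brainstem degree.
#'
#' @param fc node x node connectivity matrix.
#' @param seed_set,target_set integer or logical node indices; both nonempty.
#' @return numeric vector of length `|target_set|`, named if `fc` has
#'   dimnames.
#' @export
weighted_degree <- function(fc, seed_set, target_set) {
  if (is.logical(seed_set)) seed_set <- which(seed_set)
  if (is.logical(target_set)) target_set <- which(target_set)
  if (length(seed_set) == 0) stop("`seed_set` is empty", call. = FALSE)
  if (length(target_set) == 0) stop("`target_set` is empty", call. = FALSE)
  out <- rowSums(fc[target_set, seed_set, drop = FALSE])
  names(out) <- rownames(fc)[target_set]
  out
}

#' One-way ANOVA of a degree map across node classes
#'
#' Standard fixed-effects one-way ANOVA (F = MS_between / MS_within) of
#' per-node values binned by a categorical label, e.g. cortex-to-brainstem
#' weighted degree across laminar differentiation or cytoarchitectonic
#' classes.
#'
#' @param values per-node numeric vector.
#' @param labels categorical label per node; at least 2 classes with >= 2
#'   members each.
#' @return list with `F`, `p`, `df` (between, within), and a per-class summary
#'   data frame.
#' @export
class_bin_anova <- function(values, labels) {
  keep <- !is.na(labels) & !is.na(values)
  values <- values[keep]
  labels <- factor(labels[keep])
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(counts < 2)) {
    stop("class(es) with fewer than 2 members: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  k <- length(counts)
  n <- length(values)
  grand <- mean(values)
  means <- tapply(values, labels, mean)
  ssb <- sum(counts * (means - grand)^2)
  ssw <- sum((values - means[labels])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- if (msw == 0 && msb == 0) 0 else msb / msw
  list(F = f, p = floor_p(pf(f, k - 1, n - k, lower.tail = FALSE)),
       df = c(between = k - 1, within = n - k),
       summary = data.frame(class = names(counts), n = as.integer(counts),
                            mean = as.numeric(means),
                            sd = as.numeric(tapply(values, labels, sd))))
}

#' Correlate a degree map with an annotation map
#'
#' Pearson or Spearman correlation between two per-node maps, with either a
#' parametric p-value or a spatial-autocorrelation-preserving spin p-value
#' when a [generate_rotations()] ensemble is supplied. The first map is the
#' one rotated under the null.
#'
#' @param map,annot numeric vectors of equal length (cortical nodes).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param spins optional `spin_ensemble` over the same cortical nodes.
#' @param tails `"two"` (default) or `"one"` for the spin test.
#' @return list with `r`, `p`, and `p_type` (`"parametric"` or `"spin"`);
#'   under a spin null also `null` (the null distribution).
#' @export
correlate_with_map <- function(map, annot, method = c("pearson", "spearman"),
                               spins = NULL, tails = c("two", "one")) {
  method <- match.arg(method)
  tails <- match.arg(tails)
  if (length(map) != length(annot)) {
    stop("maps differ in length", call. = FALSE)
  }
  r <- cor(map, annot, method = method)
  if (is.null(spins)) {
    ct <- suppressWarnings(cor.test(map, annot, method = method))
    list(r = r, p = floor_p(ct$p.value), p_type = "parametric")
  } else {
    sp <- spin_pvalue(r, map, annot, spins, method = method, tails = tails)
    list(r = r, p = sp$p, p_type = "spin", null = sp$null)
  }
}

#' Correlate a degree map with a batch of annotation maps
#'
#' Runs [correlate_with_map()] per column and applies Benjamini-Hochberg FDR
#' correction across the batch (the default multiple-comparisons procedure for
#' e.g. the seven MEG maps).
#'
#' @param map per-node numeric vector.
#' @param annots node x map matrix with named columns.
#' @param adjust p-adjustment method passed to [stats::p.adjust()] (default
#'   `"BH"`).
#' @inheritParams correlate_with_map
#' @return data frame with one row per map: `name`, `r`, `p`, `p_adj`.
#' @export
correlate_with_maps <- function(map, annots, method = c("pearson", "spearman"),
                                spins = NULL, adjust = "BH") {
  method <- match.arg(method)
  res <- lapply(seq_len(ncol(annots)), function(j) {
    correlate_with_map(map, annots[, j], method = method, spins = spins)
  })
  out <- data.frame(
    name = colnames(annots),
    r = vapply(res, `[[`, numeric(1), "r"),
    p = vapply(res, `[[`, numeric(1), "p")
  )
  out$p_adj <- p.adjust(out$p, method = adjust)
  out
}

#' Decode a degree map against meta-analytic term maps
#'
#' Pearson correlation of the map with each z-scored term map, ranked in
#' descending order; the top `round(top_fraction * n_terms)` terms (at least
#' one) are flagged — with the canonical 123-term vocabulary and the default
#' fraction of 0.10 that is 12 terms. Ties at the decile boundary are broken
#' by term name for determinism.
#'
#' @param map per-cortical-node numeric vector.
#' @param terms node x term matrix of z-scored term maps with named columns.
#' @param top_fraction fraction of terms to flag (default 0.10).
#' @return data frame (term, r, rank, top) sorted by descending r.
#' @export
decode_terms <- function(map, terms, top_fraction = 0.10) {
  if (!is.matrix(terms) || ncol(terms) < 1) {
    stop("`terms` must be a matrix with at least one column", call. = FALSE)
  }
  if (nrow(terms) != length(map)) stop("length mismatch", call. = FALSE)
  mu <- colMeans(terms)
  sds <- apply(terms, 2, sd)
  if (any(abs(mu) > 1e-6) || any(abs(sds - 1) > 1e-6)) {
    warning("term maps are not z-scored; z-scoring on the fly")
    terms <- zscore(terms)
  }
  nm <- colnames(terms)
  if (is.null(nm)) nm <- sprintf("term%03d", seq_len(ncol(terms)))
  r <- as.numeric(cor(map, terms))
  ord <- order(-r, nm)
  out <- data.frame(term = nm[ord], r = r[ord], rank = seq_along(ord))
  # "top 10%" counting convention: nearest integer, at least one term
  # (123 terms at 0.10 flags 12)
  out$top <- out$rank <= max(1L, round(top_fraction * ncol(terms)))
  out
}
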