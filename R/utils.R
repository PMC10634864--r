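# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# session RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# k reproducible sub-seeds (< 2^31) derived from one master seed
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max, k))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_symmetric <- function(m, name = "matrix", tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop(sprintf("`%s` contains missing or non-finite values", name), call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("`%s` is not symmetric (tolerance %g)", name, tol), call. = FALSE)
  }
  invisible(m)
}

upper_tri <- function(m) m[upper.tri(m, diag = FALSE)]

# column-wise z-scoring with sample (n-1) standard deviation
zscore <- function(x) {
  if (is.matrix(x)) {
    sds <- apply(x, 2, sd)
    if (any(sds == 0)) stop("cannot z-score a constant column", call. = FALSE)
    scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
  } else {
    s <- sd(x)
    if (s == 0) stop("cannot z-score a constant vector", call. = FALSE)
    (x - mean(x)) / s
  }
}

node_indices <- function(nodes, structure) {
  which(nodes$structure == structure)
}

check_node_table <- function(nodes) {
  req <- c("node_id", "name", "structure", "hemisphere")
  miss <- setdiff(req, names(nodes))
  if (length(miss) > 0) {
    stop("node table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(nodes$name)) stop("node names must be unique", call. = FALSE)
  if (!identical(as.integer(nodes$node_id), seq_len(nrow(nodes)) - 1L)) {
    stop("node_id must be contiguous from 0 in canonical row order",
         call. = FALSE)
  }
  invisible(nodes)
}

# Pearson floor convention: exact zeros are reported below machine range
floor_p <- function(p) pmax(p, 1e-300)
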