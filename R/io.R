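# Delimited-text readers and writers for the pipeline's tables and matrices.

#' Write / read a node table
#'
#' Tab-delimited with header; columns follow the canonical layout (node_id,
#' name, structure, hemisphere, x, y, z, sx, sy, sz, size_voxels,
#' class_laminar, class_cyto, network).
#'
#' @param nodes node table data frame.
#' @param path file path.
#' @return `read_node_table` returns the validated data frame.
#' @export
write_node_table <- function(nodes, path) {
  check_node_table(nodes)
  write.table(nodes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_node_table
#' @export
read_node_table <- function(path) {
  nodes <- read.delim(path, stringsAsFactors = FALSE)
  check_node_table(nodes)
  nodes
}

#' Write / read a dense numeric matrix as delimited text
#'
#' Tab-delimited with column-name header; row names (node names) are written
#' as a leading `name` column when present.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix` returns the matrix.
#' @export
write_matrix <- function(m, path) {
  df <- as.data.frame(m)
  if (!is.null(rownames(m))) df <- cbind(name = rownames(m), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  rn <- NULL
  if ("name" %in% names(df)[1]) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  rownames(m) <- rn
  m
}

#' Write a partition as two-column delimited text
#'
#' @param partition `stem_partition` or label vector.
#' @param path file path.
#' @param node_ids optional node identifiers (default 0-based indices).
#' @export
write_partition <- function(partition, path, node_ids = NULL) {
  labels <- partition_labels(partition)
  if (is.null(node_ids)) node_ids <- seq_along(labels) - 1L
  write.table(data.frame(node_id = node_ids, community = labels), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
NULL
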