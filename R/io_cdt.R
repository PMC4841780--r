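## Cluster 3.0 / Java TreeView export: .cdt data table plus .gtr/.atr merge
## trees. Node similarity stored in the tree files is 1 - merge height,
## Cluster 3.0's convention for correlation-based distances.

tree_ids <- function(tree, kind = c("GENE", "ARRY")) {
  kind <- match.arg(kind)
  sprintf("%s%dX", kind, seq_along(tree$labels) - 1L)
}

write_tree_file <- function(tree, path, kind) {
  leaf <- function(i) sprintf("%s%dX", kind, i - 1L)
  node <- function(i) sprintf("NODE%dX", i)
  n <- nrow(tree$merge)
  lines <- character(n)
  for (i in seq_len(n)) {
    a <- tree$merge[i, 1]; b <- tree$merge[i, 2]
    lines[i] <- paste(node(i),
                      if (a < 0) leaf(-a) else node(a),
                      if (b < 0) leaf(-b) else node(b),
                      format(1 - tree$height[i], digits = 10),
                      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export a score matrix with optional trees as .cdt/.gtr/.atr
#'
#' Writes the Cluster 3.0 dialect read by Java TreeView. Rows and columns are
#' emitted in the trees' leaf orders when trees are given, otherwise in input
#' order. Values round-trip through [read_cdt()] to 6 significant figures.
#'
#' @param matrix numeric matrix with row and column names.
#' @param row_tree,col_tree optional clustering results from
#'   [cluster_profiles()] (or any hclust-like list with `merge`, `height`,
#'   `order`, `labels`); leaf labels must be a permutation of the matrix
#'   dimnames.
#' @param path_prefix path without extension; `.cdt` (and `.gtr`/`.atr` when
#'   trees are given) are appended.
#' @return invisibly, the paths written.
#' @export
write_cdt <- function(matrix, row_tree = NULL, col_tree = NULL, path_prefix) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stopf("matrix must have row and column names")
  check_tree <- function(tree, labs, axis) {
    if (!setequal(tree$labels, labs) || length(tree$labels) != length(labs))
      stopf("%s tree leaves do not match matrix %s names", axis, axis)
  }
  ro <- seq_len(nrow(matrix)); co <- seq_len(ncol(matrix))
  if (!is.null(row_tree)) {
    check_tree(row_tree, rownames(matrix), "row")
    ro <- match(row_tree$labels[row_tree$order], rownames(matrix))
  }
  if (!is.null(col_tree)) {
    check_tree(col_tree, colnames(matrix), "col")
    co <- match(col_tree$labels[col_tree$order], colnames(matrix))
  }
  paths <- paste0(path_prefix, ".cdt")
  con <- file(paths[1], "w")
  hdr <- c(if (!is.null(row_tree)) "GID", "UNIQID", "NAME", "GWEIGHT",
           colnames(matrix)[co])
  writeLines(paste(hdr, collapse = "\t"), con)
  pad <- if (is.null(row_tree)) 3L else 4L
  if (!is.null(col_tree))
    writeLines(paste(c("AID", rep("", pad - 1L),
                       sprintf("ARRY%dX", co - 1L)), collapse = "\t"), con)
  writeLines(paste(c("EWEIGHT", rep("", pad - 1L),
                     rep("1", length(co))), collapse = "\t"), con)
  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 7))
  for (i in ro) {
    row <- c(if (!is.null(row_tree)) sprintf("GENE%dX", i - 1L),
             rownames(matrix)[i], rownames(matrix)[i], "1",
             fmt(matrix[i, co]))
    writeLines(paste(row, collapse = "\t"), con)
  }
  close(con)
  if (!is.null(row_tree)) {
    p <- paste0(path_prefix, ".gtr")
    rt <- row_tree; rt$labels <- rownames(matrix)  # GENE ids are matrix order
    rt$merge <- remap_merge(row_tree, rownames(matrix))
    write_tree_file(rt, p, "GENE"); paths <- c(paths, p)
  }
  if (!is.null(col_tree)) {
    p <- paste0(path_prefix, ".atr")
    ct <- col_tree
    ct$merge <- remap_merge(col_tree, colnames(matrix))
    write_tree_file(ct, p, "ARRY"); paths <- c(paths, p)
  }
  invisible(paths)
}

## merge rows reference leaves by the tree's own label order; re-index them
## to the matrix's dimname order so GENE/ARRY ids line up with the cdt.
remap_merge <- function(tree, labs) {
  m <- tree$merge
  neg <- m < 0
  m[neg] <- -match(tree$labels[-m[neg]], labs)
  m
}

#' Read back a .cdt file written by [write_cdt()]
#' @param path the .cdt path.
#' @return numeric matrix with dimnames in file order.
#' @export
read_cdt <- function(path) {
  lines <- readLines(path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- cells[[1]]
  has_gid <- hdr[1] == "GID"
  first_data_col <- if (has_gid) 5L else 4L
  body <- cells[-1]
  body <- body[!vapply(body, function(x) x[1] %in% c("AID", "EWEIGHT"),
                       logical(1))]
  vals <- t(vapply(body, function(x) {
    v <- x[first_data_col:length(hdr)]
    as.numeric(ifelse(v == "", NA, v))
  }, numeric(length(hdr) - first_data_col + 1L)))
  rownames(vals) <- vapply(body, function(x) x[if (has_gid) 2L else 1L], "")
  colnames(vals) <- hdr[first_data_col:length(hdr)]
  vals
}
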