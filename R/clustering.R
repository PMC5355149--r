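#' Linear normalization of a matrix
#'
#' Per-row min-max scaling to [0, 1]: `(x - row_min) / (row_max - row_min)`,
#' the scaling that makes genes with very different overall frequencies
#' comparable across a heatmap row. Constant rows map to all-zeros. A
#' global mode (one min-max over the whole matrix) is available as the
#' configurable alternative.
#'
#' @param matrix Numeric matrix with at least one row and column.
#' @param mode `"row"` (default) or `"global"`.
#' @return Numeric matrix of the same shape with values in [0, 1].
#' @export
linear_normalize <- function(matrix, mode = c("row", "global")) {
  mode <- match.arg(mode)
  m <- unclass(matrix)
  stopifnot(is.matrix(m), nrow(m) >= 1L, ncol(m) >= 1L)
  storage.mode(m) <- "double"
  if (mode == "global") {
    lo <- min(m); hi <- max(m)
    if (hi == lo) return(m * 0)
    return((m - lo) / (hi - lo))
  }
  t(apply(m, 1L, function(row) {
    lo <- min(row); hi <- max(row)
    if (hi == lo) row * 0 else (row - lo) / (hi - lo)
  }))
}

#' Complete-linkage agglomerative clustering of matrix rows
#'
#' Agglomerates rows under complete ("maximum") linkage: the distance
#' between two clusters is the maximum pairwise Euclidean distance between
#' their members. Tie-breaking is deterministic: among equally close
#' cluster pairs, the pair whose lowest original row indices are smallest
#' (compared lexicographically) merges first. Within each merge the subtree
#' containing the lower original row index is placed on the left, fixing
#' the dendrogram and the leaf order.
#'
#' @param matrix Numeric matrix with >= 2 rows; rows are the objects
#'   (genes), columns the features (phenotypes).
#' @param linkage Only `"complete"` is provided.
#' @param metric Only `"euclidean"` is provided.
#' @return A `cluster_tree`, also a valid `hclust` object (`merge`,
#'   `height`, `order`, `labels`), so [stats::cophenetic()],
#'   [stats::cutree()] and plotting work on it.
#' @export
hierarchical_cluster <- function(matrix, linkage = "complete",
                                 metric = "euclidean") {
  linkage <- match.arg(linkage, "complete")
  metric <- match.arg(metric, "euclidean")
  m <- unclass(matrix)
  stopifnot(is.matrix(m))
  n <- nrow(m)
  if (n < 2L) stop("hierarchical clustering needs at least 2 rows")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- as.matrix(stats::dist(m, method = "euclidean"))

  # active clusters: member original indices, hclust code, lowest index,
  # and left-to-right leaf order within the subtree
  members <- lapply(seq_len(n), identity)
  code <- -seq_len(n)
  lowest <- seq_len(n)
  ord <- lapply(seq_len(n), identity)
  active <- rep(TRUE, n + 0L)

  merge <- matrix(0L, nrow = n - 1L, ncol = 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL
    for (ii in seq_len(length(act) - 1L)) {
      for (jj in (ii + 1L):length(act)) {
        i <- act[ii]; j <- act[jj]
        d <- max(D[members[[i]], members[[j]]])
        lo <- sort(c(lowest[i], lowest[j]))
        key <- c(d, lo)
        if (is.null(best) || key_less(key, best$key)) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    # left subtree = the one holding the lower original index
    if (lowest[i] <= lowest[j]) { l <- i; r <- j } else { l <- j; r <- i }
    merge[step, ] <- c(code[l], code[r])
    height[step] <- best$d
    members[[i]] <- c(members[[i]], members[[j]])
    ord[[i]] <- c(ord[[l]], ord[[r]])
    lowest[i] <- min(lowest[i], lowest[j])
    code[i] <- step
    active[j] <- FALSE
  }

  structure(list(merge = merge, height = height,
                 order = ord[[which(active)]], labels = labels,
                 method = "complete", dist.method = "euclidean",
                 call = match.call()),
            class = c("cluster_tree", "hclust"))
}

# lexicographic comparison of (distance, low_index_1, low_index_2) keys
key_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' Left-to-right leaf order of a cluster tree
#'
#' Depth-first leaf sequence; within each merge the subtree containing the
#' lower original row index sits on the left (fixed at tree construction).
#'
#' @param tree A [hierarchical_cluster()] result.
#' @return Character vector of leaf labels, a permutation of the input
#'   row names.
#' @export
leaf_order <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  tree$labels[tree$order]
}

#' Export clustered heatmap data
#'
#' Writes the matrix reordered by [leaf_order()] as TSV (first column
#' `symbol`, then the feature columns in their input order) and the merge
#' list as a sidecar JSON (`<path>.merges.json`) holding `labels` and one
#' `{left, right, height}` record per merge, with hclust coding (negative =
#' leaf index, positive = earlier merge).
#'
#' @param matrix The (typically normalized) matrix the tree was built on.
#' @param tree A [hierarchical_cluster()] over the matrix rows.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_heatmap_data <- function(matrix, tree, path) {
  m <- unclass(matrix)
  ord <- leaf_order(tree)
  stopifnot(setequal(ord, rownames(m)))
  out <- data.frame(symbol = ord, m[ord, , drop = FALSE],
                    check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  merges <- data.frame(left = tree$merge[, 1], right = tree$merge[, 2],
                       height = tree$height)
  jsonlite::write_json(list(labels = tree$labels, merges = merges),
                       paste0(path, ".merges.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
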