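# Hierarchical clustering with uncentered correlation, the classic
# microarray clustergram recipe: distance d = 1 - cosine-form similarity,
# agglomerative average/single/complete linkage, deterministic index-based
# tie-breaks, and a merge list carrying the similarity at each join.

#' Uncentered correlation (cosine similarity)
#'
#' `sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))` — Pearson correlation
#' without mean-centering, so the similarity respects the absolute up/down
#' pattern rather than the shape around each profile's own mean.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Similarity in \[-1, 1\].
#' @export
uncentered_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L) {
    stopf("`x` and `y` must have equal length >= 1")
  }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stopf("zero-norm vector has no uncentered correlation")
  sum(x * y) / (nx * ny)
}

# Pairwise uncentered-correlation distance matrix (1 - similarity).
uncentered_dist <- function(mat) {
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) {
    stopf("all-zero row(s) %s cannot be clustered under uncentered correlation",
          paste(which(norms == 0), collapse = ", "))
  }
  s <- (mat %*% t(mat)) / outer(norms, norms)
  d <- 1 - s
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Agglomerative hierarchical clustering of a matrix's rows
#'
#' Rows (genes, or arrays if the matrix is transposed first) are clustered on
#' distance `1 - uncentered_correlation`. Linkage distances between clusters
#' are over the original pairwise distances (unweighted average, minimum, or
#' maximum). Ties in the minimum-distance pair are broken by the smallest
#' (i, j) cluster-index pair, so results are bit-reproducible.
#'
#' @param mat Numeric matrix, >= 2 rows; row names label the leaves.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @param axis Label recording what the rows are (`"genes"` or `"arrays"`).
#' @return Object of class `cluster_result`: `labels`; `merge` (n-1 x 2
#'   matrix, negative entries = leaves, positive = earlier merges, as in
#'   [stats::hclust()]); `height` (distance at each join) and `similarity`
#'   (`1 - height`); `order` (leaf order, left-to-right tree traversal);
#'   `axis`, `linkage`; and `data`, the input matrix, kept for CDT export.
#' @export
cluster_matrix <- function(mat, linkage = c("average", "single", "complete"),
                           axis = c("genes", "arrays")) {
  linkage <- match.arg(linkage)
  axis <- match.arg(axis)
  if (!is.matrix(mat) || nrow(mat) < 2L) stopf("need a matrix with >= 2 rows")
  n <- nrow(mat)
  labels <- rownames(mat) %||% as.character(seq_len(n))
  d <- uncentered_dist(mat)

  # active clusters: id (hclust convention: -leaf or +merge-step), size,
  # current row in the working distance matrix
  id <- -seq_len(n)
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))  # original row indices per cluster slot

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    # minimum-distance pair among active clusters, smallest (i, j) on ties
    m <- d[act, act, drop = FALSE]
    m[lower.tri(m, diag = TRUE)] <- Inf
    best_d <- min(m)
    cand <- which(m == best_d, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L])[1L], ]
    i <- act[cand[[1L]]]; j <- act[cand[[2L]]]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best_d
    # linkage update against every other active cluster, from original
    # pairwise distances via cluster sizes (exact for the three linkages)
    for (k in setdiff(act, c(i, j))) {
      d[i, k] <- d[k, i] <- switch(linkage,
        average = (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j]),
        single = min(d[i, k], d[j, k]),
        complete = max(d[i, k], d[j, k]))
    }
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }

  order <- tree_leaf_order(merge)
  structure(list(labels = labels, merge = merge, height = height,
                 similarity = 1 - height, order = order, axis = axis,
                 linkage = linkage, data = mat),
            class = "cluster_result")
}

# Left-to-right traversal of the merge matrix (hclust-style leaf order).
tree_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d %s, %s linkage on uncentered correlation\n",
              length(x$labels), x$axis, x$linkage))
  invisible(x)
}

#' Convert a cluster result to a [stats::hclust()] object
#'
#' Convenience for plotting with base dendrogram tools.
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.cluster_result <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$linkage,
                 dist.method = "uncentered correlation", call = match.call()),
            class = "hclust")
}
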