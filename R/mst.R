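# Euclidean minimum spanning tree over the complete graph of map points, and
# clustering by cutting the heaviest tree edges: removing the k-1 largest
# edges leaves k connected components, the clusters. Distances are computed
# exactly over all N(N-1)/2 pairs; at map sizes of a few hundred points there
# is no need for approximate neighbor graphs.

# union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Euclidean minimum spanning tree of a 2D point set
#'
#' Kruskal's algorithm over the complete graph with Euclidean edge weights.
#' Weight ties are broken deterministically in favor of the lexicographically
#' smaller `(i, j)` index pair, so the returned tree is reproducible even on
#' degenerate inputs.
#'
#' @param points Numeric matrix (N x 2, finite coordinates). N >= 1.
#' @return `data.frame` with columns `i`, `j` (1-based point indices,
#'   `i < j`) and `weight`, one row per tree edge (N - 1 rows; empty for
#'   N = 1), ordered by insertion (ascending weight).
#' @export
build_mst <- function(points) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("non-finite coordinate in points")
  n <- nrow(points)
  empty <- data.frame(i = integer(), j = integer(), weight = numeric())
  if (n <= 1L) return(empty)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  w <- sqrt((points[i, 1] - points[j, 1])^2 + (points[i, 2] - points[j, 2])^2)
  ord <- order(w, i, j)
  parent <- uf_new(n)
  keep <- integer(n - 1L)
  m <- 0L
  for (e in ord) {
    ri <- uf_find(parent, i[e]); rj <- uf_find(parent, j[e])
    if (ri != rj) {
      parent[ri] <- rj
      m <- m + 1L
      keep[m] <- e
      if (m == n - 1L) break
    }
  }
  data.frame(i = i[keep], j = j[keep], weight = w[keep])
}

#' Cut the heaviest tree edges to obtain k clusters
#'
#' Removes the `k - 1` largest-weight edges of a spanning tree (ties: the
#' lexicographically smaller index pair is removed first) and labels the
#' resulting connected components. Cluster ids `0 .. k-1` are assigned by
#' descending component size; equally sized components are ordered by their
#' smallest member index.
#'
#' @param tree Edge `data.frame` from [build_mst()].
#' @param k Desired number of clusters, `1 <= k <= N`.
#' @param n Number of points spanned by `tree` (needed explicitly because a
#'   tree on N points has N - 1 edges, and N = 1 has none).
#' @return Object of class `mst_clustering`: `labels` (integer vector,
#'   0-based cluster ids per point), `k`, `cut_edges` (the removed edges,
#'   heaviest first), `mst_total_weight`.
#' @export
cut_to_k <- function(tree, k, n = nrow(tree) + 1L) {
  stopifnot(is.data.frame(tree))
  if (k < 1 || k > n) stop("k must be between 1 and the number of points")
  ord <- order(-tree$weight, tree$i, tree$j)
  cut <- utils::head(ord, k - 1L)
  kept <- tree[setdiff(seq_len(nrow(tree)), cut), , drop = FALSE]
  parent <- uf_new(n)
  for (e in seq_len(nrow(kept))) {
    ri <- uf_find(parent, kept$i[e]); rj <- uf_find(parent, kept$j[e])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  comp <- match(roots, unique(roots))
  size <- tabulate(comp)
  first <- vapply(seq_len(max(comp)), function(c) min(which(comp == c)),
                  integer(1))
  rank <- order(-size, first)
  labels <- match(comp, rank) - 1L
  structure(list(labels = labels, k = as.integer(k),
                 cut_edges = tree[cut, , drop = FALSE],
                 mst_total_weight = sum(tree$weight)),
            class = "mst_clustering")
}

#' MST clustering of a 2D map
#'
#' Convenience wrapper: [build_mst()] then [cut_to_k()].
#'
#' @param map A `map2d` object or an N x 2 coordinate matrix.
#' @param k Number of clusters.
#' @return An `mst_clustering` (see [cut_to_k()]); `labels` are aligned with
#'   the map's rows and named by its rownames.
#' @export
mst_cluster <- function(map, k) {
  coords <- if (inherits(map, "map2d")) map$coords else as.matrix(map)
  cl <- cut_to_k(build_mst(coords), k, n = nrow(coords))
  names(cl$labels) <- rownames(coords)
  cl
}

#' @export
print.mst_clustering <- function(x, ...) {
  cat("mst_clustering: k =", x$k, ", sizes:",
      paste(tabulate(x$labels + 1L, nbins = x$k), collapse = ", "),
      ", MST total weight", format(x$mst_total_weight, digits = 5), "\n")
  invisible(x)
}
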