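#' Pair-normalized betweenness centrality in a tree
#'
#' For each node, the fraction of unordered node pairs (excluding pairs that
#' contain the node itself) whose unique tree path passes through it. A leaf
#' scores 0; a star center scores 1. Computed exactly in O(n) from subtree
#' sizes: removing node v splits the tree into components of sizes s_1..s_k,
#' and the raw count is C(n-1, 2) minus the within-component pair counts.
#'
#' @param tree a [spanning_tree()] with `n >= 3`.
#' @return numeric vector of length `n` in `[0, 1]`.
#' @export
tree_betweenness <- function(tree) {
  n <- tree$n
  if (n < 3L) stop("betweenness undefined for n < 3")
  rooted <- root_tree(tree)
  size <- subtree_sizes(tree, rooted)
  bc <- numeric(n)
  pairs_total <- (n - 1) * (n - 2) / 2
  # component sizes around v: sizes of child subtrees + the parent-side remainder
  child_sq <- numeric(n)   # sum over children u of C(size[u], 2)
  child_sum <- numeric(n)  # sum over children u of size[u]
  for (v in rooted$order[-1L]) {
    p <- rooted$parent[v]
    child_sq[p] <- child_sq[p] + size[v] * (size[v] - 1) / 2
    child_sum[p] <- child_sum[p] + size[v]
  }
  up <- n - 1 - child_sum  # parent-side component size (0 for the root)
  bc <- (pairs_total - child_sq - up * (up - 1) / 2) / pairs_total
  bc
}

#' Average shortest path length (hops) of a tree
#'
#' Mean hop distance over all unordered node pairs. In a tree each edge
#' separates the nodes into groups of size s and n - s, contributing
#' s(n - s) pair-hops, so the metric is exact and O(n).
#'
#' @param tree a [spanning_tree()].
#' @return mean hop count; `1` for `n = 2`.
#' @export
path_length <- function(tree) {
  n <- tree$n
  rooted <- root_tree(tree)
  size <- subtree_sizes(tree, rooted)
  s <- size[rooted$order[-1L]]             # child-side size of each edge
  sum(s * (n - s)) / (n * (n - 1) / 2)
}

#' Leaf fraction of a tree
#' @param tree a [spanning_tree()].
#' @return fraction of degree-1 nodes; high for star-like (integrated) trees.
#' @export
leaf_fraction <- function(tree) {
  mean(tree_degrees(tree) == 1L)
}

#' Tree hierarchy index
#'
#' Quantifies the trade-off between network integration and hub overloading:
#' `Th = L / (2 m BCmax)` where `L` is the leaf count, `m = n - 1` the edge
#' count and `BCmax` the maximum pair-normalized betweenness. A pure star
#' scores exactly 0.5 for every `n >= 3`; a path tends to 0 as `n` grows.
#'
#' @param tree a [spanning_tree()] with `n >= 3`.
#' @return tree hierarchy in `(0, 1]`.
#' @export
tree_hierarchy <- function(tree) {
  if (tree$n < 3L) stop("tree hierarchy undefined for n < 3")
  leaves <- sum(tree_degrees(tree) == 1L)
  m <- tree$n - 1L
  bcmax <- max(tree_betweenness(tree))
  leaves / (2 * m * bcmax)
}

#' Maximum degree of a tree
#' @param tree a [spanning_tree()].
#' @export
max_degree <- function(tree) {
  max(tree_degrees(tree))
}

#' Degree assortativity of a tree
#'
#' Pearson correlation of endpoint degrees over both orientations of every
#' edge (Newman's r). `-1` for a star; `NA` when endpoint degrees have zero
#' variance (e.g. n = 2), in which case the metric is excluded from group
#' tests downstream.
#'
#' @param tree a [spanning_tree()].
#' @return assortativity in `[-1, 1]`, or `NA`.
#' @export
assortativity <- function(tree) {
  deg <- tree_degrees(tree)
  x <- c(deg[tree$edges[, 1L]], deg[tree$edges[, 2L]])
  y <- c(deg[tree$edges[, 2L]], deg[tree$edges[, 1L]])
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Degree divergence (kappa) of a tree
#'
#' Second moment of the degree distribution over the first,
#' `kappa = mean(k^2) / mean(k)`; measures the broadness of the degree
#' spectrum (`n/2` for a star, < 2 for a path).
#'
#' @param tree a [spanning_tree()].
#' @export
degree_divergence <- function(tree) {
  k <- tree_degrees(tree)
  sum(k^2) / sum(k)
}

#' The six global MST metrics
#'
#' Bundles path length `L`, leaf fraction `Lf`, tree hierarchy `Th`,
#' maximum degree `Dmax`, assortativity `r` and degree divergence `kappa`
#' for one tree — the standard global description of an MST configuration
#' on the line-like (segregated) to star-like (integrated) continuum.
#'
#' @param tree a [spanning_tree()] with `n >= 3`.
#' @return A one-row `data.frame` of class `tree_metrics` with columns
#'   `L`, `Lf`, `Th`, `Dmax`, `r`, `kappa`.
#' @examples
#' global_metrics(spanning_tree(cbind(1, 2:10)))  # star on 10 nodes
#' @export
global_metrics <- function(tree) {
  out <- data.frame(
    L = path_length(tree),
    Lf = leaf_fraction(tree),
    Th = tree_hierarchy(tree),
    Dmax = max_degree(tree),
    r = assortativity(tree),
    kappa = degree_divergence(tree)
  )
  class(out) <- c("tree_metrics", "data.frame")
  out
}

#' Global metrics for a list of trees
#'
#' @param trees named list of [spanning_tree()] objects (one per subject).
#' @return `data.frame` with a `subject_id` column and the six metric columns.
#' @export
cohort_metrics <- function(trees) {
  out <- do.call(rbind, lapply(trees, function(t) as.data.frame(global_metrics(t))))
  ids <- names(trees)
  if (is.null(ids)) ids <- as.character(seq_along(trees))
  cbind(data.frame(subject_id = ids), out, row.names = NULL)
}

#' @export
print.tree_metrics <- function(x, digits = 4, ...) {
  cat("Global MST metrics\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
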