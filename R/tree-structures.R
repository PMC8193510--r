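#' Construct a spanning tree
#'
#' A `spanning_tree` holds the skeleton extracted from a connectivity network:
#' `n` nodes and exactly `n - 1` undirected edges that connect all nodes
#' without cycles. Edge weights `w` (original connectivity) and distances `d`
#' (typically `1/w`) are carried along when known.
#'
#' @param edges two-column integer matrix, one row per undirected edge
#'   (node indices in `1:n`).
#' @param n number of nodes; defaults to the largest index in `edges`.
#' @param node_labels optional character vector of length `n`.
#' @param w,d optional numeric vectors of per-edge weights and distances.
#' @return An object of class `spanning_tree` with components `n`, `edges`
#'   (rows sorted so the smaller index comes first), `w`, `d`, `node_labels`.
#' @examples
#' star <- spanning_tree(cbind(1, 2:6))
#' path <- spanning_tree(cbind(1:5, 2:6))
#' tree_degrees(star)
#' @export
spanning_tree <- function(edges, n = NULL, node_labels = NULL, w = NULL, d = NULL) {
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  if (is.null(n)) n <- max(edges)
  n <- as.integer(n)
  if (n < 2L) stop("a spanning tree needs at least 2 nodes")
  if (nrow(edges) != n - 1L)
    stop(sprintf("a spanning tree on %d nodes must have %d edges, got %d",
                 n, n - 1L, nrow(edges)))
  if (any(edges < 1L | edges > n)) stop("edge endpoints outside 1..n")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loop in edge list")
  # orient each edge small->large, keep w/d aligned
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, 2:1]
  # connectivity via union-find; n-1 edges + connected => acyclic
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
    if (ra == rb) stop("edge list contains a cycle: not a tree")
    parent[ra] <- rb
  }
  if (!is.null(node_labels)) {
    node_labels <- as.character(node_labels)
    if (length(node_labels) != n) stop("node_labels must have length n")
  } else node_labels <- as.character(seq_len(n))
  structure(list(n = n, edges = edges, w = w, d = d, node_labels = node_labels),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  deg <- tree_degrees(x)
  cat(sprintf("Spanning tree: %d nodes, %d edges\n", x$n, nrow(x$edges)))
  cat(sprintf("  leaf fraction %.3f, max degree %d\n",
              mean(deg == 1L), max(deg)))
  invisible(x)
}

#' Node degrees of a tree
#' @param tree a [spanning_tree()].
#' @return integer vector of length `n`.
#' @export
tree_degrees <- function(tree) {
  tabulate(tree$edges, nbins = tree$n)
}

# Canonical character keys for undirected edges; used for set operations.
edge_keys <- function(tree) {
  paste(tree$edges[, 1L], tree$edges[, 2L], sep = "-")
}

# Root the tree at node 1 and return parent pointers and a DFS ordering.
# Iterative to stay safe on path-like trees of a few hundred nodes.
root_tree <- function(tree) {
  n <- tree$n
  adj <- vector("list", n)
  for (e in seq_len(nrow(tree$edges))) {
    a <- tree$edges[e, 1L]; b <- tree$edges[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(n); parent[1L] <- 0L
  order <- integer(n)
  stack <- integer(n); stack[1L] <- 1L; top <- 1L; k <- 0L
  visited <- logical(n); visited[1L] <- TRUE
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    k <- k + 1L; order[k] <- v
    for (u in adj[[v]]) if (!visited[u]) {
      visited[u] <- TRUE; parent[u] <- v
      top <- top + 1L; stack[top] <- u
    }
  }
  list(parent = parent, order = order)
}

# Subtree sizes under the rooting at node 1 (processed in reverse DFS order).
subtree_sizes <- function(tree, rooted = root_tree(tree)) {
  n <- tree$n
  size <- rep(1L, n)
  for (v in rev(rooted$order[-1L])) {
    size[rooted$parent[v]] <- size[rooted$parent[v]] + size[v]
  }
  size
}
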