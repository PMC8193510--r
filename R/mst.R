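#' Minimum spanning tree by Kruskal's algorithm
#'
#' Sorts candidate edges by distance and adds them one by one, skipping any
#' edge that would close a cycle, until all nodes are connected. On the
#' inverted-connectivity distance matrix this extracts the strongest-edge
#' backbone of the network. The MST is unique when distances are unique;
#' ties are broken deterministically by edge index (stable sort) and a
#' warning notes that uniqueness is then not guaranteed.
#'
#' @param dm a `distance_matrix` from [to_distance()], or a plain symmetric
#'   numeric matrix of distances (NA = absent edge).
#' @return A [spanning_tree()] carrying per-edge `d` and `w = 1/d`.
#' @examples
#' z <- 0.5 - as.matrix(dist(cbind(runif(6), runif(6)))) / 4
#' diag(z) <- 0
#' t <- kruskal_mst(to_distance(connectivity_matrix(z)))
#' @export
kruskal_mst <- function(dm) {
  if (inherits(dm, "distance_matrix")) {
    d <- dm$d; labels <- dm$node_labels
  } else {
    d <- as.matrix(dm)
    labels <- rownames(d)
    diag(d) <- NA_real_
  }
  n <- nrow(d)
  idx <- which(upper.tri(d) & is.finite(d), arr.ind = TRUE)
  dv <- d[cbind(idx[, 1L], idx[, 2L])]
  if (anyDuplicated(dv))
    warning("tied edge distances: MST not unique, ties broken by edge index")
  ord <- order(dv, idx[, 1L], idx[, 2L])
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  sel <- integer(n - 1L); k <- 0L
  for (e in ord) {
    ra <- find(idx[e, 1L]); rb <- find(idx[e, 2L])
    if (ra != rb) {
      parent[ra] <- rb
      k <- k + 1L; sel[k] <- e
      if (k == n - 1L) break
    }
  }
  if (k < n - 1L)
    stop(sprintf("distance graph is disconnected: spanning tree impossible (%d of %d edges found)",
                 k, n - 1L))
  spanning_tree(idx[sel, , drop = FALSE], n = n, node_labels = labels,
                w = 1 / dv[sel], d = dv[sel])
}

#' Group-representative minimum spanning tree
#'
#' Averages the Fisher-z connectivity matrices of a group elementwise and
#' extracts the MST of the mean matrix — the group-level backbone used for
#' hub/connector mapping and degree-distribution analysis.
#'
#' @param cohort list of [connectivity_matrix()] objects sharing node labels.
#' @param repair passed to [to_distance()].
#' @return A [spanning_tree()].
#' @export
group_representative_mst <- function(cohort, repair = FALSE) {
  stopifnot(length(cohort) >= 1L)
  labels <- cohort[[1L]]$node_labels
  for (cm in cohort) {
    stopifnot(inherits(cm, "connectivity_matrix"))
    if (!identical(cm$node_labels, labels))
      stop("node labels differ across subjects; cannot average")
  }
  zbar <- Reduce(`+`, lapply(cohort, `[[`, "z")) / length(cohort)
  kruskal_mst(to_distance(connectivity_matrix(zbar, subject_id = "group-mean",
                                              node_labels = labels),
                          repair = repair))
}

#' Export a spanning tree as edge list or GraphML
#'
#' @param tree a [spanning_tree()].
#' @param file output path.
#' @param format `"edgelist"` (tab-separated: node_a, node_b, w, d) or
#'   `"graphml"`.
#' @export
write_tree <- function(tree, file, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  a <- tree$node_labels[tree$edges[, 1L]]
  b <- tree$node_labels[tree$edges[, 2L]]
  w <- if (is.null(tree$w)) rep(NA_real_, nrow(tree$edges)) else tree$w
  d <- if (is.null(tree$d)) rep(NA_real_, nrow(tree$edges)) else tree$d
  if (format == "edgelist") {
    utils::write.table(data.frame(node_a = a, node_b = b, w = w, d = d),
                       file, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    con <- file(file, "w"); on.exit(close(con))
    writeLines(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
      '  <graph edgedefault="undirected">'), con)
    writeLines(sprintf('    <node id="%s"/>', tree$node_labels), con)
    writeLines(sprintf('    <edge source="%s" target="%s"><data key="w">%.10g</data></edge>',
                       a, b, w), con)
    writeLines(c('  </graph>', '</graphml>'), con)
  }
  invisible(file)
}

#' Read a spanning tree from an edge-list file written by [write_tree()]
#' @param file path to a tab-separated edge list with columns node_a, node_b, w, d.
#' @param node_labels optional full label set (needed if some nodes could be
#'   absent from the edge list; for a tree all nodes appear).
#' @return A [spanning_tree()].
#' @export
read_tree <- function(file, node_labels = NULL) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric", "numeric"))
  if (is.null(node_labels)) node_labels <- sort(unique(c(df$node_a, df$node_b)))
  spanning_tree(cbind(match(df$node_a, node_labels), match(df$node_b, node_labels)),
                n = length(node_labels), node_labels = node_labels,
                w = df$w, d = df$d)
}
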