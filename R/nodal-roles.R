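#' Local importance of tree nodes
#'
#' For node v with neighborhood Adj(v), the local importance is
#' `li(v) = |A| / |Adj(v)| + 1/n` where `A` is the set of neighbors whose
#' degree does not exceed v's (equal degrees count). The 1/n term is a
#' baseline: the larger the network, the less important any single node.
#' Bounds: `1/n` when every neighbor has strictly higher degree (a leaf under
#' a hub) and `1 + 1/n` when every neighbor has strictly lower degree (a star
#' center).
#'
#' @param tree a [spanning_tree()].
#' @param v optional node index/indices; default all nodes.
#' @return numeric vector of local importance values in `[1/n, 1 + 1/n]`.
#' @export
local_importance <- function(tree, v = seq_len(tree$n)) {
  deg <- tree_degrees(tree)
  n <- tree$n
  # per node: count neighbors with degree <= own degree
  le_count <- numeric(n)
  da <- deg[tree$edges[, 1L]]; db <- deg[tree$edges[, 2L]]
  for (e in seq_len(nrow(tree$edges))) {
    a <- tree$edges[e, 1L]; b <- tree$edges[e, 2L]
    if (db[e] <= da[e]) le_count[a] <- le_count[a] + 1
    if (da[e] <= db[e]) le_count[b] <- le_count[b] + 1
  }
  (le_count / deg + 1 / n)[v]
}

#' Connector index of tree nodes
#'
#' `ci(v) = BC(v) / li(v)`: high for nodes carrying much globally integrated
#' traffic (high betweenness) while being locally unimportant — the low-degree
#' "bridges" that join different hubs. Hubs score lower because their local
#' importance is high; leaves score 0 because their betweenness is 0. Together
#' with degree, ci spans a two-dimensional connectivity-transitivity space
#' that separates hubs from connectors in an MST.
#'
#' @inheritParams local_importance
#' @return numeric vector of connector index values (>= 0).
#' @export
connector_index <- function(tree, v = seq_len(tree$n)) {
  (tree_betweenness(tree) / local_importance(tree))[v]
}

#' Per-node profile of an MST
#'
#' Degree, pair-normalized betweenness, local importance, connector index and
#' the hub/connector role label for every node of a tree.
#'
#' Roles follow the mean + 2 SD rule: hubs are nodes whose degree exceeds the
#' node-population mean by more than `sd_threshold` population SDs, connectors
#' the same for ci. A node passing both thresholds is labeled
#' `"hub+connector"` (empirically rare, but not forbidden).
#'
#' @param tree a [spanning_tree()] with `n >= 3`.
#' @param sd_threshold SD multiplier for the hub/connector cutoffs (default 2).
#' @return `data.frame` of class `nodal_profiles` with columns `node`,
#'   `degree`, `bc`, `li`, `ci`, `role`.
#' @export
nodal_profiles <- function(tree, sd_threshold = 2) {
  deg <- tree_degrees(tree)
  bc <- tree_betweenness(tree)
  li <- local_importance(tree)
  ci <- bc / li
  out <- data.frame(node = tree$node_labels, degree = deg,
                    bc = bc, li = li, ci = ci,
                    role = "peripheral", stringsAsFactors = FALSE)
  out <- classify_roles(out, sd_threshold = sd_threshold)
  class(out) <- c("nodal_profiles", "data.frame")
  out
}

#' Classify nodes as hubs, connectors or peripheral
#'
#' @param profiles `data.frame` with columns `degree` and `ci` (e.g. from
#'   [nodal_profiles()]).
#' @param sd_threshold SD multiplier (default 2).
#' @return the input with a `role` column: `"hub"`, `"connector"`,
#'   `"hub+connector"` or `"peripheral"`. Population (not sample) SD is used:
#'   the threshold is over a fixed, finite node set.
#' @export
classify_roles <- function(profiles, sd_threshold = 2) {
  stopifnot(all(c("degree", "ci") %in% names(profiles)))
  if (nrow(profiles) < 3L) stop("need at least 3 nodes to classify roles")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sd_deg <- pop_sd(profiles$degree)
  if (sd_deg == 0) warning("all degrees equal: no hubs can be identified")
  sd_ci <- pop_sd(profiles$ci)
  hub <- sd_deg > 0 & profiles$degree > mean(profiles$degree) + sd_threshold * sd_deg
  conn <- sd_ci > 0 & profiles$ci > mean(profiles$ci) + sd_threshold * sd_ci
  profiles$role <- ifelse(hub & conn, "hub+connector",
                   ifelse(hub, "hub",
                   ifelse(conn, "connector", "peripheral")))
  if (any(hub & conn))
    message(sum(hub & conn), " node(s) classified as both hub and connector")
  profiles
}

#' @export
print.nodal_profiles <- function(x, ...) {
  cat(sprintf("Nodal profiles: %d nodes (%d hub, %d connector, %d dual)\n",
              nrow(x), sum(x$role == "hub"), sum(x$role == "connector"),
              sum(x$role == "hub+connector")))
  imp <- x[x$role != "peripheral", , drop = FALSE]
  if (nrow(imp)) print.data.frame(imp, digits = 4, row.names = FALSE)
  invisible(x)
}
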