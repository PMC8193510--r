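# Canonical small trees used across tests.

star_tree <- function(n, center = 1L) {
  spanning_tree(cbind(center, setdiff(seq_len(n), center)), n = n)
}

path_tree <- function(n) {
  spanning_tree(cbind(seq_len(n - 1L), 2:n), n = n)
}

# Two hubs joined through a degree-2 bridge node (12 nodes):
# hub 1 carries leaves 4..8, hub 2 carries leaves 9..12, node 3 bridges them.
barbell_tree <- function() {
  spanning_tree(rbind(c(1, 3), c(2, 3),
                      cbind(1, 4:8), cbind(2, 9:12)), n = 12)
}

# All labeled spanning trees on n nodes via Pruefer sequences (n^(n-2) trees).
# Independent enumeration oracle for Kruskal.
all_labeled_trees <- function(n) {
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  lapply(seq_len(nrow(seqs)), function(i) pruefer_to_edges(seqs[i, ], n))
}

pruefer_to_edges <- function(prf, n) {
  degree <- rep(1L, n)
  for (v in prf) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(prf)) {
    leaf <- which(degree == 1L)[1L]
    edges[i, ] <- c(leaf, prf[i])
    degree[leaf] <- degree[leaf] - 1L
    degree[prf[i]] <- degree[prf[i]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

tree_total_distance <- function(edges, d) {
  sum(d[cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))])
}

# Random symmetric distance matrix with unique weights.
random_distance_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- sample(seq_len(n * (n - 1) / 2)) + runif(n * (n - 1) / 2) / 10
  d <- d + t(d)
  diag(d) <- NA
  d
}

# Connectivity matrix whose MST is unambiguous, for pipeline fixtures.
random_connectivity <- function(n, subject_id = "s", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(0, n, n)
  z[upper.tri(z)] <- runif(n * (n - 1) / 2, 0.05, 1)
  z <- z + t(z)
  connectivity_matrix(z, subject_id = subject_id)
}
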