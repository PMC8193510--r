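#' Edge overlap between two spanning trees
#'
#' `sigma(a, b) = |E_a intersect E_b| / (n - 1)`: the fraction of shared
#' edges (compared as unordered node pairs). A similarity kernel on subjects:
#' symmetric, in `[0, 1]`, with `sigma(a, a) = 1`.
#'
#' @param a,b [spanning_tree()] objects on the same node set.
#' @return overlap in `[0, 1]`; `(n - 1) * overlap` is the shared edge count.
#' @export
tree_overlap <- function(a, b) {
  stopifnot(inherits(a, "spanning_tree"), inherits(b, "spanning_tree"))
  if (a$n != b$n || !identical(a$node_labels, b$node_labels))
    stop("trees are defined on different node sets")
  length(intersect(edge_keys(a), edge_keys(b))) / (a$n - 1L)
}

#' Pairwise overlap matrix for a cohort of trees
#'
#' @param trees named list of [spanning_tree()] objects on a common node set.
#' @return symmetric `overlap_matrix` (subjects x subjects, unit diagonal).
#' @export
overlap_matrix <- function(trees) {
  s <- length(trees)
  stopifnot(s >= 2L)
  keys <- lapply(trees, edge_keys)
  m <- trees[[1L]]$n - 1L
  om <- diag(1, s)
  for (i in seq_len(s - 1L)) for (j in (i + 1L):s) {
    if (trees[[i]]$n != trees[[j]]$n ||
        !identical(trees[[i]]$node_labels, trees[[j]]$node_labels))
      stop("trees are defined on different node sets")
    om[i, j] <- om[j, i] <- length(intersect(keys[[i]], keys[[j]])) / m
  }
  ids <- names(trees)
  if (is.null(ids)) ids <- as.character(seq_len(s))
  dimnames(om) <- list(ids, ids)
  structure(om, class = c("overlap_matrix", "matrix"))
}

#' Within-group mean and SD of pairwise tree overlap
#'
#' Averages the strictly-lower-triangle overlap entries among subjects of the
#' same group (the diagonal is excluded).
#'
#' @param om an [overlap_matrix()] (or plain symmetric matrix).
#' @param groups factor/vector of group labels, one per subject (matrix order).
#' @return `data.frame` with columns `group`, `mean`, `sd`, `n_pairs`.
#' @export
within_group_similarity <- function(om, groups) {
  om <- unclass(om)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(om))
  out <- lapply(levels(groups), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2L) stop("group '", g, "' has fewer than 2 subjects")
    vals <- om[idx, idx][lower.tri(diag(length(idx)))]
    data.frame(group = g, mean = mean(vals), sd = stats::sd(vals),
               n_pairs = length(vals))
  })
  do.call(rbind, out)
}

#' Permutation test of within-group MST similarity
#'
#' Tests whether two groups differ in MST structure: if they do, the observed
#' within-group overlap exceeds what group-relabeled cohorts achieve. The
#' statistic is the mean of the two within-group overlap means (unweighted by
#' default; size-weighted optional). Group labels are permuted with sizes
#' fixed, and the one-sided p-value is the fraction of permutations whose
#' statistic is not less than the observed one (divided by exactly `n_perm`;
#' the observed arrangement is not added to the null).
#'
#' @param trees named list of [spanning_tree()] objects, or a precomputed
#'   [overlap_matrix()].
#' @param groups two-level factor of group labels, one per subject.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the label shuffles.
#' @param weighted if `TRUE`, weight the group means by pair counts.
#' @return A `perm_test` object: `observed_stat`, `null_stats`, `p_value`,
#'   `n_permutations`, `seed`, plus the per-group summary.
#' @export
similarity_permutation_test <- function(trees, groups, n_perm = 10000,
                                        seed = 1L, weighted = FALSE) {
  om <- if (inherits(trees, "overlap_matrix") || is.matrix(trees)) unclass(trees)
        else unclass(overlap_matrix(trees))
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) != 2L) stop("exactly two groups are supported")
  if (n_perm < 100L) warning("fewer than 100 permutations: p-value resolution is coarse")
  s <- nrow(om)
  stopifnot(length(groups) == s)
  pair <- which(lower.tri(om), arr.ind = TRUE)
  o <- om[pair]
  gi <- as.integer(groups)
  stat_for <- function(g) {
    same <- g[pair[, 1L]] == g[pair[, 2L]]
    g1 <- same & g[pair[, 1L]] == 1L
    g2 <- same & g[pair[, 1L]] == 2L
    m1 <- mean(o[g1]); m2 <- mean(o[g2])
    if (weighted) (sum(o[g1]) + sum(o[g2])) / (sum(g1) + sum(g2))
    else (m1 + m2) / 2
  }
  observed <- stat_for(gi)
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm),
                       function(i) stat_for(sample(gi)), numeric(1))
  p <- sum(null_stats >= observed - 1e-12) / n_perm
  structure(list(observed_stat = observed, null_stats = null_stats,
                 p_value = p, n_permutations = n_perm, seed = seed,
                 group_summary = within_group_similarity(om, groups),
                 statistic = "mean within-group overlap"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s)\n", x$statistic))
  cat(sprintf("  observed = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$observed_stat, x$p_value, x$n_permutations, x$seed))
  if (!is.null(x$group_summary)) {
    print.data.frame(x$group_summary, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Write an overlap matrix to CSV
#' @param om an [overlap_matrix()].
#' @param file output path.
#' @export
write_overlap <- function(om, file) {
  utils::write.csv(as.data.frame(unclass(om)), file, row.names = TRUE)
  invisible(file)
}
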