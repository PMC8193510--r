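#' Fisher-z connectivity from ROI time series
#'
#' Computes the pairwise Pearson correlation of ROI-specific time series and
#' applies the Fisher z (arctanh) transform, the standard variance-stabilizing
#' edge definition for functional connectivity.
#'
#' Correlations of exactly +/-1 between distinct nodes (e.g. duplicated
#' series) are clamped to +/-(1 - 1e-7) with a warning so that the transform
#' stays finite. The diagonal is set to zero and ignored by all consumers.
#'
#' @param values numeric matrix, nodes x timepoints.
#' @param subject_id subject identifier.
#' @param node_labels optional node labels; default row names or `1..n`.
#' @return A `connectivity_matrix`: list with `subject_id`, `z` (symmetric
#'   Fisher-z matrix, zero diagonal) and `node_labels`.
#' @examples
#' ts <- matrix(rnorm(5 * 50), 5, 50)
#' cm <- compute_connectivity(ts, "s01")
#' @export
compute_connectivity <- function(values, subject_id = "subject", node_labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("need at least 2 nodes")
  if (ncol(values) < 3L) stop("need at least 3 timepoints")
  if (anyNA(values)) stop("missing values in time series")
  v <- apply(values, 1L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    stop("zero-variance time series for node(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(node_labels)) {
    node_labels <- rownames(values)
    if (is.null(node_labels)) node_labels <- as.character(seq_len(nrow(values)))
  }
  r <- stats::cor(t(values))
  off <- row(r) != col(r)
  if (any(abs(r[off]) >= 1)) {
    warning("perfect off-diagonal correlation(s) clamped to +/-(1 - 1e-7)")
    r[off] <- pmin(pmax(r[off], -(1 - 1e-7)), 1 - 1e-7)
  }
  z <- atanh(r)
  diag(z) <- 0
  connectivity_matrix(z, subject_id = subject_id, node_labels = node_labels)
}

#' Construct a connectivity matrix object
#'
#' @param z symmetric numeric matrix of Fisher-z weights; the diagonal is
#'   ignored (stored as zero).
#' @inheritParams compute_connectivity
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(z, subject_id = "subject", node_labels = NULL) {
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop("connectivity matrix must be square")
  if (max(abs(z - t(z))) > 1e-8) stop("connectivity matrix must be symmetric")
  z <- (z + t(z)) / 2
  off <- row(z) != col(z)
  if (any(!is.finite(z[off]))) stop("non-finite off-diagonal connectivity")
  diag(z) <- 0
  if (is.null(node_labels)) {
    node_labels <- rownames(z)
    if (is.null(node_labels)) node_labels <- as.character(seq_len(nrow(z)))
  }
  dimnames(z) <- list(node_labels, node_labels)
  structure(list(subject_id = subject_id, z = z, node_labels = as.character(node_labels)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("Connectivity matrix '%s': %d nodes (Fisher z)\n",
              x$subject_id, nrow(x$z)))
  invisible(x)
}

#' Convert connectivity weights to MST distances
#'
#' Negative and zero Fisher-z edges are removed (the MST is built on the
#' strongest positive connections only), and remaining weights are inverted,
#' `d_ij = 1 / w_ij`, so that the minimum-distance spanning tree is the
#' maximum-weight backbone.
#'
#' If removing non-positive edges disconnects the graph this fails loudly,
#' naming the components; with `repair = TRUE` the minimum number of
#' largest-|z| non-positive edges are re-inserted as tiny positive weights to
#' restore connectivity.
#'
#' @param cm a [connectivity_matrix()].
#' @param repair logical; reconnect a disconnected positive graph (default
#'   `FALSE`, hard error).
#' @return A `distance_matrix`: list with `d` (NA where edges are absent,
#'   NA diagonal) and `node_labels`.
#' @export
to_distance <- function(cm, repair = FALSE) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  z <- cm$z
  n <- nrow(z)
  d <- ifelse(z > 0, 1 / z, NA_real_)
  diag(d) <- NA_real_
  comp <- positive_components(z)
  if (max(comp) > 1L) {
    if (!repair) {
      sizes <- table(comp)
      stop(sprintf(
        "positive-edge graph is disconnected (%d components, sizes %s); use repair = TRUE to reconnect",
        max(comp), paste(sizes, collapse = ", ")))
    }
    # candidate non-positive edges, strongest |z| first; add those joining
    # distinct components with a weight far below any retained positive edge
    ut <- which(upper.tri(z) & z <= 0, arr.ind = TRUE)
    ord <- order(-abs(z[ut]))
    ut <- ut[ord, , drop = FALSE]
    wpos <- z[upper.tri(z) & z > 0]
    wtiny <- if (length(wpos)) min(wpos) * 1e-3 else 1e-6
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    # seed union-find with the existing positive components
    for (k in seq_len(n)) parent[k] <- which(comp == comp[k])[1L]
    added <- 0L
    for (e in seq_len(nrow(ut))) {
      ra <- find(ut[e, 1L]); rb <- find(ut[e, 2L])
      if (ra != rb) {
        parent[ra] <- rb
        d[ut[e, 1L], ut[e, 2L]] <- d[ut[e, 2L], ut[e, 1L]] <- 1 / wtiny
        added <- added + 1L
        if (added == max(comp) - 1L) break
      }
    }
    warning(sprintf("repaired disconnected positive graph by adding %d tiny-weight edge(s)", added))
  }
  structure(list(d = d, node_labels = cm$node_labels), class = "distance_matrix")
}

# Connected components of the positive-weight graph; returns component id per node.
positive_components <- function(z) {
  n <- nrow(z)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  idx <- which(upper.tri(z) & z > 0, arr.ind = TRUE)
  for (e in seq_len(nrow(idx))) {
    ra <- find(idx[e, 1L]); rb <- find(idx[e, 2L])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Read a square connectivity matrix from delimited text
#'
#' @param file path to a whitespace- or comma-delimited square matrix; a
#'   header row of node labels is detected automatically.
#' @param subject_id subject identifier (default: file name without extension).
#' @return A [connectivity_matrix()].
#' @export
read_connectivity <- function(file, subject_id = NULL) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(file))
  first <- readLines(file, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  raw <- tryCatch(
    as.matrix(utils::read.table(file, header = FALSE, sep = sep,
                                colClasses = "character", check.names = FALSE)),
    error = function(e) stop("corrupt connectivity matrix file: ", file,
                             " (", conditionMessage(e), ")", call. = FALSE))
  # a header row (node labels, possibly numeric) makes the file one row taller
  labels <- NULL
  if (nrow(raw) == ncol(raw) + 1L) {
    labels <- as.character(raw[1L, ])
    raw <- raw[-1L, , drop = FALSE]
  }
  m <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  if (anyNA(m) || nrow(m) != ncol(m))
    stop("corrupt connectivity matrix file: ", file)
  connectivity_matrix(m, subject_id = subject_id, node_labels = labels)
}

#' Write a connectivity matrix as delimited text
#'
#' @param cm a [connectivity_matrix()].
#' @param file output path (comma-separated, header row of node labels).
#' @export
write_connectivity <- function(cm, file) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  utils::write.table(cm$z, file, sep = ",", row.names = FALSE,
                     col.names = cm$node_labels, quote = FALSE)
  invisible(file)
}
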