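#' Specification of a synthetic cohort
#'
#' Collects the generative parameters for [generate_cohort()]: two groups of
#' subjects whose connectivity is built around a planted spanning tree with
#' tunable star-likeness, and phenotypes carrying a planted mediation chain
#' age -> leaf fraction -> negative-symptom score.
#'
#' Defaults emulate the reference cohort: two groups of 40, 164-node
#' networks, 150 timepoints, ages 21-55, a 29:11 male:female ratio, higher
#' head motion in patients, and a patient shift toward star-like (more
#' integrated) trees.
#'
#' @param n_subjects_per_group subjects per group (default 40).
#' @param n_nodes network nodes (default 164, must be >= 4).
#' @param n_timepoints sampled timepoints per subject (default 150; may be
#'   less than `n_nodes`, the connectivity is then rank-deficient but valid).
#' @param age_range min/max age in years (default `c(21, 55)`).
#' @param star_bias_base baseline star bias in `[0, 1]` (default 0.45).
#' @param star_bias_group_offset additive patient-group shift of the star
#'   bias (default 0.15: patients more star-like/integrated).
#' @param star_bias_age_slope path a of the planted chain: star-bias change
#'   per SD of age (default 0.03).
#' @param symptom_lf_slope path b: negative-symptom change per SD of planted
#'   leaf fraction (default 0.4).
#' @param symptom_direct_age_slope path c': direct age effect on the symptom
#'   (default 0.15).
#' @param noise_sd_topology SD of the Gaussian noise on the per-subject star
#'   bias (default 0.08).
#' @param noise_sd_symptom SD of the symptom noise (default 0.9).
#' @param edge_strength planted-tree edge correlation before SPD shrinkage
#'   (default 0.6).
#' @param baseline_corr off-tree baseline correlation (default 0.1; must be
#'   `< edge_strength`).
#' @param male_fraction fraction of male subjects per group (default 29/40).
#' @param motion_group_ratio multiplicative patient head-motion offset
#'   (default 1.43).
#' @param data what per-subject data to generate: `"connectivity"` (Fisher-z
#'   matrix from sampled time series), `"timeseries"` (raw series), or
#'   `"none"` (phenotypes and planted trees only).
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects_per_group = 40, n_nodes = 164,
                        n_timepoints = 150, age_range = c(21, 55),
                        star_bias_base = 0.45, star_bias_group_offset = 0.15,
                        star_bias_age_slope = 0.03, symptom_lf_slope = 0.4,
                        symptom_direct_age_slope = 0.15,
                        noise_sd_topology = 0.08, noise_sd_symptom = 0.9,
                        edge_strength = 0.6, baseline_corr = 0.1,
                        male_fraction = 29 / 40, motion_group_ratio = 1.43,
                        data = c("connectivity", "timeseries", "none"),
                        seed = 1L) {
  data <- match.arg(data)
  stopifnot(n_subjects_per_group >= 2, n_nodes >= 4, n_timepoints >= 3,
            length(age_range) == 2, age_range[1] < age_range[2],
            star_bias_base >= 0, star_bias_base <= 1,
            noise_sd_topology >= 0, noise_sd_symptom >= 0,
            edge_strength > 0, baseline_corr >= 0,
            baseline_corr < edge_strength)
  spec <- as.list(environment())
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a random tree on the path-star continuum
#'
#' Grows a tree by sequential attachment: each new node attaches with
#' probability `star_bias` to the current maximum-degree node (star move,
#' lowest index on ties) and otherwise to the most recently added node
#' (path move). `star_bias = 1` yields a pure star, `star_bias = 0` a pure
#' path, and the expected leaf fraction increases with `star_bias` in
#' between — a one-parameter realization of the line-like to star-like MST
#' continuum.
#'
#' @param n_nodes number of nodes (>= 4).
#' @param star_bias real in `[0, 1]`.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A [spanning_tree()].
#' @examples
#' leaf_fraction(generate_tree_topology(10, 1, seed = 0))  # star: 0.9
#' leaf_fraction(generate_tree_topology(10, 0, seed = 0))  # path: 0.2
#' @export
generate_tree_topology <- function(n_nodes, star_bias, seed = NULL) {
  if (n_nodes < 4) stop("n_nodes must be at least 4")
  stopifnot(star_bias >= 0, star_bias <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_nodes)
  deg <- integer(n)
  to <- integer(n - 1L)
  to[1L] <- 1L; deg[1L] <- 1L; deg[2L] <- 1L
  star_move <- stats::runif(n) < star_bias
  for (i in seq_len(n - 2L) + 2L) {
    target <- if (star_move[i]) which.max(deg[seq_len(i - 1L)]) else i - 1L
    to[i - 1L] <- target
    deg[target] <- deg[target] + 1L
    deg[i] <- 1L
  }
  spanning_tree(cbind(2:n, to), n = n)
}

#' Tree-structured covariance matrix
#'
#' Builds a correlation-like matrix whose strongest off-diagonal entries are
#' exactly the edges of a planted tree: unit diagonal, `edge_strength` on
#' tree edges, `baseline` elsewhere. If the matrix is not positive definite
#' (hub-heavy trees), all off-diagonal entries are shrunk by 10% steps until
#' the smallest eigenvalue exceeds `tol`; the tree edges still dominate
#' after shrinkage, so the MST of the noise-free matrix recovers the planted
#' tree exactly.
#'
#' @param tree a [spanning_tree()].
#' @param edge_strength correlation on tree edges (> baseline).
#' @param baseline off-tree correlation (>= 0).
#' @param tol minimum eigenvalue required (default 1e-6).
#' @param max_steps shrinkage steps allowed before failing (default 100).
#' @return symmetric positive-definite matrix with unit diagonal; attribute
#'   `"shrink_factor"` records the applied off-diagonal scaling.
#' @export
tree_to_covariance <- function(tree, edge_strength = 0.6, baseline = 0.1,
                               tol = 1e-6, max_steps = 100L) {
  stopifnot(baseline >= 0, baseline < edge_strength)
  n <- tree$n
  S <- matrix(baseline, n, n)
  S[cbind(tree$edges[, 1L], tree$edges[, 2L])] <- edge_strength
  S[cbind(tree$edges[, 2L], tree$edges[, 1L])] <- edge_strength
  diag(S) <- 1
  shrink <- 1
  for (step in seq_len(max_steps + 1L)) {
    lmin <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (lmin > tol) {
      attr(S, "shrink_factor") <- shrink
      return(S)
    }
    if (step > max_steps) break
    off <- row(S) != col(S)
    S[off] <- S[off] * 0.9
    shrink <- shrink * 0.9
  }
  stop("could not reach positive definiteness within ", max_steps, " shrinkage steps")
}

#' Generate a synthetic cohort
#'
#' Draws two groups of subjects. Each subject receives a star bias
#' `star_bias_base + offset * patient + a * z(age) + noise` (clipped to
#' `[0, 1]`, clipping recorded), a planted tree at that bias, zero-mean
#' Gaussian time series sampled from the tree-structured covariance (no
#' temporal autocorrelation: only zero-lag correlations are consumed
#' downstream), and phenotypes: gender at the specified ratio, lognormal
#' head motion with a patient offset, medication (patients only), six
#' cognitive test scores loading on latent working-memory and
#' executive-function factors with age and group effects, and three symptom
#' scores of which the negative-symptom score carries the planted chain
#' `b * z(Lf) + c' * z(age) + noise`.
#'
#' Age is standardized against the uniform population moments of
#' `age_range` so that the planted paths do not depend on the sampled ages.
#'
#' @param spec a [cohort_spec()].
#' @return An `mst_cohort`: list with `spec`, `phenotypes` (data.frame),
#'   `trees` (named list of planted [spanning_tree()]s), `connectivity` or
#'   `timeseries` (per `spec$data`), and `truth` (per-subject star bias,
#'   clipping flags, planted leaf fractions, path coefficients).
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects_per_group = 5, n_nodes = 20,
#'                                   data = "none", seed = 7))
#' head(co$phenotypes)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ng <- spec$n_subjects_per_group
  n_sub <- 2L * ng
  group <- rep(c("control", "patient"), each = ng)
  ids <- sprintf("sub-%03d", seq_len(n_sub))
  age <- stats::runif(n_sub, spec$age_range[1], spec$age_range[2])
  z_age <- (age - mean(spec$age_range)) / (diff(spec$age_range) / sqrt(12))
  n_male <- round(ng * spec$male_fraction)
  gender <- as.vector(vapply(1:2, function(i)
    sample(rep(c("M", "F"), c(n_male, ng - n_male))), character(ng)))
  motion <- stats::rlnorm(n_sub, meanlog = log(0.40), sdlog = 0.3) *
    ifelse(group == "patient", spec$motion_group_ratio, 1)
  medication <- ifelse(group == "patient",
                       stats::rlnorm(n_sub, meanlog = log(250), sdlog = 0.8), 0)

  raw_bias <- spec$star_bias_base +
    spec$star_bias_group_offset * (group == "patient") +
    spec$star_bias_age_slope * z_age +
    stats::rnorm(n_sub, sd = spec$noise_sd_topology)
  star_bias <- pmin(pmax(raw_bias, 0), 1)
  clipped <- star_bias != raw_bias

  trees <- lapply(star_bias, function(b) generate_tree_topology(spec$n_nodes, b))
  names(trees) <- ids
  lf <- vapply(trees, leaf_fraction, numeric(1))
  z_lf <- as.numeric(scale(lf))

  negative_symptom <- spec$symptom_lf_slope * z_lf +
    spec$symptom_direct_age_slope * z_age +
    stats::rnorm(n_sub, sd = spec$noise_sd_symptom)
  psychotic_symptom <- 0.3 * as.numeric(scale(negative_symptom)) +
    stats::rnorm(n_sub, sd = 0.95)
  disorganization <- stats::rnorm(n_sub)

  # latent cognition: mild age decline, patient deficit (~1 SD per Table-like contrast)
  wm_latent <- -0.25 * z_age - 1.0 * (group == "patient") + stats::rnorm(n_sub, sd = 0.8)
  ef_latent <- -0.20 * z_age - 1.0 * (group == "patient") + stats::rnorm(n_sub, sd = 0.8)
  test_score <- function(latent, mu, sdev, loading = 0.75)
    mu + sdev * (loading * latent + sqrt(1 - loading^2) * stats::rnorm(n_sub))
  pheno <- data.frame(
    subject_id = ids, group = group, age = age, gender = gender,
    motion = motion, medication = medication,
    wms_digit_span = test_score(wm_latent, 28.0, 6.3),
    wms_symbol_span = test_score(wm_latent, 23.8, 6.7),
    wms_letter_number = test_score(wm_latent, 19.8, 2.5),
    dkefs_verbal_fluency = test_score(ef_latent, 39.9, 10.8),
    cpt_dprime = test_score(ef_latent, 322.0, 6.3),
    stroop_conflict = test_score(ef_latent, 0.98, 0.03),
    psychotic_symptom = psychotic_symptom,
    negative_symptom = negative_symptom,
    disorganization = disorganization,
    stringsAsFactors = FALSE)

  connectivity <- NULL; timeseries <- NULL
  if (spec$data != "none") {
    sample_subject <- function(tree) {
      S <- tree_to_covariance(tree, spec$edge_strength, spec$baseline_corr)
      R <- chol(S)
      t(R) %*% matrix(stats::rnorm(spec$n_nodes * spec$n_timepoints),
                      spec$n_nodes, spec$n_timepoints)
    }
    series <- lapply(ids, function(id) sample_subject(trees[[id]]))
    names(series) <- ids
    if (spec$data == "timeseries") {
      timeseries <- series
    } else {
      connectivity <- lapply(ids, function(id)
        compute_connectivity(series[[id]], subject_id = id))
      names(connectivity) <- ids
    }
  }
  structure(list(spec = spec, phenotypes = pheno, trees = trees,
                 connectivity = connectivity, timeseries = timeseries,
                 truth = list(star_bias = stats::setNames(star_bias, ids),
                              clipped = stats::setNames(clipped, ids),
                              leaf_fraction = stats::setNames(lf, ids),
                              a = spec$star_bias_age_slope,
                              b = spec$symptom_lf_slope,
                              c_prime = spec$symptom_direct_age_slope)),
            class = "mst_cohort")
}

#' @export
print.mst_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d per group), %d nodes, data = %s\n",
              nrow(x$phenotypes), x$spec$n_subjects_per_group,
              x$spec$n_nodes, x$spec$data))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one CSV connectivity matrix per subject, `phenotypes.csv`,
#' `manifest.csv` (subject_id -> matrix file) and `truth.json` (planted tree
#' edge lists, per-subject star bias and clipping flags).
#'
#' @param cohort an `mst_cohort` generated with `data = "connectivity"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mst_cohort"))
  if (is.null(cohort$connectivity))
    stop("cohort has no connectivity matrices (generate with data = 'connectivity')")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- cohort$phenotypes$subject_id
  files <- file.path(dir, paste0(ids, "_connectivity.csv"))
  for (i in seq_along(ids)) write_connectivity(cohort$connectivity[[ids[i]]], files[i])
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(subject_id = ids, file = basename(files)),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- list(
    star_bias = as.list(cohort$truth$star_bias),
    clipped = as.list(cohort$truth$clipped),
    trees = lapply(cohort$trees, function(t)
      apply(t$edges, 1L, function(e) t$node_labels[e], simplify = FALSE)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv`, `phenotypes.csv` and the
#'   per-subject matrices.
#' @return list with `phenotypes` and `connectivity` (named list of
#'   [connectivity_matrix()]).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  pheno <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                           stringsAsFactors = FALSE)
  conn <- lapply(seq_len(nrow(manifest)), function(i)
    read_connectivity(file.path(dir, manifest$file[i]),
                      subject_id = manifest$subject_id[i]))
  names(conn) <- manifest$subject_id
  list(phenotypes = pheno, connectivity = conn)
}
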