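#' Pipeline configuration
#'
#' Bundles the analysis constants. Defaults match standard practice for this
#' analysis: 10,000 permutations for the similarity test, 5,000 for the
#' covariate-adjusted group tests, 5,000 bootstrap resamples for mediation,
#' and a 2 SD hub/connector threshold. All randomness flows from the single
#' root `seed`, split per stage with fixed offsets.
#'
#' @param n_perm_similarity permutations for the MST-overlap test.
#' @param n_perm_group permutations per metric for the group tests.
#' @param n_boot mediation bootstrap resamples.
#' @param hub_sd_threshold SD multiplier for hub/connector classification.
#' @param covariates phenotype columns controlled in group tests.
#' @param mediation_models which of models 1-4 to run.
#' @param repair_disconnected passed to [to_distance()].
#' @param seed root seed.
#' @return A `run_config` list.
#' @export
run_config <- function(n_perm_similarity = 10000, n_perm_group = 5000,
                       n_boot = 5000, hub_sd_threshold = 2,
                       covariates = c("age", "gender", "motion"),
                       mediation_models = 1:4,
                       repair_disconnected = FALSE, seed = 1L) {
  stopifnot(seed + 400L < .Machine$integer.max)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full MST-connectome pipeline
#'
#' Executes, in order: connectivity (already provided or computed upstream)
#' -> per-subject MST extraction -> global metrics -> group-representative
#' trees with nodal roles -> pairwise overlap and within-group similarity
#' permutation test -> degree-distribution fits per group ->
#' covariate-adjusted group tests with BH-FDR -> mediation/moderation
#' models. Results are written to `out_dir` as CSV/JSON with a provenance
#' record; reruns with the same inputs, config and seed are bit-identical.
#'
#' @param input an `mst_cohort` from [generate_cohort()] (with connectivity),
#'   a directory written by [write_cohort()], or a list with `phenotypes`
#'   and `connectivity` as returned by [read_cohort()].
#' @param config a [run_config()].
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return A `pipeline_result` list with elements `metrics`, `trees`,
#'   `similarity`, `roles`, `degree_fits`, `group_tests`, `nodal_tests`,
#'   `mediation`, `config`.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (is.character(input)) input <- read_cohort(input)
  pheno <- input$phenotypes
  conn <- input$connectivity
  if (is.null(conn)) stop("stage connectivity: no connectivity matrices in input")
  log_lines <- character(0)
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("%-12s %6.2fs", name,
                                       as.numeric(Sys.time() - ts, units = "secs")))
    out
  }
  ids <- pheno$subject_id
  stopifnot(all(ids %in% names(conn)))
  conn <- conn[ids]
  group <- as.factor(pheno$group)

  trees <- stage("mst", {
    out <- lapply(ids, function(id)
      kruskal_mst(to_distance(conn[[id]], repair = config$repair_disconnected)))
    names(out) <- ids
    out
  })
  metrics <- stage("metrics", cohort_metrics(trees))

  covars <- pheno[intersect(config$covariates, names(pheno))]
  covars <- data.frame(lapply(covars, function(col)
    if (is.character(col)) as.factor(col) else col))

  similarity <- stage("similarity", similarity_permutation_test(
    trees, group, n_perm = config$n_perm_similarity, seed = config$seed + 1L))

  roles <- stage("roles", {
    lapply(split(seq_along(ids), group), function(idx) {
      rep_tree <- group_representative_mst(conn[idx],
                                           repair = config$repair_disconnected)
      list(tree = rep_tree,
           profiles = nodal_profiles(rep_tree,
                                     sd_threshold = config$hub_sd_threshold))
    })
  })

  degree_fits <- stage("fit-degree", lapply(roles, function(r)
    compare_degree_fits(degree_histogram(r$tree))))

  metric_cols <- c("L", "Lf", "Th", "Dmax", "r", "kappa")
  group_tests <- stage("compare", suppressWarnings(group_metric_tests(
    metrics[metric_cols], group, covariates = covars,
    n_perm = config$n_perm_group, seed = config$seed + 10L)))

  nodal_tests <- stage("compare-nodal", {
    labels <- trees[[1L]]$node_labels
    deg <- t(vapply(trees, tree_degrees, integer(length(labels))))
    ci <- t(vapply(trees, connector_index, numeric(length(labels))))
    nod <- as.data.frame(cbind(deg, ci))
    names(nod) <- c(paste0("degree_", labels), paste0("ci_", labels))
    suppressWarnings(group_metric_tests(nod, group, covariates = covars,
                                        n_perm = config$n_perm_group,
                                        seed = config$seed + 100L))
  })

  mediation <- stage("mediate", {
    fits <- lapply(config$mediation_models, function(m)
      run_mediation_model(metrics, pheno, m, n_boot = config$n_boot,
                          seed = config$seed + 200L + m))
    names(fits) <- paste0("model_", config$mediation_models)
    fits
  })

  result <- structure(list(metrics = metrics, trees = trees,
                           similarity = similarity, roles = roles,
                           degree_fits = degree_fits,
                           group_tests = group_tests,
                           nodal_tests = nodal_tests,
                           mediation = mediation, config = config,
                           log = log_lines),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir, pheno)
  log_lines <- c(log_lines, sprintf("total        %6.2fs",
                                    as.numeric(Sys.time() - t0, units = "secs")))
  result$log <- log_lines
  result
}

# Serialize every pipeline artifact with a provenance record.
write_pipeline_result <- function(result, out_dir, pheno) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  utils::write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  write_overlap(overlap_matrix(result$trees),
                file.path(out_dir, "overlap_matrix.csv"))
  jsonlite::write_json(list(
    observed = result$similarity$observed_stat,
    p_value = result$similarity$p_value,
    n_permutations = result$similarity$n_permutations,
    seed = result$similarity$seed,
    groups = result$similarity$group_summary),
    file.path(out_dir, "similarity_test.json"), auto_unbox = TRUE, digits = NA)
  for (g in names(result$roles)) {
    utils::write.csv(result$roles[[g]]$profiles,
                     file.path(out_dir, sprintf("roles_%s.csv", g)),
                     row.names = FALSE)
  }
  jsonlite::write_json(lapply(result$degree_fits, function(fs)
    lapply(fs$fits, function(f) list(family = f$family, alpha = f$alpha,
                                     kc = f$kc, r_squared = f$r_squared,
                                     scale = f$scale))),
    file.path(out_dir, "degree_fits.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$group_tests, file.path(out_dir, "group_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(result$nodal_tests, file.path(out_dir, "nodal_tests.csv"),
                   row.names = FALSE)
  med <- lapply(result$mediation, function(m) {
    if (inherits(m, "moderation_fit"))
      list(interaction_beta = m$interaction_beta, p = m$p)
    else lapply(m, function(f) list(a = f$a, b = f$b, c_prime = f$c_prime,
                                    indirect = f$indirect, ci_low = f$ci_low,
                                    ci_high = f$ci_high,
                                    significant = f$significant, n = f$n))
  })
  jsonlite::write_json(med, file.path(out_dir, "mediation.json"),
                       auto_unbox = TRUE, digits = NA)
  prov <- list(package = "mstnet",
               version = as.character(utils::packageVersion("mstnet")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               seed = cfg$seed,
               config = cfg[setdiff(names(cfg), "seed")],
               n_subjects = nrow(pheno))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("MST-connectome pipeline result\n")
  cat(sprintf("  %d subjects, %d nodes\n", nrow(x$metrics), x$trees[[1L]]$n))
  cat(sprintf("  similarity: observed %.3f, p = %.4g\n",
              x$similarity$observed_stat, x$similarity$p_value))
  cat("  group tests (global metrics):\n")
  print.data.frame(x$group_tests, digits = 3, row.names = FALSE)
  invisible(x)
}
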