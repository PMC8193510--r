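#' Covariate-adjusted permutation test for a group difference
#'
#' Tests whether a network metric differs between two groups while
#' controlling nuisance covariates (age, gender, head motion, ...). The
#' default scheme is Freedman-Lane residual permutation: the metric is
#' regressed on the covariates alone, the reduced-model residuals are
#' permuted and added back to the reduced-model fit, and the group effect
#' (covariate-adjusted group mean difference) is recomputed on each permuted
#' outcome. With no covariates this reduces to a plain two-sample
#' permutation test.
#'
#' The two-sided p-value uses the smoothed estimate
#' `(1 + #{|null| >= |observed|}) / (1 + n_perm)`.
#'
#' @param y numeric metric vector (one value per subject).
#' @param group two-level factor.
#' @param covariates optional numeric matrix/data.frame of covariates
#'   (factors in a data.frame are expanded to dummies; an intercept is
#'   always included).
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @param method `"freedman_lane"` (default) or `"raw"` (permute y directly).
#' @return A `perm_test` object with `observed_stat` (adjusted group mean
#'   difference, level 2 minus level 1), `null_stats`, `p_value`.
#' @export
covariate_adjusted_permutation_test <- function(y, group, covariates = NULL,
                                                n_perm = 5000, seed = 1L,
                                                method = c("freedman_lane", "raw")) {
  method <- match.arg(method)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("exactly two groups are supported")
  if (min(table(group)) < 2L) stop("each group needs at least 2 subjects")
  n <- length(y)
  stopifnot(length(group) == n, all(is.finite(y)))
  X <- cbind(`(Intercept)` = rep(1, n), expand_covariates(covariates, n))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariates")
  g <- as.numeric(group == levels(group)[2L])
  qr_x <- qr(X)
  resid_mat <- function(M) M - qr.fitted(qr_x, M)   # residualize against covariates
  gR <- resid_mat(g)
  gg <- sum(gR^2)
  if (gg < 1e-12) stop("group is collinear with the covariates")
  e <- as.numeric(resid_mat(y))                      # reduced-model residuals
  observed <- sum(gR * e) / gg
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  E <- matrix(if (method == "freedman_lane") e[perm_idx] else y[perm_idx],
              nrow = n)
  ER <- resid_mat(E)
  null_stats <- as.numeric(crossprod(gR, ER)) / gg
  # tolerance so exact ties are counted despite floating-point noise
  tol <- 1e-8 * (abs(observed) + 1e-12)
  p <- (1 + sum(abs(null_stats) >= abs(observed) - tol)) / (1 + n_perm)
  structure(list(observed_stat = observed, null_stats = null_stats,
                 p_value = p, n_permutations = n_perm, seed = seed,
                 covariates = colnames(X)[-1L], method = method,
                 statistic = sprintf("adjusted mean difference (%s - %s)",
                                     levels(group)[2L], levels(group)[1L])),
            class = "perm_test")
}

# Expand a covariate matrix/data.frame to a numeric matrix (dummy-code factors).
expand_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) {
    m <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  } else {
    m <- as.matrix(covariates)
    storage.mode(m) <- "double"
  }
  stopifnot(nrow(m) == n)
  m
}

#' Group tests over a metric table with FDR correction
#'
#' Runs [covariate_adjusted_permutation_test()] for each metric column and
#' adjusts the raw p-values with Benjamini-Hochberg across the whole family
#' (e.g. the six global metrics, or 164 regions x 2 nodal metrics).
#' Metrics with any undefined value (e.g. assortativity of a degenerate
#' tree) are dropped with a warning.
#'
#' @param metrics `data.frame` of metric columns (rows = subjects).
#' @param group two-level factor.
#' @param covariates as in [covariate_adjusted_permutation_test()].
#' @param n_perm permutations per metric (default 5000).
#' @param seed integer seed (each metric uses a derived seed).
#' @param method permutation scheme.
#' @return `data.frame` with columns `metric`, `observed`, `p_raw`, `p_fdr`,
#'   `n_perm`, `seed`.
#' @export
group_metric_tests <- function(metrics, group, covariates = NULL,
                               n_perm = 5000, seed = 1L,
                               method = "freedman_lane") {
  metrics <- as.data.frame(metrics)
  keep <- vapply(metrics, function(col) is.numeric(col) && all(is.finite(col)),
                 logical(1))
  if (!all(keep))
    warning("dropping metric(s) with undefined values: ",
            paste(names(metrics)[!keep], collapse = ", "))
  metrics <- metrics[keep]
  out <- lapply(seq_along(metrics), function(i) {
    tst <- covariate_adjusted_permutation_test(
      metrics[[i]], group, covariates, n_perm = n_perm,
      seed = seed + i - 1L, method = method)
    data.frame(metric = names(metrics)[i], observed = tst$observed_stat,
               p_raw = tst$p_value, n_perm = n_perm, seed = seed + i - 1L)
  })
  out <- do.call(rbind, out)
  out$p_fdr <- fdr_bh(out$p_raw)
  out[c("metric", "observed", "p_raw", "p_fdr", "n_perm", "seed")]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1); a thin wrapper over
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, `p_fdr >= p` elementwise.
#' @export
fdr_bh <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Pearson intercorrelation of MST metrics
#'
#' @param metrics `data.frame`/matrix of metric columns (rows = subjects).
#' @return symmetric correlation matrix; constant columns are excluded with
#'   a warning.
#' @export
metric_intercorrelation <- function(metrics) {
  m <- as.matrix(as.data.frame(metrics))
  storage.mode(m) <- "double"
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    warning("excluding constant/undefined column(s): ",
            paste(colnames(m)[sds == 0 | !is.finite(sds)], collapse = ", "))
    m <- m[, sds > 0 & is.finite(sds), drop = FALSE]
  }
  stats::cor(m)
}

#' Partial correlation
#'
#' Correlation of the residuals of `x` and `y` after regressing each on the
#' control variables; p-value from the t distribution with
#' `df = n - n_controls - 2`. With no controls this is the plain Pearson
#' correlation test.
#'
#' @param x,y numeric vectors.
#' @param controls optional matrix/data.frame of control variables.
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  C <- expand_covariates(controls, n)
  k <- if (is.null(C)) 0L else ncol(C)
  sx0 <- stats::sd(x); sy0 <- stats::sd(y)
  if (k > 0L) {
    qr_c <- qr(cbind(1, C))
    x <- qr.resid(qr_c, x)
    y <- qr.resid(qr_c, y)
  }
  # a variable fully explained by the controls has (numerically) zero residual
  if (stats::sd(x) < 1e-10 * sx0 || stats::sd(y) < 1e-10 * sy0)
    return(list(r = 0, p = 1, df = n - k - 2L))
  r <- stats::cor(x, y)
  df <- n - k - 2L
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), df = df)
}

#' Age/gender bipartite cohort matching
#'
#' Within each gender stratum, matches each minority-group subject to a
#' distinct majority-group subject by minimum total absolute age difference
#' (optimal bipartite assignment via the Hungarian method,
#' [clue::solve_LSAP()]). The matched cohort has equal group sizes and
#' identical gender ratios by construction.
#'
#' @param pheno `data.frame` with subject id, group, age and gender columns.
#' @param group_col,age_col,gender_col,id_col column names (defaults
#'   `"group"`, `"age"`, `"gender"`, `"subject_id"`).
#' @return the matched subset of `pheno` (both groups), with an attribute
#'   `"total_age_cost"` giving the summed |age difference|.
#' @export
match_cohorts <- function(pheno, group_col = "group", age_col = "age",
                          gender_col = "gender", id_col = "subject_id") {
  stopifnot(all(c(group_col, age_col, gender_col, id_col) %in% names(pheno)))
  grp <- droplevels(as.factor(pheno[[group_col]]))
  if (nlevels(grp) != 2L) stop("exactly two groups are supported")
  sizes <- table(grp)
  minority <- names(sizes)[which.min(sizes)]
  majority <- setdiff(levels(grp), minority)
  keep <- integer(0)
  total_cost <- 0
  for (g in unique(as.character(pheno[[gender_col]]))) {
    in_stratum <- pheno[[gender_col]] == g
    rows_min <- which(in_stratum & grp == minority)
    rows_maj <- which(in_stratum & grp == majority)
    if (length(rows_maj) < length(rows_min))
      stop(sprintf("stratum '%s': majority group smaller (%d) than minority (%d); matching infeasible",
                   g, length(rows_maj), length(rows_min)))
    if (!length(rows_min)) next
    cost <- abs(outer(pheno[[age_col]][rows_min], pheno[[age_col]][rows_maj], `-`))
    sol <- clue::solve_LSAP(cost)
    keep <- c(keep, rows_min, rows_maj[as.integer(sol)])
    total_cost <- total_cost + sum(cost[cbind(seq_along(rows_min), as.integer(sol))])
  }
  out <- pheno[sort(keep), , drop = FALSE]
  attr(out, "total_age_cost") <- total_cost
  out
}
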