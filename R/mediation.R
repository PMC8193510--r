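#' Reduce behavior test scores to factor scores
#'
#' Two reduction modes for multi-test cognitive/symptom batteries:
#' `"composite"` averages the z-scored tests assigned to each factor (e.g.
#' working memory from the three WMS tests; executive function from verbal
#' fluency, CPT d-prime and Stroop), and `"efa"` runs a maximum-likelihood
#' exploratory factor analysis with oblique (promax) rotation and
#' regression-method factor scores. Factor scores are standardized.
#'
#' @param scores `data.frame` of test scores (rows = subjects).
#' @param assignments named list mapping factor name -> character vector of
#'   test columns (composite mode), or a single integer number of factors
#'   (EFA mode).
#' @param method `"composite"` or `"efa"`; default picks composite when
#'   `assignments` is a list.
#' @return A `factor_model`: list with `method`, `scores` (subjects x
#'   factors, standardized), `loadings`.
#' @export
extract_factors <- function(scores, assignments,
                            method = if (is.list(assignments)) "composite" else "efa") {
  method <- match.arg(method, c("composite", "efa"))
  scores <- as.data.frame(scores)
  if (anyNA(scores)) {
    warning("missing values: subjects removed listwise")
    scores <- scores[stats::complete.cases(scores), , drop = FALSE]
  }
  if (method == "composite") {
    stopifnot(is.list(assignments), !is.null(names(assignments)))
    fac <- vapply(assignments, function(tests) {
      stopifnot(all(tests %in% names(scores)))
      z <- scale(as.matrix(scores[tests]))
      as.numeric(scale(rowMeans(z)))
    }, numeric(nrow(scores)))
    colnames(fac) <- names(assignments)
    loadings <- NULL
  } else {
    n_factors <- as.integer(assignments)
    fa <- tryCatch(
      stats::factanal(x = as.matrix(scores), factors = n_factors,
                      rotation = "promax", scores = "regression"),
      error = function(e) stop("EFA failed to converge: ", conditionMessage(e)))
    fac <- scale(fa$scores)
    loadings <- unclass(fa$loadings)
  }
  structure(list(method = method, scores = as.data.frame(fac),
                 loadings = loadings),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Factor model (%s): %d factor(s), %d subjects\n",
              x$method, ncol(x$scores), nrow(x$scores)))
  if (!is.null(x$loadings)) print(round(x$loadings, 3))
  invisible(x)
}

#' Mediation analysis with bootstrap confidence intervals
#'
#' Product-of-coefficients mediation: path `a` from regressing the mediator
#' on the exposure (plus covariates), paths `b` and `c'` from regressing the
#' outcome on mediator and exposure (plus covariates); the indirect effect is
#' `a * b`, with a percentile bootstrap interval over subjects resampled with
#' replacement. All variables are standardized before fitting, so
#' coefficients are on the standardized scale and the identity
#' `c = c' + a * b` holds exactly in the no-covariate case. The effect is
#' called significant when the interval excludes 0.
#'
#' @param x exposure vector (e.g. age).
#' @param mediator mediator vector (e.g. MST leaf fraction).
#' @param y outcome vector, or a data.frame/matrix of outcomes (one model per
#'   column).
#' @param covariates optional covariate matrix/data.frame entered in both
#'   regressions.
#' @param n_boot bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return A `mediation_fit` (or a named list of them for multiple
#'   outcomes): `a`, `b`, `c_prime`, `c_total`, `indirect`, `ci_low`,
#'   `ci_high`, `significant`, `n_boot`, `boot` (resampled indirect effects).
#' @examples
#' set.seed(1)
#' x <- rnorm(200); m <- 0.5 * x + rnorm(200); y <- 0.4 * m + rnorm(200)
#' fit_mediation(x, m, y, n_boot = 200, seed = 1)
#' @export
fit_mediation <- function(x, mediator, y, covariates = NULL, n_boot = 5000,
                          seed = 1L, conf = 0.95) {
  if (is.data.frame(y) || (is.matrix(y) && ncol(y) > 1)) {
    y <- as.data.frame(y)
    out <- lapply(y, fit_mediation, x = x, mediator = mediator,
                  covariates = covariates, n_boot = n_boot, seed = seed,
                  conf = conf)
    return(out)
  }
  y <- as.numeric(as.matrix(y))
  n <- length(x)
  if (n < 10L) stop("need at least 10 subjects")
  stopifnot(length(mediator) == n, length(y) == n)
  xs <- as.numeric(scale(x)); ms <- as.numeric(scale(mediator))
  ys <- as.numeric(scale(y))
  C <- expand_covariates(covariates, n)
  if (!is.null(C)) {
    C <- scale(C)
    if (qr(cbind(1, C))$rank < ncol(C) + 1L) stop("collinear covariates")
  }
  est <- mediation_paths(xs, ms, ys, C)
  set.seed(seed)
  if (is.null(C)) {
    # vectorized bootstrap: all regressions reduce to centered cross-moments
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    Xb <- matrix(xs[idx], nrow = n); Mb <- matrix(ms[idx], nrow = n)
    Yb <- matrix(ys[idx], nrow = n)
    Xb <- sweep(Xb, 2L, colMeans(Xb)); Mb <- sweep(Mb, 2L, colMeans(Mb))
    Yb <- sweep(Yb, 2L, colMeans(Yb))
    Sxx <- colSums(Xb^2); Smm <- colSums(Mb^2); Sxm <- colSums(Xb * Mb)
    Sxy <- colSums(Xb * Yb); Smy <- colSums(Mb * Yb)
    a_b <- Sxm / Sxx
    det <- Smm * Sxx - Sxm^2
    b_b <- (Smy * Sxx - Sxy * Sxm) / det
    boot <- a_b * b_b
  } else {
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      p <- mediation_paths(xs[idx], ms[idx], ys[idx], C[idx, , drop = FALSE])
      p$a * p$b
    }, numeric(1))
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE))
  structure(list(a = est$a, b = est$b, c_prime = est$c_prime,
                 c_total = est$c_total, indirect = est$a * est$b,
                 ci_low = ci[1L], ci_high = ci[2L], conf = conf,
                 significant = ci[1L] > 0 || ci[2L] < 0,
                 n = n, n_boot = n_boot, seed = seed,
                 covariates = colnames(C), boot = boot),
            class = "mediation_fit")
}

# OLS path coefficients for one sample (standardized inputs assumed).
mediation_paths <- function(xs, ms, ys, C = NULL) {
  X1 <- cbind(1, xs, C)
  X2 <- cbind(1, ms, xs, C)
  a <- .lm.fit(X1, ms)$coefficients[2L]
  cf2 <- .lm.fit(X2, ys)$coefficients
  c_total <- .lm.fit(X1, ys)$coefficients[2L]
  list(a = a, b = cf2[2L], c_prime = cf2[3L], c_total = c_total)
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("Mediation (product of coefficients, percentile bootstrap)\n")
  cat(sprintf("  a = %.4f, b = %.4f, c' = %.4f, c = %.4f\n",
              x$a, x$b, x$c_prime, x$c_total))
  cat(sprintf("  indirect a*b = %.4f, %d%% CI [%.4f, %.4f]%s (n = %d, %d resamples)\n",
              x$indirect, round(100 * x$conf), x$ci_low, x$ci_high,
              if (x$significant) " *" else "", x$n, x$n_boot))
  invisible(x)
}

#' @export
coef.mediation_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c_prime = object$c_prime,
    c_total = object$c_total, indirect = object$indirect)
}

#' Moderation analysis (group x exposure interaction)
#'
#' OLS of the outcome on exposure, group, their interaction and covariates;
#' a significantly nonzero interaction coefficient means the exposure-outcome
#' slope differs between groups.
#'
#' @param x exposure vector (standardized internally).
#' @param group two-level factor.
#' @param y outcome vector (standardized internally).
#' @param covariates optional covariates.
#' @return A `moderation_fit`: `interaction_beta`, `p`, plus the full lm fit.
#' @export
fit_moderation <- function(x, group, y, covariates = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("degenerate moderator: group is constant")
  n <- length(y)
  C <- expand_covariates(covariates, n)
  dat <- data.frame(y = as.numeric(scale(y)), x = as.numeric(scale(x)),
                    group = group)
  form <- if (is.null(C)) y ~ x * group else y ~ x * group + C
  fit <- stats::lm(form, data = dat)
  sm <- stats::summary.lm(fit)$coefficients
  row <- grep(":", rownames(sm))[1L]
  structure(list(interaction_beta = sm[row, 1L], p = sm[row, 4L], lm = fit),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("Moderation: interaction beta = %.4f, p = %.4g\n",
              x$interaction_beta, x$p))
  invisible(x)
}

#' Run one of the four path models
#'
#' The four models relating age, MST integration (leaf fraction as the
#' representative tree metric) and behavior:
#' \describe{
#'   \item{1}{Mediation age -> leaf fraction -> working memory & executive
#'     function, healthy controls only.}
#'   \item{2}{The same mediation in both groups combined (group entered as a
#'     covariate).}
#'   \item{3}{Mediation age -> leaf fraction -> the three symptom factors
#'     (psychotic, negative, disorganization), patients only; medication
#'     entered as a covariate.}
#'   \item{4}{Moderation: does group moderate the age -> leaf fraction
#'     slope (age x group interaction), both groups.}
#' }
#' Head motion and gender are covariates in every model. Cognitive composites
#' are built from the six test columns when not already present.
#'
#' @param metrics `data.frame` with `subject_id` and `Lf` columns (from
#'   [cohort_metrics()]).
#' @param phenotypes phenotype `data.frame` (see [generate_cohort()]).
#' @param model_id integer 1-4.
#' @param mediator metric column used as mediator (default `"Lf"`); set to
#'   `"pc1"` to use the first principal component of the six global metrics
#'   as a latent network-structure score.
#' @param n_boot,seed,conf passed to [fit_mediation()].
#' @return for models 1-3 a named list of `mediation_fit` objects (one per
#'   outcome); for model 4 a `moderation_fit`.
#' @export
run_mediation_model <- function(metrics, phenotypes, model_id,
                                mediator = "Lf", n_boot = 5000, seed = 1L,
                                conf = 0.95) {
  if (!model_id %in% 1:4) stop("model_id must be 1, 2, 3 or 4")
  dat <- merge(phenotypes, metrics, by = "subject_id", sort = TRUE)
  if (mediator == "pc1") {
    six <- scale(as.matrix(dat[c("L", "Lf", "Th", "Dmax", "r", "kappa")]))
    pc <- stats::prcomp(six, center = FALSE, scale. = FALSE)
    dat$pc1 <- pc$x[, 1L] * sign(stats::cor(pc$x[, 1L], dat$Lf))
  }
  med <- dat[[mediator]]
  cog_tests <- list(
    working_memory = c("wms_digit_span", "wms_symbol_span", "wms_letter_number"),
    executive_function = c("dkefs_verbal_fluency", "cpt_dprime", "stroop_conflict"))
  if (model_id %in% 1:2 && !all(c("working_memory", "executive_function") %in% names(dat))) {
    fm <- extract_factors(dat[unlist(cog_tests)], cog_tests)
    dat$working_memory <- fm$scores$working_memory
    dat$executive_function <- fm$scores$executive_function
  }
  base_cov <- data.frame(motion = dat$motion, gender = as.factor(dat$gender))
  if (model_id == 1L) {
    sel <- dat$group == "control"
    fit_mediation(dat$age[sel], med[sel],
                  dat[sel, c("working_memory", "executive_function")],
                  covariates = base_cov[sel, ], n_boot = n_boot, seed = seed,
                  conf = conf)
  } else if (model_id == 2L) {
    cov2 <- cbind(base_cov, group = as.factor(dat$group))
    fit_mediation(dat$age, med,
                  dat[c("working_memory", "executive_function")],
                  covariates = cov2, n_boot = n_boot, seed = seed, conf = conf)
  } else if (model_id == 3L) {
    sel <- dat$group == "patient"
    cov3 <- cbind(base_cov, medication = dat$medication)[sel, ]
    fit_mediation(dat$age[sel], med[sel],
                  dat[sel, c("psychotic_symptom", "negative_symptom", "disorganization")],
                  covariates = cov3, n_boot = n_boot, seed = seed, conf = conf)
  } else {
    fit_moderation(dat$age, dat$group, med, covariates = base_cov)
  }
}
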