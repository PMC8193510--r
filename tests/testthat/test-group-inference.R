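test_that("without covariates the test matches exact enumeration on a tiny sample", {
  # n = 8, groups of 4: 70 label splits; exact p by enumeration
  y <- c(1.2, 0.3, -0.5, 2.1, -1.0, 0.4, 1.7, -0.2)
  g <- rep(c("a", "b"), each = 4)
  obs <- mean(y[5:8]) - mean(y[1:4])
  splits <- combn(8, 4)
  exact <- mean(apply(splits, 2, function(idx) {
    abs(mean(y[-idx]) - mean(y[idx])) >= abs(obs) - 1e-12
  }))
  res <- covariate_adjusted_permutation_test(y, g, n_perm = 20000, seed = 1)
  expect_equal(res$observed_stat, obs)
  expect_equal(res$p_value, exact, tolerance = 0.02)
  # freedman-lane and raw label permutation agree when there is nothing to adjust
  res_raw <- covariate_adjusted_permutation_test(y, g, n_perm = 20000, seed = 1,
                                                 method = "raw")
  expect_equal(res$p_value, res_raw$p_value, tolerance = 0.02)
})

test_that("permutation p-values are invariant to affine rescaling", {
  set.seed(61)
  n <- 40
  y <- rnorm(n)
  g <- rep(c("a", "b"), each = n / 2)
  cov <- cbind(age = rnorm(n), motion = rexp(n))
  r1 <- covariate_adjusted_permutation_test(y, g, cov, n_perm = 300, seed = 2)
  r2 <- covariate_adjusted_permutation_test(10 * y + 3, g,
                                            sweep(cov, 2, c(2, 0.1), `*`),
                                            n_perm = 300, seed = 2)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r2$observed_stat, 10 * r1$observed_stat)
})

test_that("rank-deficient or collinear designs are named errors", {
  y <- rnorm(20); g <- rep(c("a", "b"), 10)
  cov <- cbind(x = 1:20, x2 = 2 * (1:20))
  expect_error(covariate_adjusted_permutation_test(y, g, cov), "rank-deficient")
  expect_error(covariate_adjusted_permutation_test(y, g,
               cbind(gnum = as.numeric(g == "b"))), "collinear")
})

test_that("a planted shift at the reference sample size is reliably detected", {
  set.seed(62)
  p <- replicate(20, {
    y <- c(rnorm(40), rnorm(40, mean = 1))   # 1 SD shift, n = 40 + 40
    g <- rep(c("c", "p"), each = 40)
    cov <- cbind(age = rnorm(80))
    covariate_adjusted_permutation_test(y, g, cov, n_perm = 500,
                                        seed = sample.int(1e6, 1))$p_value
  })
  expect_lt(median(p), 0.01)
})

test_that("group_metric_tests applies a single BH family and drops undefined metrics", {
  set.seed(63)
  n <- 30
  metrics <- data.frame(m1 = rnorm(n), m2 = rnorm(n), bad = rep(NA_real_, n))
  g <- rep(c("a", "b"), each = n / 2)
  expect_warning(res <- group_metric_tests(metrics, g, n_perm = 99, seed = 3),
                 "undefined")
  expect_equal(res$metric, c("m1", "m2"))
  expect_equal(res$p_fdr, fdr_bh(res$p_raw))
  expect_true(all(res$p_fdr >= res$p_raw))
})

test_that("BH step-up adjustment matches hand computation", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(0.05, 6)), rep(0.05, 6))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  hand <- pmin(1, rev(cummin(rev(sort(p) * 5 / (1:5)))))  # step-up rule
  expect_equal(fdr_bh(p)[order(p)], hand)
})

test_that("metric intercorrelations carry the integration continuum signs", {
  set.seed(64)
  mets <- do.call(rbind, lapply(runif(60, 0.1, 0.9), function(b)
    as.data.frame(global_metrics(generate_tree_topology(50, b)))))
  cm <- metric_intercorrelation(mets[c("L", "Lf", "kappa")])
  expect_equal(diag(cm), rep(1, 3), ignore_attr = TRUE)
  expect_lt(cm["Lf", "L"], 0)
  expect_gt(cm["Lf", "kappa"], 0)
  expect_warning(metric_intercorrelation(cbind(mets[c("L", "Lf")], const = 1)),
                 "constant")
})

test_that("partial correlation matches the precision-matrix closed form", {
  set.seed(65)
  # trivariate Gaussian with known precision matrix
  Omega <- rbind(c(2, -0.8, -0.5), c(-0.8, 1.5, 0.3), c(-0.5, 0.3, 1.2))
  Sigma <- solve(Omega)
  L <- chol(Sigma)
  X <- matrix(rnorm(10000 * 3), ncol = 3) %*% L
  target <- -Omega[1, 2] / sqrt(Omega[1, 1] * Omega[2, 2])
  est <- partial_correlation(X[, 1], X[, 2], X[, 3, drop = FALSE])
  expect_equal(est$r, target, tolerance = 0.05)
  expect_equal(est$df, 10000 - 1 - 2)
  # no controls reduces to Pearson
  pc <- partial_correlation(X[, 1], X[, 2])
  expect_equal(pc$r, cor(X[, 1], X[, 2]))
  # controlling y by itself kills the correlation
  self <- partial_correlation(X[, 1], X[, 3], X[, 3, drop = FALSE])
  expect_lt(abs(self$r), 1e-10)
})

test_that("bipartite matching minimizes total age difference within strata", {
  pheno <- data.frame(
    subject_id = paste0("s", 1:8),
    group = c(rep("patient", 3), rep("control", 5)),
    age = c(30, 40, 50, 29, 31, 41, 49, 60),
    gender = "M")
  m <- match_cohorts(pheno)
  expect_equal(sum(m$group == "patient"), 3)
  expect_equal(sum(m$group == "control"), 3)
  expect_equal(attr(m, "total_age_cost"), 3)  # exhaustive optimum
  expect_false("s8" %in% m$subject_id)        # age 60 has no close partner
  # already matched cohorts pair at zero cost (exact partner in each stratum)
  ph2 <- data.frame(subject_id = paste0("t", 1:6),
                    group = rep(c("a", "b"), each = 3),
                    age = c(25, 35, 45, 45, 35, 25),
                    gender = rep(c("M", "F", "M"), 2))
  m2 <- match_cohorts(ph2)
  expect_equal(attr(m2, "total_age_cost"), 0)
  expect_equal(nrow(m2), 6)
  # minority outnumbers majority inside a stratum: infeasible, named
  ph3 <- data.frame(subject_id = paste0("u", 1:5),
                    group = c("a", "a", "b", "b", "b"),
                    age = c(30, 40, 35, 20, 50),
                    gender = c("M", "M", "M", "F", "F"))
  expect_error(match_cohorts(ph3), "stratum 'M'")
})

test_that("matched synthetic cohorts are age-balanced", {
  set.seed(66)
  co <- generate_cohort(cohort_spec(n_subjects_per_group = 30, n_nodes = 20,
                                    data = "none", seed = 66))
  m <- match_cohorts(co$phenotypes)
  tt <- t.test(age ~ group, data = m)
  expect_gt(tt$p.value, 0.5)
})
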