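test_that("a noiseless chain with exogenous mediator variation is recovered exactly", {
  set.seed(71)
  n <- 200
  x <- rnorm(n)
  u <- residuals(lm(rnorm(n) ~ x))   # mediator source, orthogonal to x in-sample
  m <- 0.5 * x + sqrt(1 - 0.25) * u
  y <- 0.6 * m + 0.2 * x             # outcome exactly linear: zero noise
  f <- fit_mediation(x, m, y, n_boot = 50, seed = 1)
  # standardized truth from the generative covariances
  sx <- sd(x); sm <- sd(m); sy <- sd(y)
  expect_equal(f$a, 0.5 * sx / sm, tolerance = 1e-10)
  expect_equal(f$b, 0.6 * sm / sy, tolerance = 1e-10)
  expect_equal(f$c_prime, 0.2 * sx / sy, tolerance = 1e-10)
})

test_that("c = c' + a*b holds to machine precision on standardized data", {
  set.seed(72)
  for (i in 1:5) {
    n <- 60
    x <- rnorm(n); m <- 0.4 * x + rnorm(n); y <- 0.5 * m + 0.1 * x + rnorm(n)
    f <- fit_mediation(x, m, y, n_boot = 20, seed = i)
    expect_equal(f$c_total, f$c_prime + f$a * f$b, tolerance = 1e-12)
  }
})

test_that("the vectorized bootstrap equals an explicit refitting loop", {
  set.seed(73)
  n <- 50; B <- 40
  x <- rnorm(n); m <- 0.4 * x + rnorm(n); y <- 0.5 * m + rnorm(n)
  f <- fit_mediation(x, m, y, n_boot = B, seed = 9)
  xs <- as.numeric(scale(x)); ms <- as.numeric(scale(m)); ys <- as.numeric(scale(y))
  set.seed(9)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  manual <- vapply(seq_len(B), function(j) {
    i <- idx[, j]
    a <- coef(lm(ms[i] ~ xs[i]))[2]
    b <- coef(lm(ys[i] ~ ms[i] + xs[i]))[2]
    unname(a * b)
  }, numeric(1))
  expect_equal(f$boot, manual, tolerance = 1e-10)
})

test_that("bootstrap CI endpoints are monotone in the confidence level", {
  set.seed(74)
  n <- 100
  x <- rnorm(n); m <- 0.4 * x + rnorm(n); y <- 0.5 * m + rnorm(n)
  f90 <- fit_mediation(x, m, y, n_boot = 400, seed = 2, conf = 0.90)
  f99 <- fit_mediation(x, m, y, n_boot = 400, seed = 2, conf = 0.99)
  expect_lte(f99$ci_low, f90$ci_low)
  expect_gte(f99$ci_high, f90$ci_high)
})

test_that("an indirect effect can be significant while the total effect is not", {
  # suppression: direct and indirect paths cancel
  set.seed(75)
  n <- 3000
  x <- rnorm(n)
  m <- 0.6 * x + 0.8 * rnorm(n)
  y <- 0.5 * m - 0.3 * x + rnorm(n)
  f <- fit_mediation(x, m, y, n_boot = 600, seed = 3)
  expect_true(f$significant)
  expect_lt(abs(f$c_total), 0.06)
})

test_that("covariates are honored and collinearity is caught", {
  set.seed(76)
  n <- 150
  c1 <- rnorm(n)
  x <- rnorm(n) + c1
  m <- 0.5 * x + 0.8 * c1 + rnorm(n)
  y <- 0.5 * m + rnorm(n)
  f_adj <- fit_mediation(x, m, y, covariates = cbind(c1 = c1),
                         n_boot = 100, seed = 4)
  # adjusted a matches the partial regression coefficient from lm
  ref <- coef(lm(scale(m) ~ scale(x) + scale(c1)))[2]
  expect_equal(f_adj$a, unname(ref), tolerance = 1e-10)
  expect_error(fit_mediation(x, m, y, covariates = cbind(a = c1, b = 2 * c1),
                             n_boot = 50, seed = 1), "collinear")
})

test_that("composite factors average the assigned z-scored tests", {
  set.seed(77)
  latent <- rnorm(120)
  tests <- data.frame(t1 = 2 * latent + 5, t2 = -1 + 0.5 * latent,
                      t3 = latent * 3)
  fm <- extract_factors(tests, list(f = c("t1", "t2", "t3")))
  expect_equal(abs(cor(fm$scores$f, latent)), 1, tolerance = 1e-12)
  expect_equal(mean(fm$scores$f), 0, tolerance = 1e-12)
  expect_equal(sd(fm$scores$f), 1, tolerance = 1e-12)
  # a single assigned test is just that test standardized
  fm1 <- extract_factors(tests, list(f = "t1"))
  expect_equal(fm1$scores$f, as.numeric(scale(tests$t1)))
})

test_that("EFA recovers a planted 3-factor block structure", {
  set.seed(78)
  n <- 500
  lat <- matrix(rnorm(n * 3), n, 3)
  tests <- do.call(cbind, lapply(1:3, function(k)
    sapply(1:3, function(j) 0.8 * lat[, k] + 0.6 * rnorm(n))))
  colnames(tests) <- paste0("t", 1:9)
  fm <- extract_factors(as.data.frame(tests), 3, method = "efa")
  L <- abs(fm$loadings)
  # each test's dominant loading is on its own block's factor
  block <- rep(1:3, each = 3)
  dominant <- apply(L, 1, which.max)
  expect_true(all(tapply(dominant, block, function(d) length(unique(d))) == 1))
  expect_true(all(L[cbind(1:9, dominant)] > 0.6))
  cross <- L; cross[cbind(1:9, dominant)] <- NA
  expect_true(all(cross < 0.3, na.rm = TRUE))
})

test_that("moderation detects a planted slope difference and rejects constants", {
  set.seed(79)
  p <- replicate(50, {
    x <- rnorm(80)
    g <- rep(c("a", "b"), each = 40)
    y <- 0.3 * x + 0.5 * x * (g == "b") + rnorm(80)
    fit_moderation(x, g, y)$p
  })
  expect_lt(median(p), 0.05)
  # equal slopes: calibrated p-values
  p0 <- replicate(60, {
    x <- rnorm(60); g <- rep(c("a", "b"), each = 30)
    fit_moderation(x, g, 0.3 * x + rnorm(60))$p
  })
  expect_gt(suppressWarnings(ks.test(p0, "punif"))$p.value, 0.001)
  expect_error(fit_moderation(rnorm(10), rep("a", 10), rnorm(10)), "degenerate")
})

test_that("the four model wrappers select the right subsamples", {
  set.seed(80)
  co <- generate_cohort(cohort_spec(n_subjects_per_group = 25, n_nodes = 30,
                                    data = "none", seed = 80))
  mets <- cohort_metrics(co$trees)
  m1 <- run_mediation_model(mets, co$phenotypes, 1, n_boot = 50, seed = 1)
  expect_named(m1, c("working_memory", "executive_function"))
  expect_equal(m1$working_memory$n, 25)
  m2 <- run_mediation_model(mets, co$phenotypes, 2, n_boot = 50, seed = 1)
  expect_equal(m2$working_memory$n, 50)
  m3 <- run_mediation_model(mets, co$phenotypes, 3, n_boot = 50, seed = 1)
  expect_named(m3, c("psychotic_symptom", "negative_symptom", "disorganization"))
  expect_equal(m3$negative_symptom$n, 25)
  expect_true("medication" %in% sub("[0-9]*$", "", m3$negative_symptom$covariates) ||
                any(grepl("medication", m3$negative_symptom$covariates)))
  m4 <- run_mediation_model(mets, co$phenotypes, 4, n_boot = 50, seed = 1)
  expect_s3_class(m4, "moderation_fit")
  expect_error(run_mediation_model(mets, co$phenotypes, 5), "model_id")
  # pc1 latent network-structure mediator is accepted
  m3b <- run_mediation_model(mets, co$phenotypes, 3, mediator = "pc1",
                             n_boot = 50, seed = 1)
  expect_s3_class(m3b$negative_symptom, "mediation_fit")
})
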