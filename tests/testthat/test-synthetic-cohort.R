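test_that("tree generator hits its limiting topologies", {
  expect_equal(leaf_fraction(generate_tree_topology(10, 1, seed = 0)), 0.9)
  expect_equal(max_degree(generate_tree_topology(10, 1, seed = 0)), 9)
  expect_equal(leaf_fraction(generate_tree_topology(10, 0, seed = 0)), 0.2)
  expect_equal(max_degree(generate_tree_topology(10, 0, seed = 0)), 2)
  expect_error(generate_tree_topology(3, 0.5), "at least 4")
})

test_that("expected leaf fraction is monotone in star bias", {
  set.seed(90)
  mean_lf <- sapply(c(0.2, 0.5, 0.8), function(b)
    mean(replicate(200, leaf_fraction(generate_tree_topology(50, b)))))
  expect_true(all(diff(mean_lf) > 0))
})

test_that("tree-structured covariance is SPD with dominant tree edges", {
  set.seed(91)
  for (b in c(0.2, 0.95)) {
    t <- generate_tree_topology(40, b)
    S <- tree_to_covariance(t, edge_strength = 0.6, baseline = 0.1)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_equal(diag(S), rep(1, 40), ignore_attr = TRUE)
    on_tree <- S[t$edges]
    off <- S[upper.tri(S)]
    expect_gt(min(on_tree), max(setdiff(off, on_tree)))
  }
  expect_error(tree_to_covariance(generate_tree_topology(10, 0.5, seed = 1),
                                  edge_strength = 0.3, baseline = 0.4))
})

test_that("the MST of the noise-free covariance is the planted tree", {
  set.seed(92)
  t <- generate_tree_topology(40, 0.6)
  S <- tree_to_covariance(t)
  mst <- suppressWarnings(kruskal_mst(to_distance(connectivity_matrix(S))))
  expect_equal(tree_overlap(mst, t), 1)
})

test_that("long sampled series recover the planted tree through the full pipeline", {
  co <- generate_cohort(cohort_spec(n_subjects_per_group = 2, n_nodes = 40,
                                    n_timepoints = 5000, seed = 93))
  ov <- vapply(co$phenotypes$subject_id, function(id)
    tree_overlap(kruskal_mst(to_distance(co$connectivity[[id]])),
                 co$trees[[id]]), numeric(1))
  expect_true(all(ov >= 0.9))
})

test_that("cohorts are reproducible and structurally complete", {
  spec <- cohort_spec(n_subjects_per_group = 6, n_nodes = 20, data = "none",
                      seed = 94)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$truth, c2$truth)
  ph <- c1$phenotypes
  expect_equal(nrow(ph), 12)
  expect_equal(sum(ph$group == "control"), 6)
  expect_true(all(ph$age >= 21 & ph$age <= 55))
  expect_true(all(ph$medication[ph$group == "control"] == 0))
  expect_true(all(ph$medication[ph$group == "patient"] > 0))
  expect_true(all(c("wms_digit_span", "stroop_conflict", "negative_symptom",
                    "disorganization") %in% names(ph)))
  expect_length(c1$trees, 12)
  expect_true(all(vapply(c1$trees, function(t) t$n, integer(1)) == 20))
})

test_that("age drives planted leaf fraction when the a path is positive", {
  co <- generate_cohort(cohort_spec(n_subjects_per_group = 100, n_nodes = 50,
                                    star_bias_age_slope = 0.3,
                                    star_bias_group_offset = 0,
                                    noise_sd_topology = 0.02,
                                    data = "none", seed = 95))
  ok <- !co$truth$clipped
  expect_gt(cor(co$phenotypes$age[ok], co$truth$leaf_fraction[ok]), 0)
})

test_that("with all planted slopes zero the indirect effect is null-calibrated", {
  set.seed(98)
  covers <- replicate(100, {
    co <- generate_cohort(cohort_spec(n_subjects_per_group = 15, n_nodes = 16,
                                      star_bias_age_slope = 0,
                                      star_bias_group_offset = 0,
                                      symptom_lf_slope = 0,
                                      symptom_direct_age_slope = 0,
                                      data = "none", seed = sample.int(1e6, 1)))
    f <- fit_mediation(co$phenotypes$age, co$truth$leaf_fraction,
                       co$phenotypes$negative_symptom, n_boot = 200,
                       seed = sample.int(1e6, 1))
    !f$significant
  })
  expect_gte(mean(covers), 0.90)
})

test_that("clipping of the star bias is recorded per subject", {
  co <- generate_cohort(cohort_spec(n_subjects_per_group = 20, n_nodes = 20,
                                    star_bias_base = 0.95,
                                    star_bias_group_offset = 0.1,
                                    noise_sd_topology = 0.2,
                                    data = "none", seed = 96))
  expect_true(any(co$truth$clipped))
  expect_true(all(co$truth$star_bias >= 0 & co$truth$star_bias <= 1))
})

test_that("cohorts round-trip through the on-disk layout", {
  co <- generate_cohort(cohort_spec(n_subjects_per_group = 3, n_nodes = 12,
                                    n_timepoints = 60, seed = 97))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("phenotypes.csv", "manifest.csv", "truth.json")))))
  back <- read_cohort(dir)
  expect_equal(back$phenotypes$subject_id, co$phenotypes$subject_id)
  id <- co$phenotypes$subject_id[1]
  expect_equal(back$connectivity[[id]]$z, co$connectivity[[id]]$z,
               tolerance = 1e-10)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth$trees, 6)
})
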