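test_that("transforms are exact and invert to 1e-12", {
  expect_equal(transform_marker(8, "cbrt"), 2)
  expect_equal(transform_marker(16, "sqrt"), 4)
  expect_equal(transform_marker(1, "ln"), 0)
  expect_equal(transform_marker(2.5, "identity"), 2.5)
  set.seed(1)
  x <- runif(200, 1e-6, 1e3)
  for (fam in c("sqrt", "cbrt", "ln", "identity"))
    expect_equal(inverse_transform(transform_marker(x, fam), fam), x,
                 tolerance = 1e-12)
  expect_error(transform_marker(-1, "sqrt"), ">= 0")
  expect_error(transform_marker(0, "ln"), "offset_zeros")
})

test_that("zero offsetting for log densities uses half the smallest positive", {
  x <- c(0, 2, 4, 0, 8)
  ox <- offset_zeros(x)
  expect_equal(attr(ox, "zero_offset"), 1)
  expect_equal(as.numeric(ox), c(1, 2, 4, 1, 8))
  clean <- offset_zeros(c(1, 2))
  expect_equal(attr(clean, "zero_offset"), 0)
  expect_error(offset_zeros(c(-1, 2)), "negative")
})

test_that("marker and exposure transform families match the analysis plan", {
  tf <- default_transforms()
  expect_equal(unname(tf[c("pv_cm3", "upvv_cm3")]), c("cbrt", "cbrt"))
  expect_true(all(tf[c("end_points", "bifurcation_points", "crossing_points",
                       "vessel_points", "total_length_mm",
                       "avg_thickness_mm")] == "sqrt"))
  expect_true(all(tf[grep("^density", names(tf))] == "ln"))
  xf <- default_exposure_transforms()
  expect_equal(unname(xf["seng"]), "identity")
  expect_true(all(xf[c("plgf", "sflt1", "sflt1_plgf_ratio",
                       "seng_plgf_ratio")] == "ln"))
})

test_that("Student t on a toy sample equals the hand formula", {
  a <- c(4.1, 5.0, 6.2, 5.5); b <- c(7.0, 8.1, 6.9, 7.7)
  res <- compare_groups(c(a, b), rep(c("x", "y"), each = 4))
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(abs(res$t_statistic), abs(t_hand), tolerance = 1e-12)
  expect_equal(res$df, 6)
  expect_equal(res$summary$median, c(median(a), median(b)))
  expect_equal(res$summary$iqr, c(IQR(a), IQR(b)))

  # gross separation
  set.seed(2)
  sep <- compare_groups(c(rnorm(20), rnorm(20) + 10), rep(0:1, each = 20))
  expect_lt(sep$p_value, 1e-6)
  expect_error(compare_groups(1:5, rep("a", 5)), "two levels")
  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("t-test p-values are calibrated under the null", {
  set.seed(11)
  p <- replicate(400, compare_groups(rnorm(40), rep(0:1, 20))$p_value)
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.035)
})

test_that("trajectory model recovers an injected effect in the noiseless limit", {
  sds <- modifyList(placvasc:::default_marker_sd(),
                    list(upvv_cm3 = c(1e-8, 1e-8)))
  coh <- generate_cohort(cohort_config(
    n_subjects = 60, effects = list(plgf = c(upvv_cm3 = 0.39)),
    marker_sd = sds, seed = 8))
  fit <- fit_trajectory_model(coh, "upvv_cm3", "plgf", "model2")
  expect_lt(abs(fit$beta - 0.39), 1e-6)
  expect_true(fit$ci_low <= fit$beta && fit$beta <= fit$ci_high)
})

test_that("model results carry honest metadata", {
  coh <- generate_cohort(cohort_config(n_subjects = 60, seed = 21))
  f1 <- fit_trajectory_model(coh, "total_length_mm", "sflt1", "model1")
  expect_equal(f1$n_subjects, 60L)
  expect_equal(f1$n_observations, nrow(coh$visits))
  expect_gt(f1$p_value, 0); expect_lte(f1$p_value, 1)
  expect_true(is.logical(f1$converged))
  expect_error(fit_trajectory_model(coh, "nope", "plgf"), "unknown marker")
  expect_error(fit_trajectory_model(coh, "pv_cm3", "nope"), "unknown biomarker")
})

test_that("association_table covers requested models and pairs", {
  coh <- generate_cohort(cohort_config(n_subjects = 60, seed = 31))
  tab <- association_table(coh, markers = c("pv_cm3", "upvv_cm3"),
                           biomarkers = c("plgf", "seng"),
                           models = "model1")
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$ci_low <= tab$beta & tab$beta <= tab$ci_high))
})

test_that("stratified correlations: exact linearity, null levels, null difference", {
  coh <- generate_cohort(cohort_config(n_subjects = 100, seed = 17))
  # force an exactly linear relation in one stratum check
  res <- stratified_correlation(coh, "upvv_cm3", "plgf", "fetal_sex")
  expect_equal(nrow(res$correlations), 2L)
  expect_true(all(abs(res$correlations$r) <= 1))
  expect_true(all(res$differences$p_value > 0 & res$differences$p_value <= 1))

  # perfectly linear pair gives r = 1
  coh2 <- coh
  coh2$visits$upvv_cm3 <-
    (log(coh2$subjects$plgf)[match(coh2$visits$subject_id,
                                   coh2$subjects$subject_id)])^3
  r2 <- stratified_correlation(coh2, "upvv_cm3", "plgf", "fetal_sex")
  expect_equal(r2$correlations$r, c(1, 1), tolerance = 1e-9)

  # independence: |r| small in nearly all replicates
  rs <- vapply(1:20, function(i) {
    c0 <- generate_cohort(cohort_config(n_subjects = 100, seed = 800 + i))
    stratified_correlation(c0, "upvv_cm3", "seng",
                           "any_complication")$correlations$r[1]
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.3), 0.95)

  # identical coupling in both strata: difference mostly non-significant
  ps <- vapply(1:20, function(i) {
    c0 <- generate_cohort(cohort_config(
      n_subjects = 120, effects = list(plgf = c(upvv_cm3 = 0.39)),
      seed = 900 + i))
    d <- stratified_correlation(c0, "upvv_cm3", "plgf", "fetal_sex")$differences
    d$p_value[1]
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("degenerate strata report missing correlations", {
  coh <- generate_cohort(cohort_config(n_subjects = 40, seed = 55))
  coh$visits$upvv_cm3 <- 2.5  # constant marker
  res <- stratified_correlation(coh, "upvv_cm3", "plgf", "fetal_sex")
  expect_true(all(is.na(res$correlations$r)))
})

test_that("recovery harness reports bias, coverage and convergence", {
  r <- recover_parameters(0.39, "upvv_cm3", "plgf", n_replicates = 25,
                          model = "model1", n_subjects = 120, seed = 77)
  expect_equal(r$n_replicates, 25)
  expect_lt(abs(r$bias), 4 * r$mc_se + 0.02)
  expect_gte(r$coverage, 0.8)
  expect_lte(r$nonconvergence_rate, 0.1)
  expect_false(r$flagged)
  # wider residual noise widens the sampling spread (monotonicity)
  expect_gt(r$mc_se, 0)
})
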