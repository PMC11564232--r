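test_that("pregnancy dating follows the clinical rules", {
  # fresh IVF: oocyte pick-up + 14 days
  expect_equal(date_pregnancy("ivf_fresh", ref_date = 100, opu_date = 44), 70)
  # cryo transfer + 19 days
  expect_equal(date_pregnancy("cryo", ref_date = 100, transfer_date = 49), 70)
  # LMP with regular cycle
  expect_equal(date_pregnancy("lmp", ref_date = 100, lmp_date = 30,
                              cycle_length = 28), 70)
  # LMP vs CRL discrepancy > 6 days: CRL wins
  expect_equal(date_pregnancy("lmp", ref_date = 100, lmp_date = 20,
                              cycle_length = 28, crl_ga_days = 72), 72)
  # discrepancy <= 6 days: LMP stands
  expect_equal(date_pregnancy("lmp", ref_date = 100, lmp_date = 25,
                              cycle_length = 28, crl_ga_days = 72), 75)
  # irregular cycle without CRL
  expect_error(date_pregnancy("lmp", ref_date = 100, lmp_date = 30,
                              cycle_length = 40), "CRL required")
  expect_equal(date_pregnancy("lmp", ref_date = 100, lmp_date = 30,
                              cycle_length = 40, crl_ga_days = 68), 68)
  expect_equal(date_pregnancy("crl", ref_date = 100, crl_ga_days = 66), 66)
  expect_error(date_pregnancy("ivf_fresh", ref_date = 100), "opu_date")
})

test_that("exclusion rules reproduce the enrolment flow", {
  reasons <- c(rep("withdrawal", 1), rep("miscarriage", 22),
               rep("oocyte_donation", 4), rep("missing_serum", 29),
               rep(NA_character_, 185))
  man <- data.frame(subject_id = sprintf("P%03d", seq_along(reasons)),
                    excluded_reason = reasons, stringsAsFactors = FALSE)
  res <- apply_exclusions(man)
  expect_equal(res$n_enrolled, 241L)
  expect_equal(res$n_excluded, 56L)
  expect_equal(nrow(res$included), 185L)
  expect_equal(unname(res$counts),
               c(1L, 22L, 4L, 29L))

  none <- data.frame(subject_id = "a", excluded_reason = NA_character_)
  expect_equal(nrow(apply_exclusions(none)$included), 1L)
  all_out <- data.frame(subject_id = c("a", "b"),
                        excluded_reason = c("miscarriage", "miscarriage"))
  expect_equal(nrow(apply_exclusions(all_out)$included), 0L)
  expect_error(apply_exclusions(data.frame(excluded_reason = "vanished")),
               "unknown")
})

test_that("complication labels follow the clinical definitions exactly", {
  lat <- data.frame(
    sbp_mmhg =            c(142, 139, 135, 150, 120, 120),
    dbp_mmhg =            c(85,  92,  85,  95,  70,  70),
    hypertension_after_20w = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    proteinuria_mg24h =   c(100, 350, 500, 300, 50,  50),
    growth_pct_1 =        c(50,  50,  40,  50,  35,  50),
    growth_pct_2 =        c(50,  50,  9,   50,  12,  50),
    bw_pct =              c(50,  50,  50,  9.9, 50,  50),
    ga_at_birth_days =    c(280, 280, 280, 280, 258, 259))
  out <- assign_outcomes(lat)
  expect_equal(out$pih, c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  # PE requires PIH plus >= 300 mg proteinuria
  expect_equal(out$pe,  c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_true(all(!out$pe | out$pih))
  # FGR: percentile < 10 or > 20-point drop
  expect_equal(out$fgr, c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$sga, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  # PTB strictly before 37+0 weeks = 259 days
  expect_equal(out$ptb, c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$any_complication,
               out$pih | out$pe | out$fgr | out$sga | out$ptb)
  expect_error(assign_outcomes(lat[, -1]), "missing latent")
})

test_that("generated cohorts satisfy their structural invariants", {
  coh <- generate_cohort(cohort_config(n_subjects = 120, seed = 42))
  s <- coh$subjects; v <- coh$visits
  expect_equal(nrow(s), 120L)
  expect_equal(s$sflt1_plgf_ratio, s$sflt1 / s$plgf)
  expect_equal(s$seng_plgf_ratio, s$seng / s$plgf)
  expect_true(all(s$plgf > 0 & s$sflt1 > 0 & s$seng > 0))
  expect_true(all(!s$pe | s$pih))
  expect_equal(s$any_complication, s$pih | s$pe | s$fgr | s$sga | s$ptb)
  # 2-3 visits, GA strictly increasing within subject
  nv <- table(v$subject_id)
  expect_true(all(nv >= 2 & nv <= 3))
  expect_true(all(tapply(v$ga_days, v$subject_id,
                         function(g) all(diff(g) > 0))))
  expect_true(all(v$ga_days > 40 & v$ga_days < 85))
  # markers positive on the natural scale
  for (m in placvasc:::MARKER_NAMES) expect_true(all(v[[m]] > 0))
  # determinism
  expect_identical(coh$visits,
                   generate_cohort(cohort_config(n_subjects = 120, seed = 42))$visits)
})

test_that("noiseless generation reproduces the quadratic trajectory", {
  sds <- lapply(placvasc:::default_marker_sd(), function(x) c(1e-9, 1e-9))
  zero <- setNames(rep(0, 9), names(placvasc:::default_covariate_effects()))
  coh <- generate_cohort(cohort_config(n_subjects = 30, marker_sd = sds,
                                       covariate_effects = zero, seed = 5))
  co <- placvasc:::traj_coef(placvasc:::default_trajectories()$upvv_cm3)
  g <- coh$visits$ga_days - 63
  pred <- co["a0"] + co["a1"] * g + co["a2"] * g^2
  expect_equal(transform_marker(coh$visits$upvv_cm3, "cbrt"),
               unname(pred), tolerance = 1e-6)
})

test_that("injected coupling is visible to an independent OLS oracle", {
  # subject-mean cbrt(uPVV) regressed on ln PlGF across replicate cohorts
  beta <- 0.39
  slopes <- vapply(1:30, function(i) {
    coh <- generate_cohort(cohort_config(
      n_subjects = 80, effects = list(plgf = c(upvv_cm3 = beta)),
      seed = 300 + i))
    ym <- tapply(coh$visits$upvv_cm3^(1 / 3), coh$visits$subject_id, mean)
    x <- log(coh$subjects$plgf)[match(names(ym), coh$subjects$subject_id)]
    unname(coef(lm(ym ~ x))[2])
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - beta), 3 * mc_se + 0.02)
})

test_that("complication prevalence is near the quarter of the cohort", {
  prev <- vapply(1:4, function(i)
    mean(generate_cohort(cohort_config(seed = 700 + i))$subjects$any_complication),
    numeric(1))
  expect_gt(mean(prev), 0.15)
  expect_lt(mean(prev), 0.40)
})

test_that("cohort CSVs round-trip", {
  coh <- generate_cohort(cohort_config(n_subjects = 15, seed = 3))
  d <- tempfile(); dir.create(d)
  write_cohort(coh, d)
  s2 <- read.csv(file.path(d, "subjects.csv"))
  v2 <- read.csv(file.path(d, "visits.csv"))
  expect_equal(nrow(s2), 15L)
  expect_equal(v2$upvv_cm3, coh$visits$upvv_cm3)
  unlink(d, recursive = TRUE)
})
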