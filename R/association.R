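# Statistical stage: variable transformations, longitudinal linear mixed
# models with a quadratic GA trend (model 1: GA only; model 2: GA plus the
# nine maternal covariates), biomarker group comparisons, stratified
# correlations, and the simulation-based parameter-recovery harness.

#' Marker and exposure transformations
#'
#' Analysis-scale transforms: cube root for volumetric markers (PV, uPVV),
#' square root for counts, length and thickness, natural log for densities.
#' Exposures: log for PlGF, sFlt-1 and both ratios; sEng enters untransformed
#' (as in the reported models).
#'
#' @param x Numeric vector.
#' @param family One of "sqrt", "cbrt", "ln", "identity".
#' @return Transformed (or back-transformed) values.
#' @export
transform_marker <- function(x, family = c("sqrt", "cbrt", "ln", "identity")) {
  family <- match.arg(family)
  switch(family,
    sqrt = {
      if (any(x < 0)) stop("sqrt transform needs x >= 0")
      sqrt(x)
    },
    cbrt = {
      if (any(x < 0)) stop("cbrt transform needs x >= 0")
      x^(1 / 3)
    },
    ln = {
      if (any(x <= 0))
        stop("ln transform needs x > 0; zero counts must be offset first ",
             "(see offset_zeros)")
      log(x)
    },
    identity = x)
}

#' @rdname transform_marker
#' @export
inverse_transform <- function(x, family = c("sqrt", "cbrt", "ln", "identity")) {
  family <- match.arg(family)
  switch(family, sqrt = x^2, cbrt = x^3, ln = exp(x), identity = x)
}

#' Default transform families per marker
#' @return Named character vector over the 11 marker columns.
#' @export
default_transforms <- function() {
  c(pv_cm3 = "cbrt", upvv_cm3 = "cbrt", end_points = "sqrt",
    bifurcation_points = "sqrt", crossing_points = "sqrt",
    vessel_points = "sqrt", total_length_mm = "sqrt",
    avg_thickness_mm = "sqrt", density_end = "ln",
    density_bifurcation = "ln", density_crossing = "ln")
}

#' @rdname default_transforms
#' @export
default_exposure_transforms <- function() {
  c(plgf = "ln", sflt1 = "ln", seng = "identity",
    sflt1_plgf_ratio = "ln", seng_plgf_ratio = "ln")
}

#' Offset zeros before a log transform
#'
#' Density markers are zero only when the corresponding count is zero (uPVV
#' is positive whenever a skeleton exists); zeros are replaced by half the
#' smallest positive observed value, and the offset is recorded.
#'
#' @param x Non-negative numeric vector.
#' @return `x` with zeros offset; attribute `zero_offset` (0 if unused).
#' @export
offset_zeros <- function(x) {
  if (any(x < 0)) stop("negative values cannot be log-transformed")
  if (any(x == 0)) {
    pos <- x[x > 0]
    if (!length(pos)) stop("all values zero: log scale undefined")
    off <- min(pos) / 2
    x[x == 0] <- off
    attr(x, "zero_offset") <- off
  } else attr(x, "zero_offset") <- 0
  x
}

MODEL2_COVARIATES <- c("age", "bmi", "nulliparous", "conception_mode",
                       "fetal_sex", "smoking", "alcohol", "folic_acid")

#' Fit the longitudinal trajectory mixed model
#'
#' Linear mixed model for a transformed marker trajectory over gestation:
#' fixed effects are centred GA (at 63 days) and its square, the transformed
#' 11-week biomarker (constant within subject), and, for model 2, maternal
#' age, BMI, parity, conception mode, fetal sex, smoking, alcohol and folic
#' acid use; the random effect is a subject intercept. REML estimation; the
#' exposure coefficient is reported with a Wald 95% CI and normal-theory
#' p-value.
#'
#' @param cohort A [generate_cohort()] result, or a list with `subjects` and
#'   `visits` data.frames of the same layout.
#' @param marker Marker column name (see [default_transforms()]).
#' @param biomarker Exposure name (see [default_exposure_transforms()]).
#' @param model "model1" (GA only) or "model2" (GA + covariates).
#' @return List: `beta`, `se`, `ci_low`, `ci_high`, `p_value`, `n_subjects`,
#'   `n_observations`, `converged`, and the `fit` object.
#' @export
fit_trajectory_model <- function(cohort, marker, biomarker,
                                 model = c("model1", "model2")) {
  model <- match.arg(model)
  tf <- default_transforms()
  xf <- default_exposure_transforms()
  if (!marker %in% names(tf)) stop("unknown marker: ", marker)
  if (!biomarker %in% names(xf)) stop("unknown biomarker: ", biomarker)
  subjects <- cohort$subjects
  visits <- cohort$visits
  if (length(unique(visits$subject_id)) < 10)
    stop("need at least 10 subjects")
  df <- merge(visits[, c("subject_id", "ga_days", marker)],
              subjects[, c("subject_id", biomarker,
                           intersect(MODEL2_COVARIATES, names(subjects)))],
              by = "subject_id")
  mval <- df[[marker]]
  if (tf[[marker]] == "ln") mval <- offset_zeros(mval)
  df$y <- transform_marker(as.numeric(mval), tf[[marker]])
  df$x <- transform_marker(df[[biomarker]], xf[[biomarker]])
  df$ga_c <- (df$ga_days - 63) / 7   # weeks, centred at 9 weeks
  df$ga_c2 <- df$ga_c^2
  rhs <- "ga_c + ga_c2 + x"
  if (model == "model2")
    rhs <- paste(rhs, "+ age + bmi + nulliparous + conception_mode +",
                 "fetal_sex + smoking + alcohol + folic_acid")
  fml <- stats::as.formula(paste("y ~", rhs, "+ (1 | subject_id)"))
  fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
  converged <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    !lme4::isSingular(fit, tol = 1e-5)
  co <- summary(fit)$coefficients
  beta <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  z <- beta / se
  list(beta = beta, se = se,
       ci_low = beta - stats::qnorm(0.975) * se,
       ci_high = beta + stats::qnorm(0.975) * se,
       p_value = 2 * stats::pnorm(-abs(z)),
       n_subjects = length(unique(df$subject_id)),
       n_observations = nrow(df),
       converged = converged, fit = fit)
}

#' Fit models 1 and 2 for every biomarker-marker pair
#'
#' @param cohort A cohort list.
#' @param markers,biomarkers Names to include (defaults: all).
#' @param models Which adjustment sets to fit.
#' @return data.frame with one row per (model, biomarker, marker):
#'   beta, ci_low, ci_high, p_value, converged.
#' @export
association_table <- function(cohort, markers = MARKER_NAMES,
                              biomarkers = BIOMARKER_NAMES,
                              models = c("model1", "model2")) {
  rows <- list()
  for (mod in models)
    for (b in biomarkers)
      for (m in markers) {
        r <- fit_trajectory_model(cohort, m, b, mod)
        rows[[length(rows) + 1]] <- data.frame(
          model = mod, biomarker = b, marker = m, beta = r$beta,
          ci_low = r$ci_low, ci_high = r$ci_high, p_value = r$p_value,
          converged = r$converged, stringsAsFactors = FALSE)
      }
  do.call(rbind, rows)
}

#' Compare biomarker levels between outcome groups
#'
#' Equal-variance (Student) two-sample t-test plus per-group mean/SD and
#' median/IQR summaries, as used for comparing pregnancies with and without
#' placenta-related complications.
#'
#' @param values Numeric vector (e.g. a serum biomarker).
#' @param group Logical or two-level factor of the same length.
#' @return List: `summary` (per-group n, mean, sd, median, iqr),
#'   `t_statistic`, `df`, `p_value`, `mean_difference`.
#' @export
compare_groups <- function(values, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("`group` must have exactly two levels")
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  if (any(table(group) < 2)) stop("each group needs at least 2 observations")
  tt <- stats::t.test(values ~ group, var.equal = TRUE)
  sm <- do.call(rbind, lapply(levels(group), function(g) {
    v <- values[group == g]
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               median = stats::median(v), iqr = stats::IQR(v),
               stringsAsFactors = FALSE)
  }))
  list(summary = sm, t_statistic = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value,
       mean_difference = unname(diff(rev(tt$estimate))))
}

#' Stratified biomarker-marker correlations
#'
#' Unadjusted Pearson correlations between a transformed 11-week biomarker
#' and the subject-mean transformed marker, per stratum (conception mode,
#' fetal sex or complication status), with pairwise Fisher r-to-z tests for
#' between-stratum differences (the subgroup-difference method is a package
#' choice; the source analysis does not state one).
#'
#' @param cohort A cohort list.
#' @param marker,biomarker Column names.
#' @param stratifier One of "conception_mode", "fetal_sex",
#'   "any_complication".
#' @return List: `correlations` (stratum, n, r) and `differences`
#'   (stratum_a, stratum_b, z, p_value).
#' @export
stratified_correlation <- function(cohort, marker, biomarker,
                                   stratifier = c("conception_mode",
                                                  "fetal_sex",
                                                  "any_complication")) {
  stratifier <- match.arg(stratifier)
  tf <- default_transforms(); xf <- default_exposure_transforms()
  subjects <- cohort$subjects
  visits <- cohort$visits
  mval <- visits[[marker]]
  if (tf[[marker]] == "ln") mval <- offset_zeros(mval)
  yt <- transform_marker(as.numeric(mval), tf[[marker]])
  ymean <- tapply(yt, visits$subject_id, mean)
  df <- data.frame(subject_id = names(ymean), y = as.numeric(ymean),
                   stringsAsFactors = FALSE)
  df <- merge(df, subjects[, c("subject_id", biomarker, stratifier)],
              by = "subject_id")
  df$x <- transform_marker(df[[biomarker]], xf[[biomarker]])
  strata <- split(df, df[[stratifier]])
  cors <- do.call(rbind, lapply(names(strata), function(sname) {
    s <- strata[[sname]]
    r <- if (nrow(s) >= 3 && stats::sd(s$x) > 0 && stats::sd(s$y) > 0)
      stats::cor(s$x, s$y) else NA_real_
    data.frame(stratum = sname, n = nrow(s), r = r, stringsAsFactors = FALSE)
  }))
  diffs <- list()
  cmb <- if (nrow(cors) >= 2) utils::combn(nrow(cors), 2) else NULL
  if (!is.null(cmb)) {
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      ri <- cors$r[i]; rj <- cors$r[j]
      ni <- cors$n[i]; nj <- cors$n[j]
      if (is.na(ri) || is.na(rj) || ni < 4 || nj < 4) next
      z <- (atanh(ri) - atanh(rj)) / sqrt(1 / (ni - 3) + 1 / (nj - 3))
      diffs[[length(diffs) + 1]] <- data.frame(
        stratum_a = cors$stratum[i], stratum_b = cors$stratum[j], z = z,
        p_value = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
    }
  }
  list(correlations = cors,
       differences = if (length(diffs)) do.call(rbind, diffs) else NULL)
}

#' Parameter-recovery harness
#'
#' Generates seeded replicate cohorts with a known coefficient injected for
#' one biomarker-marker pair, refits the trajectory mixed model on each, and
#' reports the mean recovered coefficient, bias, Monte-Carlo SE, empirical
#' 95% CI coverage and the non-convergence rate (flagged above 10%).
#'
#' @param beta_true Injected true coefficient (transformed scales).
#' @param marker,biomarker Pair to inject and refit.
#' @param n_replicates Number of replicate cohorts (>= 50 recommended).
#' @param model Adjustment set to refit with.
#' @param n_subjects Cohort size per replicate.
#' @param seed Base seed; replicate r uses seed + r.
#' @return List: `mean_beta`, `bias`, `mc_se`, `coverage`, `n_replicates`,
#'   `nonconvergence_rate`, `flagged`, and the per-replicate `betas`.
#' @export
recover_parameters <- function(beta_true, marker, biomarker,
                               n_replicates = 200, model = "model2",
                               n_subjects = 185, seed = 1) {
  betas <- numeric(n_replicates)
  covered <- logical(n_replicates)
  conv <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    eff <- list()
    eff[[biomarker]] <- stats::setNames(beta_true, marker)
    cfg <- cohort_config(n_subjects = n_subjects, effects = eff,
                         seed = (seed + r) %% .Machine$integer.max)
    coh <- generate_cohort(cfg)
    fit <- fit_trajectory_model(coh, marker, biomarker, model)
    betas[r] <- fit$beta
    covered[r] <- fit$ci_low <= beta_true && beta_true <= fit$ci_high
    conv[r] <- fit$converged
  }
  mc_se <- stats::sd(betas) / sqrt(n_replicates)
  list(mean_beta = mean(betas), bias = mean(betas) - beta_true,
       mc_se = mc_se, coverage = mean(covered), n_replicates = n_replicates,
       nonconvergence_rate = mean(!conv),
       flagged = mean(!conv) > 0.1, betas = betas)
}
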