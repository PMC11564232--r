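# Synthetic longitudinal cohort with the statistical structure the
# association stage assumes: ~185 ongoing pregnancies, 2-3 visits at 7/9/11
# weeks gestation, marker trajectories quadratic in GA with a subject random
# intercept, serum angiogenic biomarkers drawn once (11 weeks) and coupled to
# the markers on the analysis (transformed) scales, plus the pregnancy-dating
# and exclusion rules and complication labelling.

MARKER_NAMES <- c("pv_cm3", "upvv_cm3", "end_points", "bifurcation_points",
                  "crossing_points", "vessel_points", "total_length_mm",
                  "avg_thickness_mm", "density_end", "density_bifurcation",
                  "density_crossing")

BIOMARKER_NAMES <- c("plgf", "sflt1", "seng", "sflt1_plgf_ratio",
                     "seng_plgf_ratio")

#' Gestational age from dating rules
#'
#' Dating rules: natural conception with a regular 25-35 day cycle dates from
#' the last menstrual period (LMP); if LMP-based and CRL-based GA differ by
#' more than 6 days the CRL-based GA wins; fresh IVF/ICSI dates from oocyte
#' pick-up + 14 days; cryopreserved transfer dates from transfer date + 19
#' days. All dates are day numbers (or `Date`s) and GA is returned in days at
#' `ref_date`.
#'
#' @param method One of "lmp", "crl", "ivf_fresh", "cryo".
#' @param ref_date Reference day.
#' @param lmp_date First day of last menstrual period (lmp method).
#' @param cycle_length Cycle length in days (lmp method; must be 25-35).
#' @param crl_ga_days CRL-based GA (days) at `ref_date`.
#' @param opu_date Oocyte pick-up day (ivf_fresh).
#' @param transfer_date Embryo transfer day (cryo).
#' @return GA in days at `ref_date`.
#' @export
date_pregnancy <- function(method = c("lmp", "crl", "ivf_fresh", "cryo"),
                           ref_date, lmp_date = NULL, cycle_length = NULL,
                           crl_ga_days = NULL, opu_date = NULL,
                           transfer_date = NULL) {
  method <- match.arg(method)
  d <- function(x) as.numeric(x)
  switch(method,
    lmp = {
      if (is.null(lmp_date)) stop("lmp method requires `lmp_date`")
      irregular <- is.null(cycle_length) || cycle_length < 25 ||
        cycle_length > 35
      if (irregular) {
        if (is.null(crl_ga_days))
          stop("CRL required: cycle outside 25-35 days (or unknown)")
        return(d(crl_ga_days))
      }
      ga <- d(ref_date) - d(lmp_date)
      if (!is.null(crl_ga_days) && abs(ga - d(crl_ga_days)) > 6)
        return(d(crl_ga_days))
      ga
    },
    crl = {
      if (is.null(crl_ga_days)) stop("crl method requires `crl_ga_days`")
      d(crl_ga_days)
    },
    ivf_fresh = {
      if (is.null(opu_date)) stop("ivf_fresh method requires `opu_date`")
      d(ref_date) - d(opu_date) + 14
    },
    cryo = {
      if (is.null(transfer_date)) stop("cryo method requires `transfer_date`")
      d(ref_date) - d(transfer_date) + 19
    })
}

EXCLUSION_REASONS <- c("withdrawal", "miscarriage", "oocyte_donation",
                       "missing_serum")

#' Apply cohort exclusion rules
#'
#' Removes subjects with any exclusion reason (withdrawal, miscarriage,
#' oocyte donation, missing maternal blood sample) and reports counts per
#' reason.
#'
#' @param subjects data.frame with an `excluded_reason` column (NA = kept).
#' @return List: `included` (data.frame), `n_enrolled`, `n_excluded`,
#'   `counts` (named integer vector per reason).
#' @export
apply_exclusions <- function(subjects) {
  if (!"excluded_reason" %in% names(subjects))
    stop("subjects need an `excluded_reason` column")
  reason <- subjects$excluded_reason
  bad <- !is.na(reason) & !reason %in% EXCLUSION_REASONS
  if (any(bad))
    stop("unknown exclusion reason(s): ",
         paste(unique(reason[bad]), collapse = ", "))
  counts <- vapply(EXCLUSION_REASONS,
                   function(r) sum(!is.na(reason) & reason == r), integer(1))
  list(included = subjects[is.na(reason), , drop = FALSE],
       n_enrolled = nrow(subjects),
       n_excluded = sum(!is.na(reason)),
       counts = counts)
}

#' Label a pregnancy with placenta-related complications
#'
#' Applies the clinical definitions to latent state: PIH is new-onset
#' hypertension after 20 weeks with systolic BP >= 140 and/or diastolic
#' BP >= 90 mmHg; PE is PIH with >= 300 mg/24 h proteinuria; FGR is a growth
#' percentile < 10 or a drop of more than 20 percentile points between two
#' measurements; SGA is birth weight percentile < 10; PTB is birth before
#' 37+0 weeks (259 days).
#'
#' @param latent data.frame (one row per subject) with columns `sbp_mmhg`,
#'   `dbp_mmhg`, `hypertension_after_20w` (logical), `proteinuria_mg24h`,
#'   `growth_pct_1`, `growth_pct_2`, `bw_pct`, `ga_at_birth_days`.
#' @return data.frame of logical flags pih, pe, fgr, sga, ptb,
#'   any_complication.
#' @export
assign_outcomes <- function(latent) {
  need <- c("sbp_mmhg", "dbp_mmhg", "hypertension_after_20w",
            "proteinuria_mg24h", "growth_pct_1", "growth_pct_2", "bw_pct",
            "ga_at_birth_days")
  miss <- setdiff(need, names(latent))
  if (length(miss)) stop("missing latent fields: ", paste(miss, collapse = ", "))
  pih <- latent$hypertension_after_20w &
    (latent$sbp_mmhg >= 140 | latent$dbp_mmhg >= 90)
  pe <- pih & latent$proteinuria_mg24h >= 300
  fgr <- latent$growth_pct_2 < 10 |
    (latent$growth_pct_1 - latent$growth_pct_2) > 20
  sga <- latent$bw_pct < 10
  ptb <- latent$ga_at_birth_days < 259
  data.frame(pih = pih, pe = pe, fgr = fgr, sga = sga, ptb = ptb,
             any_complication = pih | pe | fgr | sga | ptb)
}

# Quadratic trajectory coefficients from transformed-scale values at
# 7, 9 and 11 weeks (49/63/77 days); GA centred at 63 days.
traj_coef <- function(y) {
  c(a0 = y[2], a1 = (y[3] - y[1]) / 28, a2 = (y[3] - 2 * y[2] + y[1]) / 392)
}

default_trajectories <- function() {
  list(pv_cm3 = c(2.0, 2.7, 3.4),          # cbrt scale: PV 8 -> 39 cm3
       upvv_cm3 = c(1.0, 1.35, 1.8),       # cbrt scale: uPVV 1 -> 5.8 cm3
       end_points = c(8, 10, 12),          # sqrt scale
       bifurcation_points = c(9, 11, 13),
       crossing_points = c(7, 8.5, 10),
       vessel_points = c(25, 33, 41),
       total_length_mm = c(24, 29, 34),    # sqrt scale: 576 -> 1156 mm
       avg_thickness_mm = c(0.9, 1.0, 1.1),
       density_end = c(3.4, 3.1, 2.8),     # ln scale, per cm3
       density_bifurcation = c(3.1, 2.9, 2.7),
       density_crossing = c(2.4, 2.3, 2.2))
}

default_marker_sd <- function() {
  list(pv_cm3 = c(0.40, 0.20), upvv_cm3 = c(0.22, 0.12),
       end_points = c(1.6, 0.9), bifurcation_points = c(1.4, 0.8),
       crossing_points = c(0.9, 0.5), vessel_points = c(5.0, 2.5),
       total_length_mm = c(3.2, 1.6), avg_thickness_mm = c(0.12, 0.06),
       density_end = c(0.45, 0.22), density_bifurcation = c(0.40, 0.20),
       density_crossing = c(0.28, 0.14))
}

# covariate effects in units of the marker's between-subject SD
default_covariate_effects <- function() {
  c(age_per_year = 0.01, bmi_per_unit = -0.012, nulliparous = -0.10,
    ivf = -0.08, cryo = -0.08, male = 0.05, smoking = -0.15,
    alcohol = -0.02, folic_acid = 0.08)
}

#' Cohort generator configuration
#'
#' Defaults encode the studied population: 185 ongoing pregnancies, visits
#' targeted at 7/9/11 weeks with +/- 3 days uniform jitter and one visit
#' missing with probability `missing_visit_prob` (every subject keeps at
#' least two), biomarkers drawn once per subject on the log scale with
#' moments matching the reported means/SDs (PlGF 41.6 (17.4) pg/mL, sFlt-1
#' 1332.6 (489) pg/mL, sEng 8.6 (2.8) ng/mL), and marker trajectories
#' quadratic in GA on the analysis scales.
#'
#' @param n_subjects Number of subjects (>= 10).
#' @param effects Named list: per biomarker, a named numeric vector of true
#'   coefficients of the (transformed) biomarker on the transformed marker,
#'   e.g. `list(plgf = c(upvv_cm3 = 0.39))`. Effects act on the centred
#'   exposure so trajectories keep their stated level.
#' @param trajectories Named list of transformed-scale marker values at
#'   7/9/11 weeks.
#' @param marker_sd Named list of c(between-subject SD, residual SD) on the
#'   transformed scale.
#' @param covariate_effects Named vector (units of between-subject SD).
#' @param missing_visit_prob Probability a subject contributes 2 visits
#'   instead of 3.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 185, effects = list(),
                          trajectories = default_trajectories(),
                          marker_sd = default_marker_sd(),
                          covariate_effects = default_covariate_effects(),
                          missing_visit_prob = 0.2, seed = 1) {
  stopifnot(n_subjects >= 10, missing_visit_prob >= 0, missing_visit_prob <= 1)
  for (b in names(effects)) {
    if (!b %in% BIOMARKER_NAMES) stop("unknown biomarker in effects: ", b)
    bad <- setdiff(names(effects[[b]]), MARKER_NAMES)
    if (length(bad)) stop("unknown marker(s) in effects: ",
                          paste(bad, collapse = ", "))
  }
  for (m in MARKER_NAMES) {
    if (any(marker_sd[[m]] <= 0)) stop("marker SDs must be positive")
  }
  structure(list(n_subjects = as.integer(n_subjects), effects = effects,
                 trajectories = trajectories, marker_sd = marker_sd,
                 covariate_effects = covariate_effects,
                 missing_visit_prob = missing_visit_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# log-scale biomarker parameters matching the reported mean (SD):
# lognormal with matching first two moments; modest PlGF/sFlt-1 correlation.
biomarker_lognormal_params <- function() {
  mom <- list(plgf = c(41.6, 17.4), sflt1 = c(1332.6, 489), seng = c(8.6, 2.8))
  lapply(mom, function(ms) {
    cv2 <- (ms[2] / ms[1])^2
    sdlog <- sqrt(log(1 + cv2))
    c(meanlog = log(ms[1]) - sdlog^2 / 2, sdlog = sdlog)
  })
}

#' Generate a synthetic longitudinal cohort
#'
#' Per subject: covariates and once-measured log-normal biomarkers are drawn;
#' a subject random intercept (between-subject SD) shifts every visit; at
#' each visit the transformed marker value is the quadratic GA trajectory
#' plus the random intercept, covariate effects, the configured
#' biomarker couplings (on centred log-exposures) and residual noise. Marker
#' values are reported on the natural scale by inverting the transform, so
#' the analysis stage re-derives exactly the simulated transformed values.
#' Counts are left continuous: rounding would bias the square-root scale the
#' models operate on.
#'
#' @param config A [cohort_config()].
#' @return List of data.frames `subjects` (one row per subject: covariates,
#'   biomarkers, latent outcome state, complication flags) and `visits`
#'   (subject_id, visit, ga_days, one column per marker, natural scale).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  tf <- default_transforms()
  with_seed(config$seed, {
    id <- sprintf("S%04d", seq_len(n))
    age <- stats::rnorm(n, 32.3, 4.4)
    bmi <- pmax(16, stats::rnorm(n, 26.0, 5.2))
    nulliparous <- stats::rbinom(n, 1, 0.578) == 1
    conception_mode <- sample(c("natural", "ivf_icsi", "cryo"), n,
                              replace = TRUE, prob = c(0.422, 0.40, 0.178))
    fetal_sex <- sample(c("M", "F"), n, replace = TRUE,
                        prob = c(0.492, 0.508))
    smoking <- stats::rbinom(n, 1, 0.146) == 1
    alcohol <- stats::rbinom(n, 1, 0.281) == 1
    folic_acid <- stats::rbinom(n, 1, 0.838) == 1

    bp <- biomarker_lognormal_params()
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n); z3 <- stats::rnorm(n)
    rho <- 0.3  # PlGF / sFlt-1 log-scale correlation
    ln_plgf <- bp$plgf["meanlog"] + bp$plgf["sdlog"] * z1
    ln_sflt1 <- bp$sflt1["meanlog"] +
      bp$sflt1["sdlog"] * (rho * z1 + sqrt(1 - rho^2) * z2)
    ln_seng <- bp$seng["meanlog"] + bp$seng["sdlog"] * z3
    plgf <- exp(ln_plgf); sflt1 <- exp(ln_sflt1); seng <- exp(ln_seng)

    subjects <- data.frame(
      subject_id = id, age = age, bmi = bmi, nulliparous = nulliparous,
      conception_mode = conception_mode, fetal_sex = fetal_sex,
      smoking = smoking, alcohol = alcohol, folic_acid = folic_acid,
      plgf = as.numeric(plgf), sflt1 = as.numeric(sflt1),
      seng = as.numeric(seng),
      sflt1_plgf_ratio = as.numeric(sflt1 / plgf),
      seng_plgf_ratio = as.numeric(seng / plgf),
      excluded_reason = NA_character_, stringsAsFactors = FALSE)

    # latent outcome state and complication labels
    sbp <- stats::rnorm(n, 119, 12)
    dbp <- 30 + 0.35 * sbp + stats::rnorm(n, 0, 6)
    hyp20 <- rep(TRUE, n)
    prot <- ifelse(sbp >= 140 | dbp >= 90,
                   stats::rlnorm(n, 6.5, 0.9), stats::rlnorm(n, 4.2, 0.7))
    zg1 <- stats::rnorm(n, 0.4, 1)
    zg2 <- zg1 + stats::rnorm(n, 0, 0.25)
    g1 <- 100 * stats::pnorm(zg1); g2 <- 100 * stats::pnorm(zg2)
    zbw <- stats::rnorm(n, 0.08, 1)
    bw_pct <- 100 * stats::pnorm(zbw)
    early <- stats::runif(n) < 0.10
    ga_birth <- ifelse(early, stats::rnorm(n, 245, 14),
                       stats::rnorm(n, 277, 8))
    ga_birth <- pmin(ga_birth, 294)
    latent <- data.frame(sbp_mmhg = sbp, dbp_mmhg = dbp,
                         hypertension_after_20w = hyp20,
                         proteinuria_mg24h = prot, growth_pct_1 = g1,
                         growth_pct_2 = g2, bw_pct = bw_pct,
                         ga_at_birth_days = ga_birth)
    subjects <- cbind(subjects, latent, assign_outcomes(latent))
    subjects$ga_at_birth <- ga_birth
    subjects$birth_weight <- round(3380 - 24 * (280 - ga_birth) +
                                     430 * zbw)

    # centred log-exposure matrix for the configured couplings
    expo <- cbind(plgf = ln_plgf - mean(ln_plgf),
                  sflt1 = ln_sflt1 - mean(ln_sflt1),
                  seng = seng - mean(seng),  # sEng enters untransformed
                  sflt1_plgf_ratio = (ln_sflt1 - ln_plgf) -
                    mean(ln_sflt1 - ln_plgf),
                  seng_plgf_ratio = (ln_seng - ln_plgf) -
                    mean(ln_seng - ln_plgf))

    # visits: 7/9/11 weeks +/- 3 d jitter; one visit dropped with configured
    # probability (subjects always keep >= 2 visits)
    targets <- c(49, 63, 77)
    vis <- lapply(seq_len(n), function(i) {
      ga <- sort(targets + stats::runif(3, -3, 3))
      keep <- rep(TRUE, 3)
      if (stats::runif(1) < config$missing_visit_prob)
        keep[sample.int(3, 1)] <- FALSE
      data.frame(subject_id = id[i], visit = which(keep),
                 ga_days = ga[keep], stringsAsFactors = FALSE)
    })
    visits <- do.call(rbind, vis)
    gc_ <- visits$ga_days - 63

    cov_design <- cbind(age_per_year = age - 32.3, bmi_per_unit = bmi - 26,
                        nulliparous = as.numeric(nulliparous),
                        ivf = as.numeric(conception_mode == "ivf_icsi"),
                        cryo = as.numeric(conception_mode == "cryo"),
                        male = as.numeric(fetal_sex == "M"),
                        smoking = as.numeric(smoking),
                        alcohol = as.numeric(alcohol),
                        folic_acid = as.numeric(folic_acid))
    ce <- config$covariate_effects
    cov_lin <- as.numeric(cov_design[, names(ce), drop = FALSE] %*% ce)

    irow <- match(visits$subject_id, id)
    for (m in MARKER_NAMES) {
      co <- traj_coef(config$trajectories[[m]])
      sdb <- config$marker_sd[[m]][1]
      sde <- config$marker_sd[[m]][2]
      b_i <- stats::rnorm(n, 0, sdb)
      eff <- rep(0, n)
      for (b in names(config$effects)) {
        be <- config$effects[[b]]
        if (!is.na(be[m]) && m %in% names(be))
          eff <- eff + be[[m]] * expo[, b]
      }
      y <- co["a0"] + co["a1"] * gc_ + co["a2"] * gc_^2 +
        b_i[irow] + sdb * cov_lin[irow] + eff[irow] +
        stats::rnorm(nrow(visits), 0, sde)
      # markers are physically non-negative; trajectories and SDs are sized
      # so transformed values stay positive with ~3.5 sigma margin, and the
      # residual tail (<1e-3 of draws) is floored at a tenth of the earliest
      # trajectory value
      if (tf[[m]] %in% c("sqrt", "cbrt"))
        y <- pmax(y, 0.1 * min(config$trajectories[[m]]))
      visits[[m]] <- inverse_transform(y, tf[[m]])
    }
    list(subjects = subjects, visits = visits, config = config)
  })
}

#' Write a generated cohort to CSV
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Paths of `subjects.csv` and `visits.csv`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- file.path(dir, "subjects.csv")
  vp <- file.path(dir, "visits.csv")
  utils::write.csv(cohort$subjects, sp, row.names = FALSE)
  utils::write.csv(cohort$visits, vp, row.names = FALSE)
  invisible(c(subjects = sp, visits = vp))
}
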