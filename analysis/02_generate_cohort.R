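#!/usr/bin/env Rscript
# Generates the synthetic longitudinal cohort used by the association stage:
# 185 ongoing pregnancies with visits at 7/9/11 weeks, covariates and
# once-measured angiogenic biomarkers, complication labels, and the adjusted
# PlGF couplings reported for the real cohort injected as ground truth.
# Writes results/cohort/subjects.csv and visits.csv plus a provenance JSON.

library(placvasc)
dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

seed <- 20260917
effects <- list(plgf = c(pv_cm3 = 0.53, upvv_cm3 = 0.39,
                         bifurcation_points = 4.64, crossing_points = 4.01,
                         total_length_mm = 13.33, avg_thickness_mm = 0.05,
                         density_end = -1.73, density_bifurcation = -0.76))
cfg <- cohort_config(n_subjects = 185, effects = effects, seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")

prov <- list(seed = seed, n_subjects = cfg$n_subjects,
             effects = effects,
             package_version = as.character(packageVersion("placvasc")),
             generated = format(Sys.time(), "%Y-%m-%d"))
jsonlite::write_json(prov, "results/cohort/provenance.json",
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("Cohort: %d subjects, %d visits (%.1f per subject)\n",
            nrow(cohort$subjects), nrow(cohort$visits),
            nrow(cohort$visits) / nrow(cohort$subjects)))
cat(sprintf("Placenta-related complications: %d (%.1f%%)\n",
            sum(cohort$subjects$any_complication),
            100 * mean(cohort$subjects$any_complication)))
cat(sprintf("PlGF %.1f (%.1f) pg/mL, sFlt-1 %.0f (%.0f) pg/mL, sEng %.1f (%.1f) ng/mL\n",
            mean(cohort$subjects$plgf), sd(cohort$subjects$plgf),
            mean(cohort$subjects$sflt1), sd(cohort$subjects$sflt1),
            mean(cohort$subjects$seng), sd(cohort$subjects$seng)))
cat("Wrote results/cohort/{subjects,visits}.csv\n")
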