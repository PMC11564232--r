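#!/usr/bin/env Rscript
# Association stage on the generated cohort (run 02_generate_cohort.R first):
# linear mixed models with quadratic GA trend for every biomarker x marker
# pair (model 1: GA only; model 2: + maternal covariates), biomarker
# comparison between complicated and uncomplicated pregnancies, and
# unadjusted stratified correlations.
# Writes results/association_models.csv, results/biomarker_group_comparison.csv
# and results/stratified_correlations.csv.

library(placvasc)
stopifnot(file.exists("results/cohort/subjects.csv"))
cohort <- list(subjects = read.csv("results/cohort/subjects.csv"),
               visits = read.csv("results/cohort/visits.csv"))

tab <- association_table(cohort)
write.csv(tab, "results/association_models.csv", row.names = FALSE)
sig <- subset(tab, model == "model2" & biomarker == "plgf" & p_value < 0.05)
cat("Model-2 PlGF associations with p < 0.05:\n")
print(sig[, c("marker", "beta", "ci_low", "ci_high", "p_value")],
      row.names = FALSE, digits = 3)

cmp <- lapply(c("plgf", "sflt1", "seng", "sflt1_plgf_ratio", "seng_plgf_ratio"),
              function(b) {
  r <- compare_groups(cohort$subjects[[b]], cohort$subjects$any_complication)
  data.frame(biomarker = b,
             median_without = r$summary$median[r$summary$group == "FALSE"],
             median_with = r$summary$median[r$summary$group == "TRUE"],
             t_statistic = r$t_statistic, p_value = r$p_value)
})
cmp <- do.call(rbind, cmp)
write.csv(cmp, "results/biomarker_group_comparison.csv", row.names = FALSE)

strata <- list()
for (st in c("conception_mode", "fetal_sex", "any_complication"))
  for (b in c("plgf", "seng_plgf_ratio")) {
    r <- stratified_correlation(cohort, "upvv_cm3", b, st)
    r$correlations$stratifier <- st
    r$correlations$biomarker <- b
    strata[[length(strata) + 1]] <- r$correlations
  }
write.csv(do.call(rbind, strata), "results/stratified_correlations.csv",
          row.names = FALSE)
cat("Wrote results/association_models.csv, biomarker_group_comparison.csv, stratified_correlations.csv\n")
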