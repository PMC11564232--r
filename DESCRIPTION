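Package: placvasc
Title: First-Trimester Utero-Placental Vascular Morphometry and Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies first-trimester utero-placental vascular development
    from 3D power-Doppler voxel volumes: extracts the utero-placental
    vascular volume (uPVV) by thresholded voxel summation inside a placental
    mask, derives the vascular skeleton (uPVS) by topology-preserving
    iterative thinning with peel-depth recording, classifies skeleton voxels
    into end, vessel, bifurcation and crossing points, and computes branching
    densities. Ships a ground-truth branching-tube phantom generator and a
    synthetic longitudinal cohort generator, and links 11-week serum
    angiogenic biomarkers (PlGF, sFlt-1, sEng and their ratios) to marker
    trajectories with linear mixed models quadratic in gestational age,
    including a simulation-based parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
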