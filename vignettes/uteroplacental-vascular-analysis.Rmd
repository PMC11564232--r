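---
title: "Quantifying first-trimester utero-placental vascular development: methods and design choices"
author: "placvasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying first-trimester utero-placental vascular development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placvasc)
```

## The problem

In the first trimester the maternal spiral arteries remodel into the
low-resistance utero-placental circulation; inadequate remodelling underlies
pre-eclampsia, fetal growth restriction and preterm birth. Two imaging markers
quantify this process from 3D power-Doppler ultrasound:

* the **utero-placental vascular volume (uPVV)**, the summed volume (cm³) of
  Doppler-positive voxels inside the placental segment — volumetric
  development;
* the **utero-placental vascular skeleton (uPVS)**, the one-voxel-wide
  centreline network obtained by iteratively peeling the uPVV — morphologic
  (branching) development, summarised by counts of end, vessel, bifurcation
  and crossing points, total length and average thickness, plus three
  branching densities (end/bifurcation/crossing points per cm³ of uPVV).

The package implements this imaging computation, a ground-truth phantom
generator to validate it, a synthetic longitudinal cohort generator, and the
mixed-model machinery that links once-measured (11-week) serum angiogenic
biomarkers — PlGF, sFlt-1, sEng and the sFlt-1/PlGF and sEng/PlGF ratios —
to marker trajectories over 7–11 weeks of gestation.

## Imaging model

### uPVV and PV

A scan is a voxel grid of Doppler amplitudes with isotropic spacing $h$ (mm)
plus a binary placental mask. The placental volume is
$\mathrm{PV} = N_{\text{mask}}\, h^3 / 1000$ cm³ and the vascular volume is
$\mathrm{uPVV} = N\{a > \tau,\ \text{in mask}\}\, h^3 / 1000$, with a strict
amplitude threshold $\tau$. The rendering threshold of the original clinical
system is unpublished, so $\tau$ is a mandatory, logged argument
(`extract_upvv()`), and 0 is appropriate only for noiseless phantoms.
Anisotropic volumes are rejected rather than resampled, because every
skeleton length/thickness formula multiplies voxel counts by a single edge
length.

### Skeletonization

`skeletonize()` realises the "peel the outermost layer until one central
voxel remains" mechanism as round-based thinning in (26, 6) digital topology:

1. **Pinhole regularisation.** Background voxels with ≥ 4 foreground face
   neighbours are filled (only when all their face neighbours belong to one
   26-component). Thin oblique tubes otherwise contain one-voxel background
   tunnels that would survive as spurious skeleton loops.
2. **Directional peel.** Per round, six face-direction sub-iterations delete
   border voxels sequentially (fixed lexicographic order, hence
   deterministic) when deletion preserves local (26, 6) topology and the
   voxel is not a line end. A voxel may only be peeled from a direction that
   has foreground behind it; without this rule a sequential pass can consume
   an entire two-voxel-wide branch end-to-end in one sweep (we observed a
   widely used reference implementation erase a 2×1×21 bar completely).
3. **Residual reduction.** The backed peel can stall at two-voxel-wide
   ribbons; a cleanup pass deletes voxels with ≥ 3 neighbours, or redundant
   triangle corners (2 mutually adjacent neighbours), when the foreground
   neighbourhood stays one 26-component. Full topological simplicity is
   deliberately relaxed here to connectivity preservation: it would protect
   voxel-scale "bubbles" (doubled strands around discretization tunnels)
   that are artifacts, not anastomoses. The connected-component count — the
   invariant the skeleton guarantees — is preserved by every rule.

**Peel depth.** Each voxel records the round at which it was first exposed
to the background, minus one: 0 for input that is already one voxel wide,
and approximately the local tube radius in voxels otherwise. Whether the
original system counts from 0 or 1 at the surface is unstated; "layers
peeled off before reaching the voxel" is the fixed semantics here.

### Graph-level canonicalization

Rasterized tubes produce three artifact classes that per-voxel degree
classification is sensitive to. `skeletonize()` removes them by default
(`prune_spurs = FALSE` gives the raw thinning output):

* **Bubbles** — short parallel double strands (cycles ≤ 24 voxels touching a
  junction): the longest degree-2 run of the cycle is deleted; removal from
  a cycle cannot disconnect. Genuine anastomotic loops are longer and are
  left alone.
* **Junction clusters** — mutually adjacent junction voxels representing one
  anatomical branch point: replaced by a single voxel of the original
  volume adjacent to all arms, or by a hub plus one-voxel bridges when the
  arms spread beyond one voxel's reach (the replacement always lies inside
  the original vascular volume, preserving the skeleton ⊆ uPVV invariant).
* **Spurs** — terminal branches no longer than twice the local peel depth
  plus two voxels, i.e. about one tube diameter: shorter than the vessel's
  own width, such branches cannot be resolved as real and are surface bumps.

All rules iterate to a fixed point in lexicographic order, so the result is
deterministic.

### Classification and markers

Each skeleton voxel is classed by its count of 26-adjacent skeleton voxels:
1 → end, 2 → vessel, 3 → bifurcation, ≥ 4 → crossing. Degree 0 (isolated)
is classed as an end point and degrees > 4 as crossings so the partition is
exhaustive. The summary formulas are literal:

* total length = skeleton voxel count × voxel edge length (mm). This
  *undercounts* oblique runs — a digital straight line with direction
  $d$ has voxel count proportional to $\max_i |d_i|$, so a body-diagonal
  branch is undercounted by up to 42%; on branching-tree phantoms with
  moderate branch angles the aggregate error is −5 to −17%. The bias is a
  property of the printed formula and is left in place.
* average thickness = mean peel depth × voxel edge length (mm). One-voxel
  wide input therefore has thickness 0 by definition; across tube phantoms
  of radius 1–3 voxels the measure is strictly increasing and close to the
  true radius.
* density of end/bifurcation/crossing points = count / uPVV (per cm³).

## Phantoms

`generate_tree()` builds binary trees of straight tube segments in
continuous mm space (trunk 10 mm × 1 mm radius by default, per-generation
length decay 0.75, radius decay 0.85, branch angle 35°, azimuths seeded
uniform). Ground truth — tip count (the trunk origin counts as a tip, since
the skeleton sees it as an end point), bifurcation nodes, centreline length,
length-weighted mean radius, analytic cylinder volume — is independent of
any voxel grid. `rasterize_tree()` then discretizes at a chosen spacing
(tubes are resolved when spacing ≤ radius/2; the validation suite uses half
the *smallest* radius in the tree) and can add Gaussian amplitude noise
clipped at zero, the simplest stand-in for Doppler speckle. X-shaped
crossings are planted as perpendicular bridges through a segment midpoint,
because a strict binary tree cannot produce degree-4 skeleton voxels; a
planted crossing is recovered as a crossing point in most runs, and
otherwise resolves into two adjacent bifurcations — a known limitation of
voxel-degree classification.

What a green phantom test establishes: exact end/bifurcation recovery in
≥ 90% of noiseless runs at resolved spacing, length within 20%, thickness
monotone in radius. What it does not establish: behaviour under speckle,
flash artifacts, segmentation error, or the anatomy of a real
utero-placental network — the phantoms are tubes, not physiology.

## Synthetic cohort

`generate_cohort()` emulates the cohort the association stage assumes:
185 ongoing pregnancies; visits targeted at 7/9/11 weeks (49/63/77 days)
with ±3-day uniform jitter; one visit dropped with probability 0.2 so every
subject keeps at least two. Covariate distributions follow the reported
baseline table (age 32.3 (4.4) years, BMI 26.0 (5.2), 57.8% nulliparous,
57.8% IVF/ICSI, 49.2% male fetus, 14.6% smoking, 28.1% alcohol, 83.8% folic
acid). Serum biomarkers are drawn once per subject as lognormals matching
the reported means/SDs (PlGF 41.6 (17.4) pg/mL; sFlt-1 1332.6 (489) pg/mL,
log-correlation 0.3 with PlGF; sEng 8.6 (2.8) ng/mL); both ratios are
computed exactly from their components.

On the transformed analysis scale, each marker follows a quadratic GA
trajectory (parameterised by its values at 7/9/11 weeks, fitted exactly
through three points) plus a subject random intercept, covariate effects
(scaled to the marker's between-subject SD), the configured biomarker
couplings applied to the *centred* transformed exposure (so the trajectory
level is unchanged and the coefficient is directly comparable to the fitted
one), and residual noise. Values are reported on the natural scale by
inverting the transform, so the analysis stage recovers exactly the
simulated transformed values; counts are left continuous because rounding
would bias the square-root scale the models operate on.

Numerical choices worth recording:

* Trajectory levels and SDs were set once to plausible first-trimester
  magnitudes **and** sized so that transformed values stay positive with
  ≈ 3.5σ margin even under the largest printed coupling (β = 13.33 on
  √length spans ±5.4 per SD of ln PlGF); the residual tail (< 10⁻³ of
  draws) is floored at a tenth of the earliest trajectory value. This is a
  consistency requirement of the Gaussian-on-transformed-scale model, not a
  tuning knob: recovery is unbiased once truncation is negligible.
* Within-subject marker correlation is not reported for the real cohort;
  the between/residual SD split (≈ 2:1) is a package choice exposed in
  `cohort_config()`.
* Complication labelling applies the clinical definitions to simulated
  latent state (blood pressure, proteinuria, growth percentiles, GA at
  birth): PIH = hypertension after 20 weeks with SBP ≥ 140 and/or
  DBP ≥ 90 mmHg; PE = PIH with ≥ 300 mg/24 h proteinuria; FGR = growth
  percentile < 10 or a > 20-point drop; SGA = birth-weight percentile < 10;
  PTB = birth before 37+0 weeks. Latent distributions are calibrated so
  ≈ 25% of subjects carry any complication, matching the reported 24.9%
  within binomial error. The reported GA-at-birth summary (mean 38+5,
  SD 20 days) is incompatible with a normal distribution and a 9.7% preterm
  rate; a 90:10 term/early mixture (N(277, 8) / N(245, 14) days) favours
  the complication rates over the printed SD.
* Outcome labels are independent of the vascular markers by default —
  consistent with the stratified analysis finding no subgroup differences.

Pregnancy dating (`date_pregnancy()`) implements the clinical rules: LMP
dating only for regular 25–35-day cycles, CRL dating when LMP and CRL
disagree by more than 6 days, oocyte pick-up + 14 days for fresh IVF/ICSI,
transfer + 19 days for cryopreserved transfers.

## Association analysis

Transforms follow the analysis plan: cube root for volumetric markers (PV,
uPVV), square root for counts/length/thickness, natural log for densities
and for the exposures PlGF, sFlt-1 and both ratios; sEng enters in ng/mL
untransformed, as in the reported models. Densities can be zero only when
the corresponding count is zero; zeros are offset by half the smallest
positive observed value before the log (`offset_zeros()`), and the offset is
recorded.

`fit_trajectory_model()` fits, per biomarker × marker pair,

$$y_{ij} = \beta_0 + \beta_1\, g_{ij} + \beta_2\, g_{ij}^2 +
  \beta\, x_i + \boldsymbol\gamma^\top \mathbf{z}_i + b_i + \varepsilon_{ij},
  \qquad b_i \sim N(0, \sigma_b^2),$$

with $g$ gestational age centred at 63 days (9 weeks, decorrelating the
trend terms; the exposure effect is unaffected by centring), $x_i$ the
transformed 11-week biomarker (constant within subject), and $\mathbf{z}_i$
empty (model 1) or the nine maternal covariates: age, BMI, parity
(nulliparity, binary), conception mode (three levels), fetal sex, smoking,
alcohol, folic acid (model 2). Design choices, all stated as such:

* random intercept only — with 2–3 visits a random slope is weakly
  identified;
* REML estimation via `lme4`, Wald 95% CIs and normal-theory p-values
  (no Satterthwaite machinery is available in this stack; with ≈ 185
  subjects the normal reference is adequate, and the null-calibration test
  verifies type-I error in [0.03, 0.07] and CI coverage in [0.92, 0.98]
  at 500 replicates);
* no biomarker × GA interaction (a single coefficient per pair, i.e. a
  constant shift of the trajectory);
* no multiple-testing correction, mirroring the analysis plan; the recovery
  report prints the number of fitted models;
* singular or non-converged fits are flagged honestly (`converged = FALSE`),
  never silently refitted.

`compare_groups()` is the equal-variance Student t-test with mean/SD and
median/IQR summaries. `stratified_correlation()` computes unadjusted Pearson
correlations between the transformed biomarker and the subject-mean
transformed marker per stratum; between-stratum differences use Fisher's
r-to-z — the original analysis does not state a method, so this is a
package decision, labelled as such.

`recover_parameters()` closes the loop: it injects a known coefficient into
replicate cohorts, refits, and reports mean recovered coefficient, bias,
Monte-Carlo SE, CI coverage and the non-convergence rate (flagged above
10%). The acceptance surface uses the printed adjusted PlGF coefficients
(cbrt PV 0.53, cbrt uPVV 0.39, √bifurcation points 4.64, √total length
13.33) as injected truths.

## Known limitations

* Equivalence with the original (unpublished) VR skeletonization cannot be
  claimed — only consistency with its verbal description and with ground
  truth phantoms.
* The literal length formula undercounts oblique vessels (above); an
  optional diagonal correction is deliberately not applied by default.
* X-crossings may resolve into adjacent bifurcation pairs at coarse
  spacing.
* The cohort generator produces marker values directly on the analysis
  scale; it does not simulate ultrasound volumes per subject (the phantom
  pathway exists for that, at phantom scale).
* Biomarkers are simulated once per subject (as measured); nothing can be
  said about longitudinal biomarker dynamics.
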