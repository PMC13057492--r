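---
title: "Quantitative bronchovascular-bundle morphometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative bronchovascular-bundle morphometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvbquant)
```

## Scope and model

Pneumoconiosis — diffuse pulmonary fibrosis from occupational dust — distorts
the bronchovascular bundle (BVB) progressively: airway walls thicken,
vascular bifurcation geometry drifts, and the peribronchial texture grows
more complex. `bvbquant` quantifies the three parameters that track this on
reformatted CT, and combines them in the published raw-scale logistic score

$$\mathrm{Logit}(P) = 2.327 \cdot \mathrm{WT/D} + 0.184 \cdot \mathrm{AVI}
  + 3.215 \cdot \mathrm{FD} - 5.871,$$

read as the probability of stage II+III versus stage I. No real images are
redistributable, so the package is organised around seeded digital phantoms
and cohort simulation: every measurement operator is validated by recovering
ground truth it was never shown.

## Coordinate and volume conventions

Volumes are stored `[z, y, x]` with `z` the slice axis; voxel indices are
0-based and the world transform is the diagonal affine
`world = origin + index * spacing` (no rotation matrix — phantoms are
generated axis-aligned, and every geometric test stays analytic).
Out-of-volume samples default to −1024 HU (air), a conservative choice for
wall and cuff detection: air can never masquerade as soft tissue. The "lung
window" display convention is centre −600 / width 1500 HU; the source
protocol names the window but not its values, so these are configurable
defaults only — no measurement depends on them.

Because no NIfTI reader is available in the supported dependency set,
volumes round-trip through a float64 little-endian raw payload plus a JSON
sidecar (dimensions, spacing, origin, md5 checksum, optional ground truth).
The round-trip is bit-exact.

## Wall morphometry (WT/D)

`measure_wall()` follows the airway-morphometry FWHM convention: rays are
cast from the lumen centroid; on each ray the inner edge is the
half-maximum crossing between the lumen and wall plateaus and the outer
edge the half-maximum crossing between wall and parenchyma; sub-sample
positions come from linear interpolation. `D` is twice the mean inner-edge
radius (the protocol says only "inner diameter", so the mean-radius
definition is ours and is stated in the docs), `WT` the mean edge
difference; 72 rays by default, and a measurement fails honestly when more
than 25% of rays find no closed wall.

One deliberate deviation from textbook FWHM: the plateau levels are
estimated *globally* (lumen: median over the connected air region; wall:
maximum over all ray peaks; parenchyma: median of the profile tails beyond
the wall). With ~1 mm walls on a 0.62 mm grid the per-ray peak is
partial-volume attenuated, and half-levels derived from it bias WT/D high
by ≈ +0.02 — enough to swamp the stage-I/stage-II contrast. Global levels
remove that bias: the half-maximum crossings sit on ramp segments that the
opposite edge's blur cannot reach, so recovery on noise-free phantoms is
accurate to ≈0.003 in the ratio.

Resolution still matters in two documented ways. First, at the default
0.62 mm isotropic grid the residual curvature-kernel bias keeps mean
absolute recovery error within one within-stage SD of each design point
(0.02/0.02/0.03), which is the package's acceptance bar; at 0.31 mm the
error is an order of magnitude smaller. Second, the wall plateau can only
be sampled purely when some reformation pixel lands on a pure-wall voxel;
reformation grids centred on the structure at half the voxel pitch (the
targeted-recon convention, used throughout the tests) guarantee that for
axis-aligned sections. A misaligned grid can attenuate the apparent plateau
and inflate WT/D by ~0.03 at 0.62 mm — worth knowing before trusting
absolute (rather than rank) values at scanner resolution.

## Bifurcation angle and AVI

Branch directions are the dominant eigenvector of the centerline-point
scatter within 10 mm of the vertex, oriented away from it; the bifurcation
angle is the arccos of their dot product — fully 3D, as the protocol's
"vector method" prescribes even though readings are anchored on oblique
coronal views. AVI is `|angle − 110°|`; the ±15° attached to the reference
is the population spread, not part of the statistic. With 0.1 mm isotropic
jitter on the centerlines the PCA direction stays within 2° of truth, well
inside the smallest within-stage SD (1.15°).

## Peribronchial fractal dimension

`box_counting_fd()` counts occupied boxes at dyadic scales, each scale
averaged over four grid offsets, and reads FD from the log–log slope. Two
estimator details depart from the naive recipe, both forced by its failure
on the package's own analytic fixtures: boxes clipped by the image edge are
weighted by the fraction of their area inside the image (otherwise a filled
81×81 square measures 1.88, not 2.00), and the single-pixel scale is dropped
whenever five or more dyadic scales exist (it is pixelisation-dominated and
drags the depth-4 Sierpinski carpet from 1.89 to 1.72). With both, the
filled square gives 2.0000, the carpet 1.8865 (analytic 1.8928) and a single
pixel 0.0000.

The pipeline's FD input is the binarised supra-threshold (>30 HU) pattern in
a 2 mm annulus outside the wall — the same soft-tissue cut the cuffing rule
uses, since the protocol states no separate FD binarisation rule; the
threshold is a logged argument. A homogeneous phantom has no such texture,
so the pipeline reports FD as `NA` there rather than inventing a value.

For controlled FD ground truth the texture generator offers a filled square,
the Sierpinski carpet, and fractional-Brownian (fBm) contours. The filled
excursion set of a thresholded fBm field always has box dimension 2, so the
generated pattern is the *iso-level contour* of the median-thresholded
field, whose dimension is 2−H. Finite-resolution box counting underestimates
that asymptotic value, so the generator maps a target FD to a Hurst exponent
through a frozen calibration table (measured dimension versus H at the
default 256 px size, 12 seeds per point, computed once with this package's
estimator). This is the stated design: H is chosen so the *expected
measured* box dimension equals the target. Targets within ≈[1.27, 1.79] are
calibrated; outside, the generator clamps and warns.

## Cuffing sign

The printed rule — soft tissue >30 HU around >50% of the circumference,
≥2 mm thick, continuous across >3 slices (read strictly: a run of ≥4
sections) — cannot be applied literally from "the outer wall edge": an
attached cuff (+50 HU) is radiologically continuous with the wall (+40 HU),
so the FWHM outer edge of a cuffed section *is* the cuff's outer edge and
the literal rule could never fire. `detect_cuffing()` therefore measures,
on 360 one-degree rays, the supra-threshold run outward from the *inner*
wall edge, and a ray qualifies when that run exceeds a reference
(uncuffed) wall thickness by the 2 mm bound. The reference defaults to the
minimum measured wall thickness across the stack — the thinnest section is
taken as the bronchus's own uncuffed wall. This reduces to the printed rule
whenever wall and cuff are separable, and it degrades predictably when
every section of a stack is cuffed (the reference is then contaminated and
the detector under-calls); that case is the stated limitation. Raising any
threshold can only turn positives negative, never the reverse, and the
property suite checks that monotonicity on randomized phantoms.

## Reformation

Oblique sections are trilinear resamples on orthonormal plane axes (exact
for affine HU fields, which the tests exploit as an oracle). Curved planar
reformation resamples perpendicular to an arc-length-uniform centerline;
in-plane frames use the double-reflection rotation-minimising construction,
which avoids torsion-induced twist — consecutive frame rotation stays below
10° at 0.5 mm steps on smooth paths. `smooth_centerline()` fits an
interpolating natural cubic spline against chord length and re-parameterises
by arc length on a dense evaluation; the output's `arc_length` records
positions on the fitted curve (exactly uniform by construction) and chord
sums agree with them to curvature order.

## Synthetic cohorts: what they do and do not establish

`cohort_spec()` encodes the reference population: 42/16/7 patients in
stages I/II/III; WT/D 0.26/0.30/0.35 (SD 0.02/0.02/0.03); AVI
8.27/12.64/16.92° (SD 1.15/1.87/2.46); FD 1.41/1.57/1.68 (SD
0.08/0.09/0.10); cuffing rates 15/42, 11/16, 6/7; auxiliary variables
(vascular calcification score, lung volume, pulmonary artery diameter) with
within-stage Gaussian-copula correlations 0.612, −0.532 and 0.479 to their
anchor parameters. Within a stage the three model parameters are drawn
independently — the source tables report no within-stage covariance, and the
sidecar metadata flags that assumption explicitly. Note the printed pooled
correlations are matched *within stage*; pooled over stages the simulated
correlations run higher because the stage means themselves co-vary.

These idealized cohorts are *cleaner* than the real one: independent
Gaussians, no measurement error, no transitional-case ambiguity. Two
consequences are documented rather than hidden. The published model's mean
AUC over 200 replicates is ≈0.996, above the real-cohort 0.911 — the
acceptance criterion treats the printed value as a floor, which these
cohorts clear easily. And the two-cut stage-calling rule (`fit_stage_cuts()`
maximises macro-averaged per-stage concordance on a labelled table; the rule
itself is our documented stand-in, since no printed mapping from score to
the three stages exists) cannot reproduce the printed per-stage error rates:
simulated stage-II concordance averages ≈89% versus the printed 68.75%.
Only the qualitative pattern survives — the transitional middle stage has
the lowest mean concordance — and that is what the tests assert.

## Staging statistics

Z-scoring uses the sample-SD (n−1) convention and stores its parameters for
exact inversion. `lasso_select()` standardises candidates, runs an
L1-penalised logistic path with stratified 10-fold cross-validation
(deterministic under its seed), selects λ by minimum mean held-out binomial
deviance — the stated criterion — and refits the selected features by
unpenalised logistic regression *on the raw scale*, which is the form the
published coefficients (with their standard errors) correspond to.
Separation in the refit is flagged, not hidden. The deviance-minimum rule is
known to drag noise variables along (selection rates ≈0.4–0.6 for pure-noise
features in the validation simulation); the conventional sparser
one-standard-error rule is exposed as `rule = "1se"` (noise rates ≈0) with
the default kept at the stated minimum-deviance criterion.

## Evaluation statistics

AUC is the Mann–Whitney statistic with ties counted ½ (tested exactly
against the all-pairs oracle), the cutoff maximises Youden's index with ties
to the lower cutoff, and the 95% interval uses the DeLong variance (the
source does not state its CI method). ICC is fixed to ICC(2,1) — two-way
random, absolute agreement, single measures — with McGraw–Wong F-based
intervals; the source says only "ICC". Weighted kappa defaults to linear
weights (source silent; quadratic available) with the Fleiss–Cohen–Everitt
asymptotic SE, checked to 1e−12 against a direct-summation oracle.
Percentages in concordance tables are rounded to 2 decimals to match the
printed convention.

Two printed quantities are excluded from validation as irreproducible from
the printed inputs: the cuffing-sign chi-square (the printed counts give
≈9.24, not 11.264) and the per-row weighted kappas of the staging
concordance table (not reproducible under any standard one-vs-rest
weighting). The combined model's printed sensitivity/specificity also
disagree between the text (92.3/88.6) and its table (81.4/89.8); the package
reports what it computes and leaves the discrepancy to this note.

## Numerical choices and degenerate inputs

* Ray casting: 0.05 mm radial step; rays with lumen-wall contrast <200 HU
  are invalid; >25% invalid rays fail the measurement with diagnostics.
* Stage calling: cuts are score midpoints; ties in the objective break to
  the first candidate, so calls are bit-reproducible.
* Box counting requires ≥27×27 px and ≥4 dyadic scales; an empty foreground
  is an error (FD of the empty set is undefined, not 0).
* Degenerate inputs error early and loudly: zero-variance z-score columns,
  single-class outcomes, non-orthonormal plane axes, self-intersecting or
  duplicated centerline points, NaN voxels, non-positive spacing.

## Known limitations

* No airway segmentation or automatic centerline extraction: centerlines
  are inputs, as in the manual-tracing protocol this mirrors.
* No scanner PSF, beam hardening, dose or motion modelling; phantom noise
  is i.i.d. Gaussian at the measured scanner level (12.4 HU).
* Absolute WT/D at 0.62 mm resolution carries a small positive
  resolution bias (within one within-stage SD); ranks and stage contrasts
  are unaffected.
* The cuffing reference-wall convention under-calls when every available
  section is cuffed.
* Synthetic cohorts validate the statistical machinery, not clinical
  accuracy: a green suite says the pipeline recovers what it was designed
  to recover, nothing more.
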