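# bvbquant

Quantitative CT morphometry of the bronchovascular bundle (BVB) for staging
pneumoconiosis — an occupational diffuse pulmonary fibrosis that distorts the
paired bronchus + pulmonary artery as it progresses. Conventional axial CT
reads these obliquely oriented structures poorly; `bvbquant` implements the
multiplanar/curved-planar reformation route: resample the volume
perpendicular to the structure, measure the airway wall there, and combine
three quantitative parameters into a logistic staging score.

The package is aimed at imaging researchers who want a fully synthetic,
seeded test bed for BVB morphometry: every measurement stage is validated by
recovery against digital phantoms with analytic ground truth, and the
statistical pipeline is validated against the published cohort-level
quantities.

## The three parameters and the staging model

For a bronchus resampled perpendicular to its centerline:

* **WT/D** — perpendicular wall thickness over inner lumen diameter at the
  narrowest cross-section, measured by full-width-half-maximum (FWHM) ray
  casting from the lumen centroid. An airway-remodelling index.
* **AVI** (angle variation index) — `|θ − 110°|`, the absolute deviation of
  the 3D vascular bifurcation angle θ (vector method on branch centerlines)
  from the healthy-population reference of 110°.
* **FD** — box-counting fractal dimension of the supra-threshold (>30 HU)
  peribronchial texture in a 2 mm annulus outside the wall.
* **Cuffing sign** — a rule-based detector: soft tissue (>30 HU) around more
  than 50% of the circumference, at least 2 mm thick, continuous across more
  than 3 consecutive sections.

The combined staging score is the published raw-scale logistic model

```
Logit(P) = 2.327 × WT/D + 0.184 × AVI + 3.215 × FD − 5.871
```

with `P = 1 / (1 + exp(−Logit))` discriminating stage II+III from stage I.
Supporting statistics: ROC/AUC (Mann–Whitney, DeLong 95% CI, Youden-optimal
cutoff), Lasso feature selection with 10-fold cross-validated binomial
deviance and an unpenalised refit, ICC(2,1), Cohen's/weighted kappa, and
per-stage concordance tables.

## Worked example

```r
library(bvbquant)

# a seeded airway phantom: 4 mm lumen, 1.04 mm wall (true WT/D = 0.26),
# scanner-level noise (12.4 HU), 0.62 mm voxels
ph <- make_airway_phantom(
  airway_phantom_spec(lumen_diameter = 4, wall_thickness = 1.04,
                      noise_sd = 12.4, seed = 1)
)
ctr <- ph$ground_truth$center_mm
sec <- resample_plane(ph$volume,
  oblique_plane(ctr, u_axis = c(0, 0, 1), v_axis = c(0, 1, 0),
                extent = c(13.64, 13.64), pixel_size = 0.31))
measure_wall(sec)
#> <airway_measurement> D 3.89 mm, WT 1.05 mm, WT/D 0.270 (72/72 rays)

# a 65-patient cohort at the per-stage reference moments, scored and staged
cohort <- simulate_cohort(seed = 1)
scored <- combined_logit(cohort)            # published model
roc    <- roc_auc(scored$logit, as.integer(scored$stage >= "II"))
roc
#> <roc_result> AUC 1.000 (95% CI 1.000-1.000); cutoff 1.758: sens 100.0%,
#>   spec 100.0%, Youden 1.000
```

The phantom measurement recovers the designed WT/D of 0.26 to within the
cohort's stage-I spread (±0.02); the simulated cohort is cleaner than any
real one (independent Gaussian parameters, no measurement error), which is
why its single-seed AUC saturates — across 200 seeds the mean AUC is ≈0.996,
comfortably above the 0.911 reported for the real cohort that the synthetic
moments were taken from.

The end-to-end demo (`run_pipeline(run_config(seed = 7))`) writes
`metrics.csv`, `staged.csv`, `report.json` (AUC, per-stage concordance,
weighted kappa, ICC) and a reproducibility manifest.

## Acceptance script

```
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates, from scratch, 200 seeded replicate cohorts (42/16/7 patients in
stages I/II/III drawn from the per-stage reference means/SDs), scores every
patient with the published combined model, computes the stage II+III vs I
AUC per replicate, and writes the mean AUC as JSON.

## Layout

* `R/` — volumes & I/O, centerlines, reformation, phantom/cohort generators,
  morphometry, staging, evaluation, pipeline, tidiers, plots
* `tests/testthat/` — unit, property and acceptance suites (all fixtures
  generated in code)
* `vignettes/bvb-morphometry.Rmd` — methods: models, assumptions, numerical
  choices, limitations
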