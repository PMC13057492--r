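Package: bvbquant
Title: Quantitative CT Morphometry of the Bronchovascular Bundle for
    Pneumoconiosis Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital-phantom driven pipeline for quantitative computed
    tomography of the bronchovascular bundle. Provides voxel-volume
    containers with trilinear sampling and lung windowing, oblique
    multiplanar and curved planar reformation along centerlines,
    full-width-half-maximum airway wall morphometry (wall
    thickness-to-diameter ratio), three-dimensional vascular bifurcation
    angles and the angle variation index, box-counting fractal dimension
    of the peribronchial texture, and a rule-based peribronchial cuffing
    sign detector. Includes seeded generators for HU-calibrated airway,
    bifurcation and fractal-texture phantoms and for per-stage patient
    cohorts; an L1-penalised logistic feature-selection step with
    cross-validation and unpenalised refit; the published combined
    logistic staging score; and diagnostic-performance and agreement
    statistics (ROC/AUC with DeLong intervals and Youden cutoffs,
    intraclass correlation, weighted kappa, per-stage concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
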