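## End-to-end orchestration: per-case measurement wrapper, run configuration
## and manifest, and the demo pipeline chaining cohort -> score -> stage ->
## evaluate.

#' Measure one bronchovascular-bundle case
#'
#' Chains the measurement stages on one volume: curved planar reformation
#' along the airway centerline, wall morphometry at the narrowest section,
#' peribronchial box-counting FD in the 2 mm annulus (binarised at the same
#' 30 HU soft-tissue cut used by the cuffing rule), the cuffing-sign rule
#' over the stack, and - when daughter-branch centerlines are supplied -
#' the 3D bifurcation angle and AVI.
#'
#' @param vol A [voxel_volume].
#' @param airway_cl A [centerline] along the bronchus.
#' @param daughter_cls Optional list of two daughter [centerline]s for the
#'   bifurcation angle.
#' @param vertex Bifurcation vertex (world mm, `(z, y, x)`); default the
#'   shared first point of the daughter centerlines.
#' @param width,pixel_size CPR geometry (mm).
#' @param fd_band_mm Peribronchial annulus width in mm.
#' @param fd_threshold HU binarisation threshold for the FD input.
#' @param avi_reference Reference bifurcation angle in degrees.
#' @param ... Passed to [measure_wall()].
#' @return One-row tibble: `wt_d`, `avi_deg`, `fd`, `cuffing`, plus QC
#'   columns (`inner_diameter_d`, `fit_r2`, `rays_valid`, `coverage`).
#' @export
measure_case <- function(vol, airway_cl, daughter_cls = NULL, vertex = NULL,
                         width = 20, pixel_size = 0.31, fd_band_mm = 2,
                         fd_threshold = 30, avi_reference = 110, ...) {
  stack <- curved_planar_reformation(vol, airway_cl,
    width = width, pixel_size = pixel_size, step = min(vol$spacing)
  )
  nar <- find_narrowest_section(stack, ...)
  w <- nar$measurement
  fd_res <- tryCatch({
    roi <- peribronchial_roi(nar$section, w, band_mm = fd_band_mm)
    box_counting_fd((nar$section$image > fd_threshold) & roi,
      pixel_size = pixel_size)
  }, error = function(e) NULL)
  cuff <- detect_cuffing(stack, hu_threshold = fd_threshold)
  avi <- NA_real_
  if (!is.null(daughter_cls)) {
    stopifnot(length(daughter_cls) == 2L)
    if (is.null(vertex)) vertex <- daughter_cls[[1]]$points[1, ]
    d1 <- branch_direction(daughter_cls[[1]], vertex)
    d2 <- branch_direction(daughter_cls[[2]], vertex)
    avi <- compute_avi(bifurcation_angle(d1, d2), avi_reference)
  }
  tibble::tibble(
    wt_d = w$wt_d_ratio,
    avi_deg = avi,
    fd = if (is.null(fd_res)) NA_real_ else fd_res$fd,
    cuffing = as.integer(cuff$positive),
    inner_diameter_d = w$inner_diameter_d,
    fit_r2 = if (is.null(fd_res)) NA_real_ else fd_res$fit_r2,
    rays_valid = w$n_valid_rays / w$n_rays,
    coverage = cuff$coverage_fraction
  )
}

#' Run configuration
#'
#' Bundles the knobs of a pipeline run. The seed is mandatory because the
#' cohort and rater simulations are stochastic; every threshold is echoed
#' verbatim into the run manifest.
#'
#' @param seed Integer seed (mandatory).
#' @param out_dir Output directory.
#' @param cohort A [cohort_spec()].
#' @param model `"published"` or `"fit"` (Lasso selection + refit).
#' @param cuts Optional fixed stage cuts; fitted on the cohort when `NULL`.
#' @param rater_icc Design value of the simulated interobserver ICC for the
#'   duplicate WT/D reading.
#' @param fd_threshold,avi_reference,cuff Measurement thresholds, echoed to
#'   the manifest.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed, out_dir = tempfile("bvbquant_run_"),
                       cohort = cohort_spec(), model = c("published", "fit"),
                       cuts = NULL, rater_icc = 0.923, fd_threshold = 30,
                       avi_reference = 110,
                       cuff = list(hu_threshold = 30, min_coverage = 0.5,
                                   min_thickness_mm = 2, min_slices = 3)) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("validation error: `seed` is mandatory for stochastic stages",
      call. = FALSE)
  }
  model <- match.arg(model)
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, cohort = cohort,
         model = model, cuts = cuts, rater_icc = rater_icc,
         fd_threshold = fd_threshold, avi_reference = avi_reference,
         cuff = cuff),
    class = "run_config"
  )
}

#' Run the cohort-level demo pipeline
#'
#' Simulates a cohort under the configured specification, scores every
#' patient with the combined model (published, or Lasso-selected and refit),
#' fits or applies the two-cut stage rule, simulates a duplicate WT/D
#' reading at the configured interobserver ICC, and writes `metrics.csv`,
#' `staged.csv`, `report.json` and `manifest.json` to the output directory.
#' Deterministic given the seed; any stage failure aborts with the stage
#' name in the error.
#'
#' @param config A [run_config()].
#' @return The run manifest (invisibly also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  warns <- character()
  step <- function(name, expr) {
    t <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE)
    })
    timings[[name]] <<- round(as.numeric(Sys.time() - t, units = "secs"), 3)
    out
  }

  cohort <- step("cohort", simulate_cohort(config$cohort, seed = config$seed))

  model <- step("model", {
    if (config$model == "published") {
      published_staging_model()
    } else {
      ls <- lasso_select(cohort, seed = config$seed)
      td <- generics::tidy(ls)
      cf <- stats::setNames(td$estimate[td$term != "(Intercept)"],
        td$term[td$term != "(Intercept)"])
      staging_model(cf, td$estimate[td$term == "(Intercept)"])
    }
  })

  scored <- step("score", combined_logit(cohort, model = model))
  cuts <- if (is.null(config$cuts)) {
    step("cuts", fit_stage_cuts(scored$logit, scored$stage))
  } else config$cuts
  staged <- step("stage", call_stage(scored, cuts))

  evalr <- step("evaluate", {
    roc <- roc_auc(staged$logit, as.integer(staged$stage >= "II"))
    conc <- concordance_table(staged$stage, staged$called_stage)
    # duplicate WT/D reading at the configured interobserver ICC
    set.seed(config$seed + 1L)
    sd_subj <- stats::sd(staged$wt_d)
    sd_err <- sd_subj * sqrt(1 / config$rater_icc - 1)
    ratings <- cbind(
      staged$wt_d + stats::rnorm(nrow(staged), 0, sd_err),
      staged$wt_d + stats::rnorm(nrow(staged), 0, sd_err)
    )
    list(
      roc = roc, concordance = conc, icc = icc(ratings),
      kappa_staging = kappa_agreement(staged$stage, staged$called_stage,
        weights = "linear")
    )
  })

  metrics_path <- file.path(config$out_dir, "metrics.csv")
  staged_path <- file.path(config$out_dir, "staged.csv")
  utils::write.csv(scored, metrics_path, row.names = FALSE)
  utils::write.csv(staged, staged_path, row.names = FALSE)
  report <- list(
    auc = evalr$roc$auc,
    auc_ci_95 = evalr$roc$ci_95,
    cutoff = evalr$roc$cutoff,
    sensitivity = evalr$roc$sensitivity,
    specificity = evalr$roc$specificity,
    youden = evalr$roc$youden,
    stage_cuts = cuts,
    per_stage_concordance = stats::setNames(
      as.list(evalr$concordance$per_class$concordance_pct),
      evalr$concordance$per_class$stage
    ),
    weighted_kappa = evalr$kappa_staging$kappa,
    weighted_kappa_se = evalr$kappa_staging$se,
    icc = evalr$icc$icc,
    icc_ci_95 = evalr$icc$ci
  )
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("bvbquant")),
    config = list(
      seed = config$seed, model = config$model, cuts = cuts,
      rater_icc = config$rater_icc, fd_threshold = config$fd_threshold,
      avi_reference = config$avi_reference, cuff = config$cuff,
      group_sizes = config$cohort$group_sizes
    ),
    outputs = list(
      metrics_csv = unname(tools::md5sum(metrics_path)),
      staged_csv = unname(tools::md5sum(staged_path)),
      report_json = unname(tools::md5sum(report_path))
    ),
    timings_s = timings,
    total_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3),
    warnings = warns
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(manifest, class = "run_manifest"))
}
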