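## broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.airway_measurement <- function(x, ...) {
  tibble::tibble(
    inner_diameter_d = x$inner_diameter_d,
    wall_thickness_wt = x$wall_thickness_wt,
    wt_d_ratio = x$wt_d_ratio,
    arc_position = x$arc_position,
    rays_valid = x$n_valid_rays / x$n_rays
  )
}

#' @export
tidy.staging_model <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$coefficients), "(Intercept)"),
    estimate = c(unname(x$coefficients), x$intercept)
  )
}

#' @export
tidy.lasso_result <- function(x, ...) {
  if (is.null(x$refit)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
      std.error = numeric(), statistic = numeric(), p.value = numeric()))
  }
  s <- summary(x$refit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @export
glance.lasso_result <- function(x, ...) {
  tibble::tibble(
    lambda_opt = x$lambda_opt,
    cv_deviance_min = min(x$cv_deviance),
    n_selected = length(x$selected_features),
    separation = x$separation,
    folds = x$folds, n = x$n
  )
}

#' @export
tidy.roc_result <- function(x, ...) x$roc_points

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, ci_low = x$ci_95[1], ci_high = x$ci_95[2],
    cutoff = x$cutoff, sensitivity = x$sensitivity,
    specificity = x$specificity, youden = x$youden,
    n_cases = x$n_cases, n_controls = x$n_controls
  )
}

#' @export
tidy.fractal_result <- function(x, ...) {
  tibble::tibble(box_size = x$box_sizes, box_count = x$box_counts)
}

#' @export
glance.fractal_result <- function(x, ...) {
  tibble::tibble(fd = x$fd, fit_r2 = x$fit_r2, n_scales = length(x$box_sizes))
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, ci_low = x$ci[1], ci_high = x$ci[2],
    n_subjects = x$n_subjects, n_raters = x$n_raters
  )
}

#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa, se = x$se, ci_low = x$ci_95[1], ci_high = x$ci_95[2],
    weights = x$weights, n = x$n
  )
}

#' @export
tidy.concordance_result <- function(x, ...) x$per_class

#' @export
tidy.cuffing_result <- function(x, ...) {
  tibble::tibble(
    positive = x$positive, coverage_fraction = x$coverage_fraction,
    cuff_thickness_mm = x$cuff_thickness_mm,
    consecutive_slices = x$consecutive_slices,
    reference_wt_mm = x$reference_wt_mm
  )
}
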