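## ggplot2 graphics for the result types.

#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- object$roc_points
  op <- tibble::tibble(fpr = 1 - object$specificity, tpr = object$sensitivity)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = op, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)",
        object$auc, object$ci_95[1], object$ci_95[2])
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cross_section <- function(object, window = window_setting(), ...) {
  img <- object$image
  lo <- window$center - window$width / 2
  disp <- pmin(pmax((img - lo) / window$width, 0), 1)
  df <- expand.grid(
    v = (seq_len(nrow(img)) - 1) * object$pixel_size,
    u = (seq_len(ncol(img)) - 1) * object$pixel_size
  )
  df$value <- as.vector(disp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
      fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (mm)", y = "v (mm)", fill = "windowed HU") +
    ggplot2::theme_minimal()
}

#' Per-stage distribution plot of the three quantitative parameters
#'
#' Boxplots of WT/D, AVI and FD by stage for a simulated or measured cohort.
#'
#' @param cohort Tibble with `stage`, `wt_d`, `avi_deg`, `fd` columns.
#' @return A ggplot object.
#' @export
plot_cohort_distributions <- function(cohort) {
  long <- tidyr::pivot_longer(
    cohort[, c("stage", "wt_d", "avi_deg", "fd")],
    cols = c("wt_d", "avi_deg", "fd"),
    names_to = "parameter", values_to = "value"
  )
  long$parameter <- factor(long$parameter,
    levels = c("wt_d", "avi_deg", "fd"),
    labels = c("WT/D", "AVI (deg)", "FD")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Clinical stage", y = NULL) +
    ggplot2::theme_minimal()
}
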