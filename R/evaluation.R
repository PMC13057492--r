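## Diagnostic-performance and agreement statistics: ROC/AUC with DeLong
## intervals and Youden cutoffs, Pearson correlation, ICC(2,1), Cohen's and
## weighted kappa, per-stage concordance.

#' ROC analysis with DeLong interval and Youden-optimal cutoff
#'
#' AUC by the Mann-Whitney formulation (ties counted 1/2); the operating
#' cutoff maximises the Youden index over all observed scores with the rule
#' "positive if score >= cutoff" (ties break to the lower cutoff); the 95%
#' AUC interval uses the DeLong variance.
#'
#' @param scores Numeric per-subject scores (higher = more disease).
#' @param labels Binary 0/1 labels (1 = case).
#' @return A `roc_result`: `auc`, `ci_95`, `roc_points` tibble (fpr, tpr),
#'   `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong variance from placements
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yi) mean((x > yi) + 0.5 * (x == yi)), numeric(1))
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  half <- stats::qnorm(0.975) * sqrt(max(var_auc, 0))
  ci <- c(max(0, auc - half), min(1, auc + half))
  # ROC curve over all thresholds (score >= t -> positive)
  th <- sort(unique(scores))
  tpr <- vapply(th, function(t) mean(x >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(y >= t), numeric(1))
  youden_all <- tpr - fpr
  best <- which(youden_all >= max(youden_all) - 1e-12)
  bi <- best[which.min(th[best])]
  pts <- tibble::tibble(
    cutoff = c(-Inf, th), fpr = c(1, fpr), tpr = c(1, tpr)
  )
  pts <- pts[order(pts$fpr, pts$tpr), ]
  structure(
    list(
      auc = auc, ci_95 = ci, roc_points = pts,
      cutoff = th[bi], sensitivity = tpr[bi], specificity = 1 - fpr[bi],
      youden = youden_all[bi], n_cases = n1, n_controls = n0
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (95%% CI %.3f-%.3f); cutoff %.4g: sens %.1f%%, spec %.1f%%, Youden %.3f\n",
    x$auc, x$ci_95[1], x$ci_95[2], x$cutoff,
    100 * x$sensitivity, 100 * x$specificity, x$youden
  ))
  invisible(x)
}

#' Youden index
#'
#' @param sensitivity,specificity Fractions in `[0, 1]`.
#' @return `sensitivity + specificity - 1`, vectorised.
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  sensitivity + specificity - 1
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation; p-value from the t transform with n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors, n >= 3, both with positive SD.
#' @return A tibble: `r`, `p_value`, `conf_low`, `conf_high`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate), p_value = ct$p.value,
    conf_low = ct$conf.int[1], conf_high = ct$conf.int[2], n = length(x)
  )
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measures, from the
#' two-way ANOVA mean squares; the 95% confidence interval follows the
#' F-distribution method of McGraw & Wong.
#'
#' @param ratings Numeric matrix, subjects x raters (>= 5 subjects, >= 2
#'   raters, no missing cells).
#' @param conf_level Confidence level for the interval.
#' @return An `icc_result`: `icc`, `ci`, the mean squares, and dimensions.
#' @export
icc <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 5L || k < 2L) stop("need >= 5 subjects and >= 2 raters", call. = FALSE)
  if (anyNA(ratings)) stop("missing cells are not supported", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_lo <- stats::qf(1 - alpha / 2, n - 1, v)
  f_hi <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_lo * mse) /
    (f_lo * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_hi * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_hi * msr)
  structure(
    list(icc = est, ci = c(lower, upper), conf_level = conf_level,
         msr = msr, msc = msc, mse = mse, n_subjects = n, n_raters = k),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.3f (%.0f%% CI %.3f-%.3f), %d subjects x %d raters\n",
    x$icc, 100 * x$conf_level, x$ci[1], x$ci[2], x$n_subjects, x$n_raters))
  invisible(x)
}

#' Cohen's kappa and weighted kappa with asymptotic SE
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with identity,
#' linear, or quadratic agreement weights; the standard error uses the
#' asymptotic formula of Fleiss, Cohen & Everitt.
#'
#' @param c1,c2 Categorical ratings of equal length (factors share the union
#'   of levels).
#' @param weights `"none"`, `"linear"`, or `"quadratic"`.
#' @return A `kappa_result`: `kappa`, `se`, `ci_95`, `weights`, `confusion`.
#' @export
kappa_agreement <- function(c1, c2, weights = c("none", "linear", "quadratic")) {
  weights <- match.arg(weights)
  stopifnot(length(c1) == length(c2))
  lev <- sort(union(unique(as.character(c1)), unique(as.character(c2))))
  f1 <- factor(as.character(c1), levels = lev)
  f2 <- factor(as.character(c2), levels = lev)
  tab <- table(f1, f2)
  n <- sum(tab)
  K <- length(lev)
  p <- tab / n
  i <- matrix(seq_len(K), K, K)
  j <- t(i)
  w <- switch(weights,
    none = (i == j) * 1,
    linear = 1 - abs(i - j) / (K - 1),
    quadratic = 1 - ((i - j) / (K - 1))^2
  )
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pi_, pj_))
  if (1 - pe < 1e-12) stop("degenerate marginals: expected agreement is 1",
    call. = FALSE)
  kap <- (po - pe) / (1 - pe)
  wbar_i <- as.numeric(w %*% pj_)      # row-wise expected weight
  wbar_j <- as.numeric(t(w) %*% pi_)   # column-wise expected weight
  dev <- w - outer(wbar_i, wbar_j, function(a, b) a + b) * (1 - kap)
  se2 <- (sum(p * dev^2) - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(se2, 0))
  structure(
    list(
      kappa = kap, se = se,
      ci_95 = c(kap - stats::qnorm(0.975) * se, kap + stats::qnorm(0.975) * se),
      weights = weights, confusion = tab, n = n
    ),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa = %.3f (SE %.3f, %s weights, n = %d)\n",
    x$kappa, x$se, x$weights, x$n))
  invisible(x)
}

#' Confusion matrix and per-stage concordance
#'
#' K x K confusion counts (rows = true stages) and the per-class concordance
#' rate, diagonal count over row total, as a percentage.
#'
#' @param true_stage,called_stage Equal-length stage vectors (factors share
#'   the union of levels).
#' @return A `concordance_result`: `confusion` (matrix), `per_class` tibble
#'   (`stage`, `n`, `concordant`, `concordance_pct`), `overall_pct`.
#' @export
concordance_table <- function(true_stage, called_stage) {
  stopifnot(length(true_stage) == length(called_stage))
  lev <- union(levels(factor(true_stage)), levels(factor(called_stage)))
  t1 <- factor(as.character(true_stage), levels = lev)
  t2 <- factor(as.character(called_stage), levels = lev)
  tab <- table(true = t1, called = t2)
  diag_n <- diag(tab)
  row_n <- rowSums(tab)
  pct <- ifelse(row_n > 0, 100 * diag_n / row_n, NA_real_)
  structure(
    list(
      confusion = tab,
      per_class = tibble::tibble(
        stage = lev, n = as.integer(row_n),
        concordant = as.integer(diag_n),
        concordance_pct = round(as.numeric(pct), 2)
      ),
      overall_pct = round(100 * sum(diag_n) / sum(tab), 2)
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result>\n")
  print(x$confusion)
  print(as.data.frame(x$per_class), row.names = FALSE)
  invisible(x)
}
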