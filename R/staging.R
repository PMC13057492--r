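## Feature standardisation, L1-penalised logistic selection with
## cross-validation, the published combined score, and stage calling.

#' Z-score standardisation of feature columns
#'
#' Standardises the model columns with the sample SD (n - 1) convention and
#' stores the per-column centre/scale so the transform can be inverted.
#'
#' @param table A data frame of per-patient features.
#' @param cols Columns to standardise (default the three model parameters).
#' @return A tibble with standardised columns and attributes
#'   `zscore_center`, `zscore_scale`, `z_scored = TRUE`.
#' @seealso [zscore_invert()]
#' @export
zscore <- function(table, cols = c("wt_d", "avi_deg", "fd")) {
  stopifnot(all(cols %in% names(table)))
  out <- tibble::as_tibble(table)
  ctr <- scl <- stats::setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    x <- out[[cl]]
    if (anyNA(x)) stop("missing values in model column ", cl, call. = FALSE)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("zero-variance column: ", cl, call. = FALSE)
    }
    ctr[cl] <- mean(x)
    scl[cl] <- s
    out[[cl]] <- (x - ctr[cl]) / s
  }
  attr(out, "zscore_center") <- ctr
  attr(out, "zscore_scale") <- scl
  attr(out, "z_scored") <- TRUE
  out
}

#' @rdname zscore
#' @param table_z A tibble produced by [zscore()].
#' @export
zscore_invert <- function(table_z) {
  ctr <- attr(table_z, "zscore_center")
  scl <- attr(table_z, "zscore_scale")
  if (is.null(ctr)) stop("input carries no z-score parameters", call. = FALSE)
  out <- table_z
  for (cl in names(ctr)) out[[cl]] <- out[[cl]] * scl[cl] + ctr[cl]
  attr(out, "zscore_center") <- NULL
  attr(out, "zscore_scale") <- NULL
  attr(out, "z_scored") <- NULL
  out
}

#' Combined logistic staging model
#'
#' The published combined model on the raw (unstandardised) scale:
#' `Logit(P) = 2.327 x WT/D + 0.184 x AVI + 3.215 x FD - 5.871`.
#'
#' @param coefficients Named coefficient vector (raw scale).
#' @param intercept Intercept.
#' @param published Logical flag marking the fixed published model.
#' @return An object of class `staging_model`.
#' @export
staging_model <- function(coefficients, intercept, published = FALSE) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
    is.numeric(intercept), length(intercept) == 1L)
  structure(
    list(coefficients = coefficients, intercept = unname(intercept),
         published = published, scale = "raw"),
    class = "staging_model"
  )
}

#' @rdname staging_model
#' @export
published_staging_model <- function() {
  staging_model(
    coefficients = c(wt_d = 2.327, avi_deg = 0.184, fd = 3.215),
    intercept = -5.871, published = TRUE
  )
}

#' @export
print.staging_model <- function(x, ...) {
  terms <- paste(sprintf("%.3f x %s", x$coefficients, names(x$coefficients)),
    collapse = " + ")
  cat(sprintf("<staging_model%s> Logit(P) = %s %+.3f\n",
    if (x$published) ", published" else "", terms, x$intercept))
  invisible(x)
}

#' Combined logit and probability
#'
#' Evaluates a staging model. With a data frame first argument the model
#' columns are taken from it and the scored tibble is returned; with
#' numeric vectors the logit/probability pair is returned directly.
#'
#' @param data A data frame containing the model columns, or a numeric
#'   vector of WT/D values.
#' @param avi_deg,fd Numeric vectors when `data` is numeric.
#' @param model A [staging_model]; default the published model.
#' @return For data-frame input: the tibble with `logit` and `probability`
#'   columns appended. For vector input: a tibble with `logit` and
#'   `probability`.
#' @examples
#' combined_logit(0.26, 8.27, 1.41)
#' @export
combined_logit <- function(data, avi_deg = NULL, fd = NULL,
                           model = published_staging_model()) {
  stopifnot(inherits(model, "staging_model"))
  if (is.data.frame(data)) {
    need <- names(model$coefficients)
    stopifnot(all(need %in% names(data)))
    X <- as.matrix(data[need])
    lg <- drop(X %*% model$coefficients) + model$intercept
    out <- tibble::as_tibble(data)
    out$logit <- lg
    out$probability <- stats::plogis(lg)
    return(out)
  }
  lg <- model$coefficients[["wt_d"]] * data +
    model$coefficients[["avi_deg"]] * avi_deg +
    model$coefficients[["fd"]] * fd + model$intercept
  tibble::tibble(logit = lg, probability = stats::plogis(lg))
}

#' L1-penalised logistic feature selection with cross-validated refit
#'
#' Standardises the candidate columns (z-scores), runs L1-penalised
#' logistic regression over a log-spaced lambda path with stratified k-fold
#' cross-validation, selects the lambda minimising the mean held-out
#' binomial deviance, and refits the selected features by unpenalised
#' logistic regression on the raw scale to obtain coefficients with
#' standard errors (the raw-scale refit is the form the published combined
#' model corresponds to).
#'
#' @param table Data frame with the candidate columns and outcome.
#' @param outcome Binary 0/1 vector, or the name of a column; default
#'   `stage >= II` when a `stage` column is present.
#' @param cols Candidate feature columns.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param rule Lambda selection rule: `"min"` (minimum mean held-out
#'   binomial deviance, the default) or `"1se"` (largest lambda within one
#'   standard error of the minimum, the sparser conventional alternative;
#'   cross-validation-minimum lasso is known to carry noise variables along).
#' @return A `lasso_result`: `lambda_path`, `cv_deviance`, `lambda_opt`,
#'   `selected_features`, `refit` (the unpenalised glm), and tidy
#'   coefficient tables via [generics::tidy()].
#' @export
lasso_select <- function(table, outcome = NULL, cols = c("wt_d", "avi_deg", "fd"),
                         folds = 10L, seed = 1L, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  stopifnot(all(cols %in% names(table)))
  if (is.null(outcome)) {
    if (!"stage" %in% names(table)) {
      stop("supply `outcome` or a `stage` column", call. = FALSE)
    }
    y <- as.integer(table$stage >= "II")
  } else if (is.character(outcome) && length(outcome) == 1L) {
    y <- as.integer(table[[outcome]])
  } else {
    y <- as.integer(outcome)
  }
  if (nrow(table) < 2L * folds) {
    stop("need at least 2 x folds rows", call. = FALSE)
  }
  if (length(unique(y)) < 2L) stop("outcome has a single class", call. = FALSE)
  tz <- zscore(table, cols)
  X <- as.matrix(tz[cols])
  set.seed(as.integer(seed))
  # stratified fold assignment so both classes appear in every fold
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    foldid[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  cv <- glmnet::cv.glmnet(X, y,
    family = "binomial", type.measure = "deviance",
    foldid = foldid, standardize = FALSE
  )
  lambda_opt <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.matrix(stats::coef(cv$glmnet.fit, s = lambda_opt))[-1, 1]
  selected <- names(beta)[beta != 0]
  refit <- NULL
  separation <- FALSE
  if (length(selected) > 0) {
    df <- data.frame(.y = y, table[selected], check.names = FALSE)
    refit <- withCallingHandlers(
      stats::glm(.y ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        msg <- conditionMessage(w)
        if (grepl("fitted probabilities numerically 0 or 1", msg) ||
            grepl("did not converge", msg)) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    if (separation) {
      warning("possible separation in the unpenalised refit; ",
        "coefficients may be unstable", call. = FALSE)
    }
  }
  structure(
    list(
      lambda_path = cv$lambda, cv_deviance = cv$cvm,
      lambda_opt = lambda_opt, selected_features = selected,
      glmnet_fit = cv$glmnet.fit, cv = cv, refit = refit,
      separation = separation, folds = folds, seed = as.integer(seed),
      rule = rule, n = length(y)
    ),
    class = "lasso_result"
  )
}

#' @export
print.lasso_result <- function(x, ...) {
  cat(sprintf(
    "<lasso_result> lambda_opt %.4g (min CV binomial deviance %.3f), selected: %s\n",
    x$lambda_opt, min(x$cv_deviance),
    if (length(x$selected_features)) paste(x$selected_features, collapse = ", ")
    else "(none)"
  ))
  invisible(x)
}

#' Fit two-cut thresholds for ordinal stage calling
#'
#' The continuous combined score is mapped to stages I/II/III by two ordered
#' cuts. Cuts are fit by maximising the macro-averaged per-stage concordance
#' (mean of the per-class diagonal proportions) over the grid of score
#' midpoints; ties break to the first candidate pair, so the fit is
#' deterministic.
#'
#' @param logit Numeric combined-score vector.
#' @param stage Ordered factor (or ordinal) of true stages with 3 levels.
#' @return Numeric length-2 vector of cuts (`cut1 < cut2`).
#' @export
fit_stage_cuts <- function(logit, stage) {
  stage <- as.integer(factor(stage))
  stopifnot(length(logit) == length(stage), max(stage) == 3L)
  s <- sort(unique(logit))
  cand <- (s[-1] + s[-length(s)]) / 2
  if (length(cand) < 2L) stop("too few distinct scores to place two cuts",
    call. = FALSE)
  best <- c(-Inf, Inf)
  best_obj <- -Inf
  for (i in seq_along(cand)) {
    called_lo <- logit > cand[i]
    for (j in seq_along(cand)) {
      if (cand[j] <= cand[i]) next
      called <- 1L + called_lo + (logit > cand[j])
      obj <- mean(vapply(1:3, function(k) {
        ik <- stage == k
        if (!any(ik)) return(NA_real_)
        mean(called[ik] == k)
      }, numeric(1)), na.rm = TRUE)
      if (obj > best_obj + 1e-12) {
        best_obj <- obj
        best <- c(cand[i], cand[j])
      }
    }
  }
  best
}

#' Call ordinal stages from combined scores
#'
#' Deterministic two-cut rule: scores at or below `cuts[1]` are stage I,
#' above `cuts[2]` stage III, otherwise stage II.
#'
#' @param logit Numeric combined-score vector, or a data frame with a
#'   `logit` column (e.g. from [combined_logit()]).
#' @param cuts Ordered numeric length-2 cut pair.
#' @return Ordered factor of stages (for data-frame input, the tibble with a
#'   `called_stage` column appended).
#' @export
call_stage <- function(logit, cuts) {
  if (any(diff(cuts) <= 0)) stop("cuts must be strictly increasing", call. = FALSE)
  if (is.data.frame(logit)) {
    out <- tibble::as_tibble(logit)
    out$called_stage <- call_stage(out$logit, cuts)
    return(out)
  }
  idx <- 1L + (logit > cuts[1]) + (logit > cuts[2])
  factor(c("I", "II", "III")[idx], levels = c("I", "II", "III"), ordered = TRUE)
}
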