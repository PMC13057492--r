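#' Centerline of a tubular structure
#'
#' An ordered 3D polyline in world mm defining reformation paths and branch
#' directions. Points are stored as an `n x 3` matrix in `(z, y, x)` order,
#' proximal to distal; `arc_length` is the cumulative length in mm per point
#' (chord sums unless set explicitly, e.g. by [smooth_centerline()]).
#'
#' @param points `n x 3` numeric matrix of world coordinates in mm `(z, y, x)`,
#'   with at least 2 distinct consecutive points.
#' @param arc_length Optional cumulative arc length per point; defaults to
#'   cumulative chord lengths.
#' @return An object of class `centerline`.
#' @export
centerline <- function(points, arc_length = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L) {
    stop("a centerline needs an n x 3 matrix with n >= 2", call. = FALSE)
  }
  if (any(!is.finite(points))) stop("centerline points must be finite", call. = FALSE)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] - points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive centerline points must be distinct", call. = FALSE)
  if (is.null(arc_length)) arc_length <- c(0, cumsum(seg))
  if (any(diff(arc_length) <= 0)) {
    stop("arc_length must be strictly increasing", call. = FALSE)
  }
  structure(list(points = unname(points), arc_length = as.numeric(arc_length)),
    class = "centerline"
  )
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf(
    "<centerline> %d points, length %.2f mm\n",
    nrow(x$points), max(x$arc_length)
  ))
  invisible(x)
}

#' Read centerlines from CSV or JSON
#'
#' CSV files carry columns `x_mm,y_mm,z_mm` in file order proximal to distal.
#' JSON files name branches: `{"parent": [[x,y,z], ...], "daughters":
#' [[[x,y,z], ...], [[x,y,z], ...]]}`. Coordinates are converted to the
#' package-internal `(z, y, x)` order.
#'
#' @param path Path to a `.csv` or `.json` centerline file.
#' @return A [centerline] for CSV input; a named list of [centerline]s
#'   (`parent`, `daughters`) for JSON input.
#' @export
read_centerline <- function(path) {
  if (!file.exists(path)) stop("centerline file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    as_cl <- function(m) {
      m <- matrix(as.numeric(unlist(m)), ncol = 3, byrow = !is.matrix(m))
      if (is.matrix(m) && ncol(m) == 3) centerline(m[, c(3, 2, 1), drop = FALSE])
    }
    out <- list()
    if (!is.null(obj$parent)) out$parent <- as_cl(obj$parent)
    if (!is.null(obj$daughters)) out$daughters <- lapply(obj$daughters, as_cl)
    return(out)
  }
  df <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop("centerline CSV must have columns x_mm,y_mm,z_mm", call. = FALSE)
  }
  centerline(cbind(df$z_mm, df$y_mm, df$x_mm))
}

#' Write a centerline to CSV
#'
#' @param cl A [centerline].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_centerline <- function(cl, path) {
  stopifnot(inherits(cl, "centerline"))
  df <- data.frame(x_mm = cl$points[, 3], y_mm = cl$points[, 2], z_mm = cl$points[, 1])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Smooth and arc-length-resample a centerline
#'
#' Fits a natural cubic spline per coordinate against the chord-length
#' parameter, then resamples at uniform arc-length steps along the fitted
#' curve. Endpoints are preserved; the maximum deviation of the fitted curve
#' from the raw polyline is reported as an attribute.
#'
#' @param raw A [centerline] with at least 4 points, no duplicated points.
#' @param spacing_step Target arc-length step in mm.
#' @return A [centerline] whose `arc_length` is exactly uniform on the fitted
#'   curve, with attribute `max_deviation_mm`.
#' @export
smooth_centerline <- function(raw, spacing_step) {
  stopifnot(inherits(raw, "centerline"))
  if (nrow(raw$points) < 4L) {
    stop("smooth_centerline needs at least 4 points", call. = FALSE)
  }
  if (anyDuplicated(raw$points)) {
    stop("centerline has duplicated points", call. = FALSE)
  }
  t0 <- raw$arc_length
  fz <- stats::splinefun(t0, raw$points[, 1], method = "natural")
  fy <- stats::splinefun(t0, raw$points[, 2], method = "natural")
  fx <- stats::splinefun(t0, raw$points[, 3], method = "natural")
  # dense evaluation for arc-length reparameterisation
  tf <- seq(min(t0), max(t0), length.out = max(2000L, 20L * length(t0)))
  P <- cbind(fz(tf), fy(tf), fx(tf))
  seg <- sqrt(rowSums((P[-1, ] - P[-nrow(P), ])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  s_out <- seq(0, total, by = spacing_step)
  if (abs(s_out[length(s_out)] - total) > 1e-9) s_out <- c(s_out, total)
  t_out <- stats::approx(s, tf, xout = s_out, ties = "ordered")$y
  out <- cbind(fz(t_out), fy(t_out), fx(t_out))
  out[1, ] <- raw$points[1, ]
  out[nrow(out), ] <- raw$points[nrow(raw$points), ]
  # deviation of raw vertices from the fitted curve at their own parameter
  # (zero for this interpolating fit; kept for smoothing variants)
  fit_at <- cbind(fz(t0), fy(t0), fx(t0))
  dev <- max(sqrt(rowSums((fit_at - raw$points)^2)))
  cl <- centerline(out, arc_length = s_out)
  attr(cl, "max_deviation_mm") <- dev
  cl
}

#' Local tangent directions of a centerline
#'
#' Central differences on the (ideally arc-length-uniform) point sequence,
#' one-sided at the endpoints; unit norm.
#'
#' @param cl A [centerline].
#' @return `n x 3` matrix of unit tangents `(z, y, x)`.
#' @keywords internal
centerline_tangents <- function(cl) {
  P <- cl$points
  n <- nrow(P)
  Tn <- matrix(0, n, 3)
  Tn[1, ] <- P[2, ] - P[1, ]
  Tn[n, ] <- P[n, ] - P[n - 1, ]
  if (n > 2) Tn[2:(n - 1), ] <- P[3:n, ] - P[1:(n - 2), ]
  Tn / sqrt(rowSums(Tn^2))
}
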