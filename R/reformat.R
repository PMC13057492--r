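#' Oblique resampling plane
#'
#' A plane through `center` spanned by two orthonormal in-plane axes, used
#' for oblique multiplanar reconstruction.
#'
#' @param center Length-3 world mm `(z, y, x)`.
#' @param u_axis,v_axis Length-3 in-plane direction vectors; normalised here,
#'   must be orthogonal to `< 1e-9` after normalisation.
#' @param extent Length-2 plane extent in mm `(u, v)`; scalar is recycled.
#' @param pixel_size Pixel size in mm, positive.
#' @return An object of class `oblique_plane`.
#' @export
oblique_plane <- function(center, u_axis, v_axis, extent = c(20, 20), pixel_size = 0.31) {
  u <- u_axis / sqrt(sum(u_axis^2))
  v <- v_axis / sqrt(sum(v_axis^2))
  if (abs(sum(u * v)) > 1e-9) stop("plane axes must be orthonormal", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (length(extent) == 1L) extent <- rep(extent, 2)
  structure(
    list(center = as.numeric(center), u_axis = u, v_axis = v,
         extent = as.numeric(extent), pixel_size = pixel_size),
    class = "oblique_plane"
  )
}

new_cross_section <- function(image, pixel_size, center_world, normal,
                              u_axis, v_axis, arc_position = NA_real_) {
  structure(
    list(image = image, pixel_size = pixel_size, center_world = center_world,
         normal = normal, u_axis = u_axis, v_axis = v_axis,
         arc_position = arc_position),
    class = "cross_section"
  )
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf(
    "<cross_section> %d x %d px @ %.3g mm%s\n",
    nrow(x$image), ncol(x$image), x$pixel_size,
    if (is.na(x$arc_position)) "" else sprintf(", arc %.2f mm", x$arc_position)
  ))
  invisible(x)
}

#' Resample a volume onto an oblique plane
#'
#' Pixel `(i, j)` (row = v, column = u) holds the trilinear sample at
#' `center + (j - cj) * pixel_size * u + (i - ci) * pixel_size * v`;
#' out-of-volume pixels receive the fill value.
#'
#' @param vol A [voxel_volume].
#' @param plane An [oblique_plane].
#' @param fill HU fill value for out-of-volume pixels.
#' @return A `cross_section`: 2D HU image plus geometry metadata.
#' @export
resample_plane <- function(vol, plane, fill = -1024) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(plane, "oblique_plane"))
  nu <- max(2L, round(plane$extent[1] / plane$pixel_size) + 1L)
  nv <- max(2L, round(plane$extent[2] / plane$pixel_size) + 1L)
  cu <- (nu - 1) / 2
  cv <- (nv - 1) / 2
  us <- (seq_len(nu) - 1 - cu) * plane$pixel_size
  vs <- (seq_len(nv) - 1 - cv) * plane$pixel_size
  # all pixel centres as world points, row-major over (v, u)
  grid <- expand.grid(v = vs, u = us)
  pts <- matrix(plane$center, nrow(grid), 3, byrow = TRUE) +
    outer(grid$u, plane$u_axis) + outer(grid$v, plane$v_axis)
  vals <- sample_trilinear(vol, pts, fill = fill)
  img <- matrix(vals, nrow = nv, ncol = nu)
  normal <- c(
    plane$u_axis[2] * plane$v_axis[3] - plane$u_axis[3] * plane$v_axis[2],
    plane$u_axis[3] * plane$v_axis[1] - plane$u_axis[1] * plane$v_axis[3],
    plane$u_axis[1] * plane$v_axis[2] - plane$u_axis[2] * plane$v_axis[1]
  )
  new_cross_section(img, plane$pixel_size, plane$center, normal,
                    plane$u_axis, plane$v_axis)
}

#' Rotation-minimising frames along a path (double-reflection method)
#'
#' @param P `n x 3` matrix of points; `Tn` matching unit tangents.
#' @return List of `u` and `v` matrices (`n x 3`), orthonormal to the tangent,
#'   with minimal rotation between consecutive frames.
#' @keywords internal
rm_frames <- function(P, Tn) {
  n <- nrow(P)
  u <- matrix(0, n, 3)
  # initial normal: any vector orthogonal to T1
  t1 <- Tn[1, ]
  a <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  r0 <- a - sum(a * t1) * t1
  u[1, ] <- r0 / sqrt(sum(r0^2))
  for (i in seq_len(n - 1)) {
    v1 <- P[i + 1, ] - P[i, ]
    c1 <- sum(v1 * v1)
    rL <- u[i, ] - (2 / c1) * sum(v1 * u[i, ]) * v1
    tL <- Tn[i, ] - (2 / c1) * sum(v1 * Tn[i, ]) * v1
    v2 <- Tn[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    ui <- if (c2 < 1e-300) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthogonalise against the tangent to curb numerical drift
    ui <- ui - sum(ui * Tn[i + 1, ]) * Tn[i + 1, ]
    u[i + 1, ] <- ui / sqrt(sum(ui^2))
  }
  v <- cbind(
    Tn[, 2] * u[, 3] - Tn[, 3] * u[, 2],
    Tn[, 3] * u[, 1] - Tn[, 1] * u[, 3],
    Tn[, 1] * u[, 2] - Tn[, 2] * u[, 1]
  )
  list(u = u, v = v)
}

#' Curved planar reformation along a centerline
#'
#' Resamples the volume on planes perpendicular to the local tangent at
#' uniform arc-length steps. In-plane frames are rotation-minimising
#' (double-reflection), so there are no frame flips; `arc_position` is
#' strictly increasing across the stack.
#'
#' @param vol A [voxel_volume].
#' @param cl A [centerline]; it is arc-length-resampled at `step` internally
#'   (via [smooth_centerline()]) when its spacing differs.
#' @param width In-plane extent of each cross-section in mm (square).
#' @param pixel_size In-plane pixel size in mm; default the volume's minimum
#'   in-plane spacing.
#' @param step Arc-length step between sections in mm; default `pixel_size`.
#' @param fill HU fill value outside the volume.
#' @param check_bounds Error when the centerline (with `width/2` margin along
#'   the plane axes) exits the volume; set `FALSE` to fill instead.
#' @return List of `cross_section` objects ordered by `arc_position`.
#' @export
curved_planar_reformation <- function(vol, cl, width = 20, pixel_size = NULL,
                                      step = NULL, fill = -1024,
                                      check_bounds = TRUE) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(cl, "centerline"))
  if (is.null(pixel_size)) pixel_size <- min(vol$spacing[2:3])
  if (is.null(step)) step <- pixel_size
  # uniform resampling when needed
  if (nrow(cl$points) >= 4L) {
    incr <- diff(cl$arc_length)
    if (max(abs(incr - step)) > 1e-6) cl <- smooth_centerline(cl, step)
  }
  P <- cl$points
  if (check_bounds) {
    lo <- vol$origin
    hi <- vol$origin + (dim(vol$data) - 1) * vol$spacing
    margin <- width / 2
    inside <- P[, 1] >= lo[1] & P[, 1] <= hi[1] &
      P[, 2] >= lo[2] + margin & P[, 2] <= hi[2] - margin &
      P[, 3] >= lo[3] + margin & P[, 3] <= hi[3] - margin
    if (!all(inside)) {
      stop("centerline exits the volume bounds (margin width/2)", call. = FALSE)
    }
  }
  Tn <- centerline_tangents(cl)
  fr <- rm_frames(P, Tn)
  lapply(seq_len(nrow(P)), function(i) {
    pl <- oblique_plane(P[i, ], fr$u[i, ], fr$v[i, ],
      extent = c(width, width), pixel_size = pixel_size
    )
    cs <- resample_plane(vol, pl, fill = fill)
    cs$arc_position <- cl$arc_length[i]
    cs
  })
}
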