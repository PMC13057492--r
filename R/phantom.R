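#' Phantom specifications
#'
#' Validated parameter records for the three digital-phantom families. The
#' default HU palette (lumen −1000, wall +40, parenchyma −850, vessel +60,
#' cuff +50) is consistent with the >30 HU soft-tissue bound used by the
#' cuffing rule; the default noise SD of 12.4 HU matches the measured image
#' noise of the source acquisition protocol.
#'
#' @param lumen_diameter,wall_thickness Tube geometry in mm, both positive.
#' @param axis Tube axis, length-3 `(z, y, x)`; normalised.
#' @param length Tube length in mm.
#' @param lumen_hu,wall_hu,parenchyma_hu HU palette.
#' @param cuff Optional list `(thickness, coverage_fraction, hu, n_slices)`
#'   describing a partial peribronchial cuff ring.
#' @param noise_sd Gaussian HU noise SD, >= 0.
#' @param seed Integer seed for the noise field.
#' @return A validated spec list.
#' @export
airway_phantom_spec <- function(lumen_diameter = 4.0, wall_thickness = 1.04,
                                axis = c(1, 0, 0), length = 12,
                                lumen_hu = -1000, wall_hu = 40,
                                parenchyma_hu = -850, cuff = NULL,
                                noise_sd = 12.4, seed = 1L) {
  stopifnot(lumen_diameter > 0, wall_thickness > 0, noise_sd >= 0, length > 0)
  axis <- axis / sqrt(sum(axis^2))
  if (!is.null(cuff)) {
    cuff <- utils::modifyList(
      list(thickness = 3, coverage_fraction = 1, hu = 50, n_slices = 5), cuff
    )
    stopifnot(cuff$coverage_fraction >= 0, cuff$coverage_fraction <= 1,
              cuff$thickness > 0, cuff$n_slices >= 1)
  }
  list(
    lumen_diameter = lumen_diameter, wall_thickness = wall_thickness,
    axis = axis, length = length, lumen_hu = lumen_hu, wall_hu = wall_hu,
    parenchyma_hu = parenchyma_hu, cuff = cuff, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
}

#' @rdname airway_phantom_spec
#' @param parent_direction,daughter_angle Bifurcation geometry: parent axis
#'   `(z, y, x)` and the 3D angle between the daughter branches in degrees,
#'   strictly inside (0, 180).
#' @param branch_radius,branch_hu Daughter/parent tube radius (mm) and HU.
#' @export
bifurcation_phantom_spec <- function(parent_direction = c(1, 0, 0),
                                     daughter_angle = 110,
                                     branch_radius = 2.5, branch_hu = 60,
                                     parenchyma_hu = -850,
                                     noise_sd = 12.4, seed = 1L) {
  if (daughter_angle <= 0 || daughter_angle >= 180) {
    stop("daughter_angle must be in (0, 180) degrees", call. = FALSE)
  }
  parent_direction <- parent_direction / sqrt(sum(parent_direction^2))
  list(
    parent_direction = parent_direction, daughter_angle = daughter_angle,
    branch_radius = branch_radius, branch_hu = branch_hu,
    parenchyma_hu = parenchyma_hu, noise_sd = noise_sd, seed = as.integer(seed)
  )
}

#' @rdname airway_phantom_spec
#' @param pattern One of `"filled"`, `"sierpinski_carpet"`, `"fbm"`.
#' @param target_fd Target box dimension for `"fbm"`, in (1, 2].
#' @param depth Recursion depth for `"sierpinski_carpet"`.
#' @export
fractal_texture_spec <- function(pattern = c("filled", "sierpinski_carpet", "fbm"),
                                 target_fd = 1.41, depth = 4L, seed = 1L) {
  pattern <- match.arg(pattern)
  if (pattern == "fbm" && (target_fd <= 1 || target_fd > 2)) {
    stop("target_fd must lie in (1, 2]", call. = FALSE)
  }
  list(pattern = pattern, target_fd = target_fd, depth = as.integer(depth),
       seed = as.integer(seed))
}

# orthonormal frame completing a unit axis vector
.axis_frame <- function(axis) {
  a <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    axis[2] * e1[3] - axis[3] * e1[2],
    axis[3] * e1[1] - axis[1] * e1[3],
    axis[1] * e1[2] - axis[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

# world coordinates of all voxel subsample positions for one offset triple
.grid_coords <- function(dims, spacing, origin, off) {
  z <- origin[1] + ((seq_len(dims[1]) - 1) + off[1]) * spacing[1]
  y <- origin[2] + ((seq_len(dims[2]) - 1) + off[2]) * spacing[2]
  x <- origin[3] + ((seq_len(dims[3]) - 1) + off[3]) * spacing[3]
  list(z = z, y = y, x = x)
}

#' Straight airway phantom with ground truth
#'
#' Voxelises a cylindrical air lumen with an annular soft-tissue wall inside
#' homogeneous parenchyma, with an optional partial cuff ring, then adds
#' i.i.d. Gaussian HU noise. Voxelisation averages `supersample^3` subsamples
#' per voxel (partial-volume edges, as in reconstructed CT); voxels strictly
#' inside a region carry its exact HU.
#'
#' @param spec An [airway_phantom_spec()].
#' @param spacing Voxel spacing `(z, y, x)` in mm; in-plane spacing must not
#'   exceed `lumen_diameter / 4` (sampling adequacy).
#' @param margin_mm Parenchyma margin around the outer wall (and cuff).
#' @param supersample Subsamples per axis for partial-volume voxelisation
#'   (1 = sharp).
#' @return List with elements `volume` (a [voxel_volume]) and `ground_truth`
#'   (spec echo plus the true WT/D ratio and tube center).
#' @export
make_airway_phantom <- function(spec = airway_phantom_spec(),
                                spacing = c(0.62, 0.62, 0.62),
                                margin_mm = 4, supersample = 2L) {
  if (max(spacing[2:3]) > spec$lumen_diameter / 4) {
    stop("in-plane spacing too coarse: must be <= lumen_diameter / 4", call. = FALSE)
  }
  r_lum <- spec$lumen_diameter / 2
  r_out <- r_lum + spec$wall_thickness
  r_max <- r_out + (if (is.null(spec$cuff)) 0 else spec$cuff$thickness) + margin_mm
  # volume sized for the tube; axis-aligned bounding box of the tilted tube
  half <- abs(spec$axis) * (spec$length / 2) + r_max
  dims <- pmax(4L, ceiling(2 * half / spacing) + 1L)
  center <- (dims - 1) / 2 * spacing
  fr <- .axis_frame(spec$axis)
  vals <- array(0, dims)
  offs <- (seq_len(supersample) - 0.5) / supersample - 0.5
  cuff <- spec$cuff
  if (!is.null(cuff)) {
    cuff_half_ax <- cuff$n_slices * spacing[1] / 2
    cuff_ang <- cuff$coverage_fraction * pi
  }
  for (oz in offs) for (oy in offs) for (ox in offs) {
    g <- .grid_coords(dims, spacing, c(0, 0, 0), c(oz, oy, ox))
    dz <- g$z - center[1]; dy <- g$y - center[2]; dx <- g$x - center[3]
    # axial and radial coordinates relative to the tube axis through center
    tax <- outer(outer(dz * spec$axis[1], dy * spec$axis[2], `+`), dx * spec$axis[3], `+`)
    p1 <- outer(outer(dz * fr$e1[1], dy * fr$e1[2], `+`), dx * fr$e1[3], `+`)
    p2 <- outer(outer(dz * fr$e2[1], dy * fr$e2[2], `+`), dx * fr$e2[3], `+`)
    rho <- sqrt(p1^2 + p2^2)
    v <- array(spec$parenchyma_hu, dims)
    inside_len <- abs(tax) <= spec$length / 2
    v[inside_len & rho < r_out] <- spec$wall_hu
    v[inside_len & rho < r_lum] <- spec$lumen_hu
    if (!is.null(cuff)) {
      ang <- atan2(p2, p1)
      sel <- inside_len & rho >= r_out & rho < r_out + cuff$thickness &
        abs(ang) <= cuff_ang & abs(tax) <= cuff_half_ax
      v[sel] <- cuff$hu
    }
    vals <- vals + v
  }
  vals <- vals / supersample^3
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vals <- vals + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)
  }
  gt <- list(
    kind = "airway", lumen_diameter_mm = spec$lumen_diameter,
    wall_thickness_mm = spec$wall_thickness,
    wt_d_ratio = spec$wall_thickness / spec$lumen_diameter,
    axis = spec$axis, center_mm = center, length_mm = spec$length,
    lumen_hu = spec$lumen_hu, wall_hu = spec$wall_hu,
    parenchyma_hu = spec$parenchyma_hu, cuff = spec$cuff,
    noise_sd = spec$noise_sd, seed = spec$seed,
    within_stage_independence_assumed = TRUE
  )
  list(volume = voxel_volume(vals, spacing), ground_truth = gt)
}

#' Bifurcating vessel phantom with ground truth
#'
#' Two straight daughter tubes meet the parent tube at a vertex; the analytic
#' 3D angle between the daughter axes equals `spec$daughter_angle`. Emitted
#' centerlines lie exactly on the tube axes.
#'
#' @param spec A [bifurcation_phantom_spec()].
#' @param spacing Voxel spacing `(z, y, x)` in mm.
#' @param branch_length Length of each branch from the vertex in mm.
#' @param supersample Subsamples per axis for voxelisation.
#' @return List with `volume`, `centerlines` (list: `parent`, `daughters`),
#'   and `ground_truth` (including the analytic `daughter_angle_deg`).
#' @export
make_bifurcation_phantom <- function(spec = bifurcation_phantom_spec(),
                                     spacing = c(0.62, 0.62, 0.62),
                                     branch_length = 15, supersample = 1L) {
  p <- spec$parent_direction
  fr <- .axis_frame(p)
  th <- spec$daughter_angle * pi / 180
  d1 <- cos(th / 2) * p + sin(th / 2) * fr$e1
  d2 <- cos(th / 2) * p - sin(th / 2) * fr$e1
  L <- branch_length
  ext <- L + spec$branch_radius + 3
  dims <- pmax(8L, ceiling(2 * ext / spacing) + 1L)
  vertex <- (dims - 1) / 2 * spacing
  segs <- list(
    list(a = vertex - p * L, b = vertex),
    list(a = vertex, b = vertex + d1 * L),
    list(a = vertex, b = vertex + d2 * L)
  )
  vals <- array(0, dims)
  offs <- (seq_len(supersample) - 0.5) / supersample - 0.5
  for (oz in offs) for (oy in offs) for (ox in offs) {
    g <- .grid_coords(dims, spacing, c(0, 0, 0), c(oz, oy, ox))
    v <- array(spec$parenchyma_hu, dims)
    for (sg in segs) {
      u <- sg$b - sg$a
      len <- sqrt(sum(u^2))
      u <- u / len
      dz <- g$z - sg$a[1]; dy <- g$y - sg$a[2]; dx <- g$x - sg$a[3]
      t_ax <- outer(outer(dz * u[1], dy * u[2], `+`), dx * u[3], `+`)
      t_ax <- pmin(pmax(t_ax, 0), len)
      # squared distance to the segment
      qz <- outer(outer(dz, dy * 0, `+`), dx * 0, `+`) - t_ax * u[1]
      qy <- outer(outer(dz * 0, dy, `+`), dx * 0, `+`) - t_ax * u[2]
      qx <- outer(outer(dz * 0, dy * 0, `+`), dx, `+`) - t_ax * u[3]
      v[qz^2 + qy^2 + qx^2 < spec$branch_radius^2] <- spec$branch_hu
    }
    vals <- vals + v
  }
  vals <- vals / supersample^3
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vals <- vals + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)
  }
  mk_cl <- function(a, b) {
    s <- seq(0, 1, length.out = max(8L, ceiling(L / 0.5) + 1L))
    centerline(cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]),
                     a[3] + s * (b[3] - a[3])))
  }
  gt <- list(
    kind = "bifurcation", daughter_angle_deg = spec$daughter_angle,
    parent_direction = p, daughter_directions = list(d1, d2),
    vertex_mm = vertex, branch_radius_mm = spec$branch_radius,
    noise_sd = spec$noise_sd, seed = spec$seed
  )
  list(
    volume = voxel_volume(vals, spacing),
    centerlines = list(
      parent = mk_cl(vertex - p * L, vertex),
      daughters = list(mk_cl(vertex, vertex + d1 * L),
                       mk_cl(vertex, vertex + d2 * L))
    ),
    ground_truth = gt
  )
}

#' Tube phantom bent along an arbitrary centerline
#'
#' Like [make_airway_phantom()] but the lumen/wall tube follows a given
#' smooth path; used to validate curved planar reformation by recovery.
#'
#' @param cl A [centerline] (world mm); the volume is sized to contain it.
#' @param lumen_diameter,wall_thickness Tube geometry in mm.
#' @param spacing Voxel spacing `(z, y, x)` in mm.
#' @param margin_mm Parenchyma margin beyond the outer wall.
#' @param lumen_hu,wall_hu,parenchyma_hu HU palette.
#' @param noise_sd,seed Gaussian HU noise.
#' @param supersample Subsamples per axis.
#' @return List with `volume` (origin chosen so the input centerline world
#'   coordinates are valid in it) and `ground_truth`.
#' @export
make_tube_phantom <- function(cl, lumen_diameter = 4.0, wall_thickness = 1.04,
                              spacing = c(0.62, 0.62, 0.62), margin_mm = 5,
                              lumen_hu = -1000, wall_hu = 40,
                              parenchyma_hu = -850, noise_sd = 0, seed = 1L,
                              supersample = 2L) {
  stopifnot(inherits(cl, "centerline"))
  r_out <- lumen_diameter / 2 + wall_thickness
  # dense path for distance queries
  fine <- if (nrow(cl$points) >= 4) smooth_centerline(cl, 0.25)$points else cl$points
  lo <- apply(fine, 2, min) - r_out - margin_mm
  hi <- apply(fine, 2, max) + r_out + margin_mm
  dims <- pmax(4L, ceiling((hi - lo) / spacing) + 1L)
  vals <- array(0, dims)
  offs <- (seq_len(supersample) - 0.5) / supersample - 0.5
  r_lum <- lumen_diameter / 2
  nvox <- prod(dims)
  for (oz in offs) for (oy in offs) for (ox in offs) {
    g <- .grid_coords(dims, spacing, lo, c(oz, oy, ox))
    pts <- cbind(
      rep(g$z, times = dims[2] * dims[3]),
      rep(rep(g$y, each = dims[1]), times = dims[3]),
      rep(g$x, each = dims[1] * dims[2])
    )
    dmin <- rep(Inf, nvox)
    chunk <- 200000L
    for (s0 in seq(1, nvox, by = chunk)) {
      s1 <- min(s0 + chunk - 1L, nvox)
      block <- pts[s0:s1, , drop = FALSE]
      dd <- matrix(Inf, nrow(block), 1)
      for (j in seq_len(nrow(fine))) {
        dj <- (block[, 1] - fine[j, 1])^2 + (block[, 2] - fine[j, 2])^2 +
          (block[, 3] - fine[j, 3])^2
        dd <- pmin(dd, dj)
      }
      dmin[s0:s1] <- sqrt(dd)
    }
    v <- rep(parenchyma_hu, nvox)
    v[dmin < r_out] <- wall_hu
    v[dmin < r_lum] <- lumen_hu
    vals <- vals + array(v, dims)
  }
  vals <- vals / supersample^3
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + array(stats::rnorm(nvox, 0, noise_sd), dims)
  }
  gt <- list(
    kind = "curved_tube", lumen_diameter_mm = lumen_diameter,
    wall_thickness_mm = wall_thickness,
    wt_d_ratio = wall_thickness / lumen_diameter, noise_sd = noise_sd
  )
  list(volume = voxel_volume(vals, spacing, origin = lo), ground_truth = gt)
}

# frozen calibration: measured box dimension of the median-level contour of a
# 256 px spectral-synthesis fBm field (package estimator, 12 seeds per point)
# against the Hurst exponent used to generate it
.fbm_fd_calibration <- data.frame(
  hurst = seq(0.10, 0.80, by = 0.05),
  fd = c(1.7919, 1.7570, 1.7200, 1.6792, 1.6389, 1.5991, 1.5567, 1.5181,
         1.4771, 1.4397, 1.4032, 1.3690, 1.3354, 1.3023, 1.2720)
)

# spectral synthesis of a 2D fractional Brownian field with Hurst H
.fbm_field <- function(n, hurst, seed) {
  set.seed(seed)
  fx <- c(0:(n %/% 2), -((n %/% 2 - 1):1)) / n
  f <- sqrt(outer(fx^2, fx^2, `+`))
  f[1, 1] <- Inf
  amp <- f^(-(hurst + 1))
  ph <- matrix(stats::rnorm(n * n), n, n) + 1i * matrix(stats::rnorm(n * n), n, n)
  Re(stats::fft(amp * ph, inverse = TRUE))
}

# 4-connected boundary of a binary mask
.mask_boundary <- function(b) {
  n <- nrow(b); m <- ncol(b)
  b & !(rbind(b[-1, , drop = FALSE], FALSE) &
    rbind(FALSE, b[-n, , drop = FALSE]) &
    cbind(b[, -1, drop = FALSE], FALSE) &
    cbind(FALSE, b[, -m, drop = FALSE]))
}

#' Planar texture with known box-counting dimension
#'
#' Generates 2D binary textures serving as ground truth for the box-counting
#' estimator: a filled square (dimension 2), the standard Sierpinski carpet
#' (dimension log 8 / log 3), or the median-level contour of a seeded
#' fractional Brownian field. For the fBm pattern the Hurst exponent is taken
#' from a frozen calibration table so that the expected measured box
#' dimension at the default 256 px size equals `target_fd`.
#'
#' @param spec A [fractal_texture_spec()].
#' @param size Image side in pixels; a power of 3 equal to `3^depth` for the
#'   carpet, at least 27 otherwise.
#' @return List with `image` (binary matrix), `fd_true`, and the spec echo.
#' @export
make_fractal_texture <- function(spec = fractal_texture_spec(), size = 256L) {
  if (size < 27L) stop("size must be >= 27 pixels", call. = FALSE)
  if (spec$pattern == "filled") {
    return(list(image = matrix(1L, size, size), fd_true = 2.0, spec = spec))
  }
  if (spec$pattern == "sierpinski_carpet") {
    if (size != 3L^spec$depth) {
      stop("carpet size must equal 3^depth", call. = FALSE)
    }
    m <- matrix(1L, 1, 1)
    for (i in seq_len(spec$depth)) {
      n <- nrow(m)
      M <- matrix(0L, 3 * n, 3 * n)
      for (a in 0:2) for (b in 0:2) {
        if (!(a == 1 && b == 1)) M[a * n + 1:n, b * n + 1:n] <- m
      }
      m <- M
    }
    return(list(image = m, fd_true = log(8) / log(3), spec = spec))
  }
  # fbm: invert the frozen calibration (monotone decreasing fd(hurst))
  cal <- .fbm_fd_calibration
  rng <- range(cal$fd)
  tfd <- min(max(spec$target_fd, rng[1]), rng[2])
  if (tfd != spec$target_fd) {
    warning(sprintf(
      "target_fd %.3f outside the calibrated range [%.2f, %.2f]; clamped",
      spec$target_fd, rng[1], rng[2]
    ), call. = FALSE)
  }
  ord <- order(cal$fd)
  hurst <- stats::approx(cal$fd[ord], cal$hurst[ord], xout = tfd)$y
  z <- .fbm_field(size, hurst, spec$seed)
  img <- .mask_boundary(z > stats::median(z))
  list(image = img * 1L, fd_true = spec$target_fd, hurst = hurst, spec = spec)
}
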