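## Bronchovascular-bundle morphometry on cross-sections:
## FWHM wall measurement, 3D bifurcation angles / AVI, box-counting fractal
## dimension of the peribronchial texture, and the cuffing-sign rule.

# bilinear sample of a section image at local-mm points (u = column axis,
# v = row axis, origin at the centre of pixel [1, 1])
.section_bilinear <- function(image, pixel_size, pts) {
  i <- pts[, 2] / pixel_size
  j <- pts[, 1] / pixel_size
  n <- nrow(image); m <- ncol(image)
  i0 <- pmin(pmax(floor(i), 0), n - 2)
  j0 <- pmin(pmax(floor(j), 0), m - 2)
  fi <- pmin(pmax(i - i0, 0), 1)
  fj <- pmin(pmax(j - j0, 0), 1)
  g <- function(di, dj) image[cbind(i0 + di + 1, j0 + dj + 1)]
  (1 - fi) * ((1 - fj) * g(0, 0) + fj * g(0, 1)) +
    fi * ((1 - fj) * g(1, 0) + fj * g(1, 1))
}

# connected component of `mask` containing pixel `seed` (row, col), grown by
# iterative 4-neighbour dilation
.flood_mask <- function(mask, seed) {
  comp <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!mask[seed[1], seed[2]]) return(comp)
  comp[seed[1], seed[2]] <- TRUE
  n <- nrow(mask); m <- ncol(mask)
  repeat {
    grown <- comp |
      rbind(comp[-1, , drop = FALSE], FALSE) |
      rbind(FALSE, comp[-n, , drop = FALSE]) |
      cbind(comp[, -1, drop = FALSE], FALSE) |
      cbind(FALSE, comp[, -m, drop = FALSE])
    grown <- grown & mask
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

# radial HU profiles: matrix [length(rr) x length(angles)]
.ray_profiles <- function(image, pixel_size, center, angles, rr) {
  vapply(angles, function(a) {
    .section_bilinear(image, pixel_size,
      cbind(center[1] + rr * cos(a), center[2] + rr * sin(a)))
  }, numeric(length(rr)))
}

#' Airway wall measurement by FWHM ray casting
#'
#' Finds the air lumen connected to `lumen_seed`, casts `n_rays` radial rays
#' from its centroid, and localises on each ray the inner (lumen-wall) and
#' outer (wall-parenchyma) edges at the half-maximum levels between the
#' plateau HU values. Plateau levels are estimated globally (lumen: median
#' over the lumen region; wall: maximum over all ray peaks; parenchyma:
#' median of the profile tails), which avoids the thin-wall bias of per-ray
#' attenuated peaks. Sub-sample edge positions by linear interpolation.
#' `D` is twice the mean inner-edge radius, `WT` the mean outer-inner
#' difference over valid rays.
#'
#' @param section A `cross_section` (from [resample_plane()] or
#'   [curved_planar_reformation()]).
#' @param lumen_seed Local section coordinates `(u, v)` in mm of a point
#'   inside the lumen; default the section centre. Must hit an air-density
#'   (< `air_threshold` HU) pixel.
#' @param n_rays Number of radial rays.
#' @param step Radial sampling step in mm.
#' @param air_threshold HU bound defining air-density lumen.
#' @param min_contrast Minimum lumen-to-wall HU contrast for a ray to count.
#' @param max_invalid Maximum tolerated fraction of invalid rays before the
#'   measurement fails.
#' @return An `airway_measurement`: inner diameter `inner_diameter_d` (mm),
#'   `wall_thickness_wt` (mm), `wt_d_ratio`, `arc_position`, per-ray radii
#'   and the plateau levels used.
#' @export
measure_wall <- function(section, lumen_seed = NULL, n_rays = 72L, step = 0.05,
                         air_threshold = -500, min_contrast = 200,
                         max_invalid = 0.25) {
  stopifnot(inherits(section, "cross_section"))
  img <- section$image
  px <- section$pixel_size
  if (is.null(lumen_seed)) {
    lumen_seed <- c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2) * px
  }
  seed_px <- c(round(lumen_seed[2] / px) + 1, round(lumen_seed[1] / px) + 1)
  seed_px <- pmin(pmax(seed_px, 1), dim(img))
  if (img[seed_px[1], seed_px[2]] >= air_threshold) {
    stop("lumen_seed does not hit an air-density (< ", air_threshold,
      " HU) region", call. = FALSE)
  }
  lum_mask <- .flood_mask(img < air_threshold, seed_px)
  idx <- which(lum_mask, arr.ind = TRUE)
  centroid <- c(mean((idx[, 2] - 1) * px), mean((idx[, 1] - 1) * px)) # (u, v)
  lum_lvl <- stats::median(img[lum_mask])
  rmax <- min(
    centroid[1], (ncol(img) - 1) * px - centroid[1],
    centroid[2], (nrow(img) - 1) * px - centroid[2]
  )
  angles <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  rr <- seq(0, rmax, by = step)
  V <- .ray_profiles(img, px, centroid, angles, rr)
  pks <- apply(V, 2, max)
  pk_is <- apply(V, 2, which.max)
  wall_lvl <- max(pks)
  tail_sel <- rr > rr[max(pk_is)] + 2
  tail_v <- if (any(tail_sel)) V[tail_sel, ] else V[rr > stats::quantile(rr, 0.8), ]
  tail_v <- tail_v[tail_v > -1023] # drop out-of-volume fill samples
  par_lvl <- if (length(tail_v)) stats::median(tail_v) else lum_lvl
  half_in <- (lum_lvl + wall_lvl) / 2
  half_out <- (wall_lvl + par_lvl) / 2
  inner <- outer_r <- rep(NA_real_, n_rays)
  for (k in seq_len(n_rays)) {
    v <- V[, k]
    pk_i <- pk_is[k]
    if (pks[k] < half_in || pks[k] - lum_lvl < min_contrast) next
    ii <- which(v[seq_len(pk_i)] >= half_in)[1]
    if (is.na(ii) || ii < 2) next
    inner[k] <- rr[ii - 1] + (half_in - v[ii - 1]) / (v[ii] - v[ii - 1]) * step
    jj <- which(v <= half_out & seq_along(v) > pk_i)[1]
    if (is.na(jj)) next
    outer_r[k] <- rr[jj - 1] + (half_out - v[jj - 1]) / (v[jj] - v[jj - 1]) * step
  }
  ok <- !is.na(inner) & !is.na(outer_r) & outer_r > inner
  if (mean(!ok) > max_invalid) {
    stop(sprintf(
      paste0("wall measurement failed: no closed wall on %d/%d rays ",
        "(levels: lumen %.0f, wall %.0f, parenchyma %.0f HU)"),
      sum(!ok), n_rays, lum_lvl, wall_lvl, par_lvl
    ), call. = FALSE)
  }
  d <- 2 * mean(inner[ok])
  wt <- mean(outer_r[ok] - inner[ok])
  structure(
    list(
      inner_diameter_d = d, wall_thickness_wt = wt, wt_d_ratio = wt / d,
      arc_position = section$arc_position,
      n_valid_rays = sum(ok), n_rays = n_rays,
      centroid_uv = centroid, angles = angles,
      inner_radii = inner, outer_radii = outer_r,
      levels = c(lumen = lum_lvl, wall = wall_lvl, parenchyma = par_lvl)
    ),
    class = "airway_measurement"
  )
}

#' @export
print.airway_measurement <- function(x, ...) {
  cat(sprintf(
    "<airway_measurement> D %.2f mm, WT %.2f mm, WT/D %.3f (%d/%d rays)\n",
    x$inner_diameter_d, x$wall_thickness_wt, x$wt_d_ratio,
    x$n_valid_rays, x$n_rays
  ))
  invisible(x)
}

#' Narrowest cross-section of a reformation stack
#'
#' Measures every section and returns the one minimising the inner lumen
#' diameter, where the ratio is read per convention; ties break to the
#' smallest arc position.
#'
#' @param stack List of `cross_section`s (>= 3).
#' @param ... Passed to [measure_wall()].
#' @return List with `section`, `measurement`, `index`, and `profile`, a
#'   tibble of per-section arc position and diameter (NA where a section was
#'   unmeasurable).
#' @export
find_narrowest_section <- function(stack, ...) {
  if (length(stack) < 3L) {
    stop("need at least 3 measurable sections", call. = FALSE)
  }
  meas <- lapply(stack, function(s) tryCatch(measure_wall(s, ...),
    error = function(e) NULL))
  d <- vapply(meas, function(m) if (is.null(m)) NA_real_ else m$inner_diameter_d,
    numeric(1))
  arc <- vapply(stack, function(s) s$arc_position, numeric(1))
  if (all(is.na(d))) stop("all sections unmeasurable", call. = FALSE)
  cand <- which(d <= min(d, na.rm = TRUE) + 1e-12)
  best <- cand[which.min(arc[cand])]
  list(
    section = stack[[best]], measurement = meas[[best]], index = best,
    profile = tibble::tibble(arc_position = arc, inner_diameter_d = d)
  )
}

#' Principal branch direction near a vertex
#'
#' Dominant eigenvector of the scatter of centerline points within `length`
#' mm of the vertex, oriented away from the vertex; unit norm.
#'
#' @param cl A [centerline].
#' @param from_vertex Length-3 world mm `(z, y, x)`.
#' @param length Window radius in mm.
#' @return Length-3 unit vector `(z, y, x)`.
#' @export
branch_direction <- function(cl, from_vertex, length = 10) {
  stopifnot(inherits(cl, "centerline"))
  P <- cl$points
  d <- sqrt(rowSums(sweep(P, 2, from_vertex)^2))
  P <- P[d <= length, , drop = FALSE]
  if (nrow(P) < 3L) stop("fewer than 3 centerline points within the window",
    call. = FALSE)
  C <- stats::cov(P)
  if (max(abs(C)) < 1e-12) stop("degenerate point scatter", call. = FALSE)
  ev <- eigen(C, symmetric = TRUE)
  dir <- ev$vectors[, 1]
  away <- colMeans(P) - from_vertex
  if (sum(dir * away) < 0) dir <- -dir
  dir / sqrt(sum(dir^2))
}

#' 3D angle between two branch directions
#'
#' @param d1,d2 Length-3 non-zero vectors.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
bifurcation_angle <- function(d1, d2) {
  n1 <- sqrt(sum(d1^2)); n2 <- sqrt(sum(d2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length direction vector", call. = FALSE)
  acos(pmin(pmax(sum(d1 * d2) / (n1 * n2), -1), 1)) * 180 / pi
}

#' Angle variation index
#'
#' Absolute deviation of a measured bifurcation angle from the healthy
#' population reference (110 degrees; the population spread of +/- 15
#' degrees is not part of the statistic).
#'
#' @param angle_deg Measured 3D angle(s) in degrees, each in `[0, 180]`.
#' @param reference_deg Reference angle, default 110.
#' @return `|angle_deg - reference_deg|`, vectorised.
#' @export
compute_avi <- function(angle_deg, reference_deg = 110) {
  if (any(angle_deg < 0 | angle_deg > 180)) {
    stop("angle_deg must lie in [0, 180]", call. = FALSE)
  }
  abs(angle_deg - reference_deg)
}

#' Peribronchial annular ROI
#'
#' Annular mask from the measured outer wall edge to `band_mm` beyond it,
#' centred on the lumen centroid.
#'
#' @param section A `cross_section`.
#' @param wall An `airway_measurement` for this section.
#' @param band_mm Band width in mm (default 2).
#' @return Logical matrix mask over the section image.
#' @export
peribronchial_roi <- function(section, wall, band_mm = 2) {
  stopifnot(inherits(section, "cross_section"),
    inherits(wall, "airway_measurement"))
  px <- section$pixel_size
  img <- section$image
  r_out <- wall$inner_diameter_d / 2 + wall$wall_thickness_wt
  ctr <- wall$centroid_uv
  edge_dist <- min(
    ctr[1], (ncol(img) - 1) * px - ctr[1],
    ctr[2], (nrow(img) - 1) * px - ctr[2]
  )
  if (r_out + band_mm > edge_dist) {
    stop("peribronchial annulus exits the image bounds", call. = FALSE)
  }
  u <- ((seq_len(ncol(img))) - 1) * px - ctr[1]
  v <- ((seq_len(nrow(img))) - 1) * px - ctr[2]
  r <- sqrt(outer(v^2, u^2, `+`))
  r >= r_out & r < r_out + band_mm
}

#' Box-counting fractal dimension of a planar pattern
#'
#' Binarises scalar input at `threshold` HU (binary input is used as is) and
#' counts occupied boxes at dyadic box sizes, each scale averaged over four
#' grid offsets. Boxes clipped by the image edge are weighted by the
#' fraction of their area inside the image, and the single-pixel scale is
#' dropped when five or more dyadic scales are available (it is dominated by
#' pixelisation). FD is the negative least-squares slope of log count
#' against log box size.
#'
#' @param x 2D numeric or logical matrix (>= 27 x 27 usable pixels).
#' @param pixel_size Pixel size in mm (scales `box_sizes` only).
#' @param threshold HU threshold for scalar input (default 30, the
#'   soft-tissue bound).
#' @return A `fractal_result`: `fd`, `box_sizes` (mm), `box_counts`,
#'   `fit_r2`.
#' @export
box_counting_fd <- function(x, pixel_size = 1, threshold = 30) {
  if (is.logical(x)) mask <- x else {
    mask <- if (all(x %in% c(0, 1))) x > 0 else x > threshold
  }
  n <- nrow(mask); m <- ncol(mask)
  if (min(n, m) < 27L) stop("ROI must be at least 27 x 27 pixels", call. = FALSE)
  sizes <- 2^(0:floor(log2(min(n, m) / 3)))
  if (length(sizes) >= 5L) sizes <- sizes[-1]
  if (length(sizes) < 4L) stop("fewer than 4 dyadic scales available", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty foreground: fractal dimension undefined",
    call. = FALSE)
  counts <- vapply(sizes, function(s) {
    offs <- if (s > 1) {
      h <- s %/% 2
      rbind(c(0, 0), c(h, 0), c(0, h), c(h, h))
    } else rbind(c(0, 0))
    mean(apply(offs, 1, function(o) {
      bi <- (idx[, 1] - 1 + o[1]) %/% s
      bj <- (idx[, 2] - 1 + o[2]) %/% s
      ub <- unique(cbind(bi, bj))
      ri <- pmin((ub[, 1] + 1) * s - o[1], n) - pmax(ub[, 1] * s - o[1], 0)
      rj <- pmin((ub[, 2] + 1) * s - o[2], m) - pmax(ub[, 2] * s - o[2], 0)
      sum(pmin(ri / s, 1) * pmin(rj / s, 1))
    }))
  }, numeric(1))
  lx <- log(sizes)
  ly <- log(counts)
  fit <- stats::lm(ly ~ lx)
  tss <- sum((ly - mean(ly))^2)
  rss <- sum(stats::residuals(fit)^2)
  r2 <- if (tss < 1e-20) 1 else 1 - rss / tss
  structure(
    list(
      fd = -unname(stats::coef(fit)[2]),
      box_sizes = sizes * pixel_size, box_counts = counts, fit_r2 = r2
    ),
    class = "fractal_result"
  )
}

#' @export
print.fractal_result <- function(x, ...) {
  cat(sprintf("<fractal_result> FD %.4f (R^2 %.3f, %d scales)\n",
    x$fd, x$fit_r2, length(x$box_sizes)))
  invisible(x)
}

#' Peribronchial cuffing-sign detection
#'
#' Implements the rule: a soft-tissue density shadow (> `hu_threshold` HU)
#' surrounding more than `min_coverage` of the bronchial circumference, at
#' least `min_thickness_mm` thick, continuous across more than `min_slices`
#' consecutive sections. Because an attached cuff is radiologically
#' continuous with the bronchial wall, the supra-threshold run on each of
#' 360 one-degree rays is measured from the inner (lumen) wall edge and must
#' exceed a reference wall thickness - by default the minimum wall thickness
#' measured across the stack, i.e. the uncuffed wall - by at least
#' `min_thickness_mm`. All three printed inequalities are read strictly.
#'
#' @param stack List of `cross_section`s, at least `min_slices + 1`.
#' @param walls Optional list of `airway_measurement`s per section; measured
#'   internally when `NULL` (unmeasurable sections count as non-qualifying
#'   and are logged in the result).
#' @param hu_threshold Soft-tissue HU bound (strictly greater-than).
#' @param min_coverage Circumference fraction bound (strictly greater-than).
#' @param min_thickness_mm Cuff thickness bound (at least).
#' @param min_slices Consecutive-section bound (strictly more than).
#' @param reference_wt Reference (uncuffed) wall thickness in mm; default
#'   the minimum measured wall thickness across the stack.
#' @param step Radial sampling step in mm.
#' @return A `cuffing_result`: `positive`, `coverage_fraction` (max over
#'   sections), `cuff_thickness_mm` (median qualifying excess in the best
#'   run), `consecutive_slices`, `per_section` tibble, `reference_wt_mm`.
#' @export
detect_cuffing <- function(stack, walls = NULL, hu_threshold = 30,
                           min_coverage = 0.5, min_thickness_mm = 2,
                           min_slices = 3L, reference_wt = NULL, step = 0.05) {
  if (length(stack) < min_slices + 1L) {
    stop("need at least min_slices + 1 sections", call. = FALSE)
  }
  if (is.null(walls)) {
    walls <- lapply(stack, function(s) tryCatch(measure_wall(s),
      error = function(e) NULL))
  }
  wt_all <- vapply(walls, function(w) {
    if (is.null(w)) NA_real_ else w$wall_thickness_wt
  }, numeric(1))
  if (all(is.na(wt_all))) stop("no measurable wall in the stack", call. = FALSE)
  if (is.null(reference_wt)) reference_wt <- min(wt_all, na.rm = TRUE)
  n_rays <- 360L
  angles <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  per <- lapply(seq_along(stack), function(i) {
    w <- walls[[i]]
    if (is.null(w)) {
      return(list(coverage = 0, runs = numeric(0), skipped = TRUE))
    }
    sec <- stack[[i]]
    px <- sec$pixel_size
    img <- sec$image
    ctr <- w$centroid_uv
    rmax <- min(ctr[1], (ncol(img) - 1) * px - ctr[1],
                ctr[2], (nrow(img) - 1) * px - ctr[2])
    rr <- seq(0, rmax, by = step)
    V <- .ray_profiles(img, px, ctr, angles, rr)
    half_in <- (w$levels[["lumen"]] + w$levels[["wall"]]) / 2
    runs <- vapply(seq_len(n_rays), function(k) {
      v <- V[, k]
      pk_i <- which.max(v)
      ii <- which(v[seq_len(pk_i)] >= half_in)[1]
      if (is.na(ii)) return(0)
      # first supra-threshold sample at/after the inner edge; the lumen-wall
      # ramp crosses hu_threshold slightly after the half-maximum point, so
      # allow at most 1 mm of ramp before the run must begin
      rest <- v[ii:length(v)]
      j0 <- which(rest > hu_threshold)[1]
      if (is.na(j0) || (j0 - 1L) * step > 1) return(0)
      over <- rest[j0:length(rest)] > hu_threshold
      stop_at <- which(!over)[1]
      len <- if (is.na(stop_at)) length(over) else stop_at - 1L
      # run measured from the inner wall edge (the soft-tissue span)
      (j0 - 1L + len) * step
    }, numeric(1))
    qual <- runs >= reference_wt + min_thickness_mm
    list(coverage = mean(qual), runs = runs[qual] - reference_wt,
      skipped = FALSE)
  })
  coverage <- vapply(per, `[[`, numeric(1), "coverage")
  above <- coverage > min_coverage
  # longest run of consecutive qualifying sections
  r <- rle(above)
  best_len <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  positive <- best_len > min_slices
  cuff_thick <- if (best_len > 0) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bi <- which(r$values & r$lengths == best_len)[1]
    stats::median(unlist(lapply(starts[bi]:ends[bi], function(i) per[[i]]$runs)))
  } else 0
  arc <- vapply(stack, function(s) s$arc_position, numeric(1))
  structure(
    list(
      positive = positive,
      coverage_fraction = max(coverage),
      cuff_thickness_mm = cuff_thick,
      consecutive_slices = as.integer(best_len),
      reference_wt_mm = reference_wt,
      per_section = tibble::tibble(
        arc_position = arc, coverage = coverage,
        skipped = vapply(per, `[[`, logical(1), "skipped")
      )
    ),
    class = "cuffing_result"
  )
}

#' @export
print.cuffing_result <- function(x, ...) {
  cat(sprintf(
    "<cuffing_result> %s: coverage %.2f, thickness %.2f mm, %d consecutive sections\n",
    if (x$positive) "POSITIVE" else "negative",
    x$coverage_fraction, x$cuff_thickness_mm, x$consecutive_slices
  ))
  invisible(x)
}
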