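# Oblique resampling, centerline smoothing, curved planar reformation.

test_that("axial identity resample reproduces the slice at voxel centres", {
  set.seed(21)
  vol <- voxel_volume(array(rnorm(15 * 15 * 15, -600, 250), c(15, 15, 15)),
    c(0.62, 0.62, 0.62))
  k <- 8L # slice index (1-based)
  ctr <- c((k - 1) * 0.62, 7 * 0.62, 7 * 0.62)
  pl <- oblique_plane(ctr, u_axis = c(0, 0, 1), v_axis = c(0, 1, 0),
    extent = c(14 * 0.62, 14 * 0.62), pixel_size = 0.62)
  cs <- resample_plane(vol, pl)
  expect_equal(dim(cs$image), c(15L, 15L))
  expect_equal(cs$image, vol$data[k, , ], tolerance = 1e-12)
  expect_error(oblique_plane(c(0, 0, 0), c(0, 0, 1), c(0, 0.3, 1)), "orthonormal")
})

test_that("a 45-degree oblique section through a tube is an ellipse with minor axis = diameter", {
  ph <- make_airway_phantom(
    airway_phantom_spec(noise_sd = 0, length = 16),
    spacing = c(0.31, 0.31, 0.31)
  )
  ctr <- ph$ground_truth$center_mm
  # plane whose normal is 45 degrees off the tube (z) axis
  u <- c(0, 0, 1)
  v <- c(1, 1, 0) / sqrt(2)
  cs <- resample_plane(ph$volume,
    oblique_plane(ctr, u, v, extent = c(16, 16), pixel_size = 0.31))
  # lumen is -1000 HU; exclude the -1024 out-of-volume fill
  lum <- which(cs$image < -950 & cs$image > -1015, arr.ind = TRUE)
  pts <- cbind(lum[, 2], lum[, 1]) * cs$pixel_size
  ev <- eigen(stats::cov(pts), symmetric = TRUE)$values
  # full extents ~ 4 * sqrt(eigenvalue) for a uniform ellipse
  minor <- 4 * sqrt(ev[2])
  major <- 4 * sqrt(ev[1])
  expect_lt(abs(minor - 4.0), 0.4)
  expect_lt(abs(major - 4.0 * sqrt(2)), 0.6)
})

test_that("smooth_centerline preserves straight lines and yields uniform speed", {
  # straight line: output collinear, zero deviation
  t <- seq(0, 20, by = 2)
  straight <- centerline(cbind(t, 0.5 * t, -0.25 * t))
  sm <- smooth_centerline(straight, 0.5)
  dir <- c(1, 0.5, -0.25) / sqrt(sum(c(1, 0.5, -0.25)^2))
  seg <- sweep(sm$points, 2, sm$points[1, ])
  expect_lt(max(abs(seg - (seg %*% dir) %*% t(dir))), 1e-6)
  expect_lt(attr(sm, "max_deviation_mm"), 1e-6)
  expect_equal(sm$points[1, ], straight$points[1, ])
  expect_equal(sm$points[nrow(sm$points), ], straight$points[nrow(straight$points), ])

  # helix sampled at ~1 mm, resampled at 0.5 mm: uniform arc increments
  s <- seq(0, 30, by = 1)
  helix <- centerline(cbind(0.8 * s, 5 * cos(s / 5), 5 * sin(s / 5)))
  hm <- smooth_centerline(helix, 0.5)
  incr <- diff(hm$arc_length)
  expect_lt(max(abs(incr[-length(incr)] - 0.5)), 1e-6)
  # chord lengths agree with the arc steps to curvature order
  ch <- sqrt(rowSums((hm$points[-1, ] - hm$points[-nrow(hm$points), ])^2))
  expect_lt(max(abs(ch[-length(ch)] - 0.5)), 5e-3)

  expect_error(smooth_centerline(centerline(cbind(0:2, 0:2, 0:2)), 0.5),
    "at least 4")
})

test_that("CPR of a straight path equals the axial stack and frames stay continuous", {
  set.seed(22)
  vol <- voxel_volume(array(rnorm(20 * 21 * 21, -700, 200), c(20, 21, 21)),
    c(0.62, 0.62, 0.62))
  ctr_yx <- 10 * 0.62
  cl <- centerline(cbind(seq(2, 17) * 0.62, ctr_yx, ctr_yx))
  stack <- curved_planar_reformation(vol, cl,
    width = 8 * 0.62, pixel_size = 0.62, step = 0.62)
  expect_equal(length(stack), 16L)
  arcs <- vapply(stack, function(s) s$arc_position, numeric(1))
  expect_true(all(diff(arcs) > 0))
  # each section must reproduce the corresponding axial sub-block exactly
  for (i in c(1, 8, 16)) {
    img <- stack[[i]]$image
    k <- 2 + i # 1-based slice
    sub <- vol$data[k, 7:15, 7:15]
    # the RMF frame may be any in-plane rotation/flip of the axial axes;
    # compare as multisets and via the centre row/column
    expect_equal(sort(as.vector(img)), sort(as.vector(sub)), tolerance = 1e-9)
    expect_equal(img[5, 5], vol$data[k, 11, 11], tolerance = 1e-9)
  }
  # frame continuity on a smooth curved path
  s <- seq(0, 24, by = 0.5)
  curved <- centerline(cbind(s, 3 * sin(s / 8), 3 * cos(s / 8)))
  Tn <- bvbquant:::centerline_tangents(curved)
  fr <- bvbquant:::rm_frames(curved$points, Tn)
  dots <- rowSums(fr$u[-1, ] * fr$u[-nrow(fr$u), ])
  max_turn <- max(acos(pmin(pmax(dots, -1), 1))) * 180 / pi
  expect_lt(max_turn, 10)
  # bounds checking
  expect_error(
    curved_planar_reformation(vol, centerline(cbind(c(0, 10), c(0, 0), c(0, 0))),
      width = 10),
    "bounds"
  )
})

test_that("CPR recovers the true diameter of a bent tube in every section", {
  s <- seq(0, 22, by = 1)
  path <- cbind(s, 8 + 3 * sin(s / 10), 8 + 3 * (1 - cos(s / 10)))
  cl <- centerline(path)
  ph <- make_tube_phantom(cl, lumen_diameter = 4, wall_thickness = 1.2,
    spacing = c(0.45, 0.45, 0.45), margin_mm = 4)
  stack <- curved_planar_reformation(ph$volume, cl,
    width = 14, pixel_size = 0.3, step = 1.0)
  inner <- seq(4, length(stack) - 3) # avoid end-cap partial sections
  ds <- vapply(stack[inner], function(cs) {
    measure_wall(cs)$inner_diameter_d
  }, numeric(1))
  expect_true(all(abs(ds - 4) / 4 < 0.05))
})

test_that("measured diameter is invariant to tube orientation", {
  set.seed(23)
  ds <- vapply(1:8, function(i) {
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ph <- make_airway_phantom(
      airway_phantom_spec(axis = ax, noise_sd = 0, length = 10),
      spacing = c(0.62, 0.62, 0.62)
    )
    fr <- bvbquant:::.axis_frame(ax)
    cs <- resample_plane(ph$volume,
      oblique_plane(ph$ground_truth$center_mm, fr$e1, fr$e2,
        extent = c(14, 14), pixel_size = 0.31))
    measure_wall(cs)$inner_diameter_d
  }, numeric(1))
  expect_lt(max(ds) - min(ds), 0.62) # within one in-plane voxel
  expect_lt(max(abs(ds - 4)), 0.62)
})
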