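# Wall morphometry, bifurcation angles, fractal dimension, cuffing rule.

test_that("FWHM wall measurement recovers WT/D on noise-free and noisy phantoms", {
  # stage-I design point, noise-free
  m1 <- measure_wall(phantom_axial_section(4.0, 1.04, spacing = 0.31)$section)
  expect_lt(abs(m1$wt_d_ratio - 0.26), 0.01)
  expect_equal(m1$wall_thickness_wt / m1$inner_diameter_d, m1$wt_d_ratio)
  # scale invariance: same ratio for the x2 phantom
  m2 <- measure_wall(phantom_axial_section(8.0, 2.08, spacing = 0.31)$section)
  expect_lt(abs(m2$wt_d_ratio - m1$wt_d_ratio), 0.01)
  # stage-III design point under the stated noise level, 20 seeds
  ratios <- vapply(1:20, function(s) {
    measure_wall(
      phantom_axial_section(4.0, 1.40, spacing = 0.31, noise_sd = 12.4,
        seed = s)$section
    )$wt_d_ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.35), 0.02)
  # a seed outside the lumen violates the precondition
  # a seed on the wall (soft tissue) violates the air-density precondition
  sec <- phantom_axial_section(4.0, 1.04, spacing = 0.31)$section
  ctr_mm <- (dim(sec$image) - 1) / 2 * sec$pixel_size
  expect_error(measure_wall(sec, lumen_seed = c(ctr_mm[2] + 2.5, ctr_mm[1])),
    "air-density")
})

test_that("WT/D is invariant to in-plane rotation of the section", {
  ph <- make_airway_phantom(airway_phantom_spec(noise_sd = 0),
    spacing = c(0.31, 0.31, 0.31))
  ctr <- ph$ground_truth$center_mm
  set.seed(31)
  ratios <- vapply(1:10, function(i) {
    a <- runif(1, 0, 2 * pi)
    u <- c(0, sin(a), cos(a))
    v <- c(0, cos(a), -sin(a))
    cs <- resample_plane(ph$volume,
      oblique_plane(ctr, u, v, extent = c(14, 14), pixel_size = 0.31))
    measure_wall(cs)$wt_d_ratio
  }, numeric(1))
  expect_lt(max(ratios) - min(ratios), 0.01)
})

test_that("the narrowest section is selected with deterministic tie-breaks", {
  # sinusoidal stenosis: D(arc) = 4 - 1 * exp-profile, minimum 3.0 at 10 mm
  arcs <- seq(0, 20, by = 1)
  ds <- 4 - 1 * exp(-((arcs - 10) / 4)^2)
  stack <- annulus_stack(ds, wall = 1.0, arc_step = 1)
  nar <- find_narrowest_section(stack)
  expect_lte(abs(nar$section$arc_position - 10), 1)
  expect_lt(abs(nar$measurement$inner_diameter_d - 3.0), 0.1)
  # constant-diameter tube: tie broken to the first section
  const <- annulus_stack(rep(4, 5), arc_step = 0.62)
  expect_equal(find_narrowest_section(const)$index, 1L)
  expect_error(find_narrowest_section(const[1:2]), "at least 3")
})

test_that("branch directions and 3D angles are recovered from centerlines", {
  z <- seq(0, 12, by = 0.5)
  straight <- centerline(cbind(z, 0 * z, 0 * z) + 1)
  expect_equal(branch_direction(straight, c(1, 1, 1)), c(1, 0, 0),
    tolerance = 1e-9)
  # robustness to isotropic jitter, 50 seeds
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    pts <- cbind(z, 0 * z, 0 * z) + matrix(rnorm(3 * length(z), 0, 0.1),
      ncol = 3)
    d <- branch_direction(centerline(pts), c(0, 0, 0), length = 10)
    bifurcation_angle(d, c(1, 0, 0))
  }, numeric(1))
  expect_lt(mean(errs), 2)
  expect_error(
    branch_direction(centerline(cbind(c(0, 1e-8, 2e-8), 0, 0) + 0), c(0, 0, 0)),
    "degenerate|distinct|fewer"
  )
  expect_equal(bifurcation_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  th <- 110 * pi / 180
  expect_equal(bifurcation_angle(c(1, 0, 0), c(cos(th), 0, sin(th))), 110,
    tolerance = 1e-9)
  expect_equal(bifurcation_angle(c(0.3, -0.4, 0.5), c(0.3, -0.4, 0.5)), 0,
    tolerance = 1e-4)
  expect_error(bifurcation_angle(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("AVI is the absolute deviation from the 110-degree reference", {
  expect_equal(compute_avi(110), 0)
  expect_equal(compute_avi(126.92), 16.92)
  expect_equal(compute_avi(101.73), 8.27)
  # symmetry about the reference
  set.seed(32)
  x <- runif(20, 0, 70)
  expect_equal(compute_avi(110 + x), compute_avi(110 - x))
  expect_error(compute_avi(200), "\\[0, 180\\]")
})

test_that("the peribronchial annulus matches its analytic area", {
  sec <- annulus_section(lumen_d = 4, wall = 1, px = 0.25, extent = 18)
  w <- measure_wall(sec)
  roi <- peribronchial_roi(sec, w, band_mm = 2)
  r_out <- w$inner_diameter_d / 2 + w$wall_thickness_wt
  analytic <- pi * ((r_out + 2)^2 - r_out^2)
  expect_lt(abs(sum(roi) * 0.25^2 - analytic), 0.1 * analytic)
  expect_equal(sum(peribronchial_roi(sec, w, band_mm = 0)), 0)
  expect_error(peribronchial_roi(sec, w, band_mm = 50), "bounds")
})

test_that("box counting reproduces analytic dimensions and is monotone under inclusion", {
  filled <- box_counting_fd(matrix(1, 81, 81))
  expect_lt(abs(filled$fd - 2.0), 0.05)
  carpet <- make_fractal_texture(
    fractal_texture_spec("sierpinski_carpet", depth = 4), size = 81
  )
  expect_lt(abs(box_counting_fd(carpet$image)$fd - 1.8928), 0.05)
  pt <- matrix(0, 81, 81)
  pt[40, 40] <- 1
  expect_equal(box_counting_fd(pt)$fd, 0, tolerance = 0.05)
  # counts non-increasing as box size grows
  expect_true(all(diff(filled$box_counts) < 0))
  expect_true(all(diff(carpet$box_counts) <= 0))
  # monotone under set inclusion: point <= curve <= filled square
  curve <- matrix(0, 81, 81)
  curve[41, ] <- 1
  expect_lt(box_counting_fd(pt)$fd, box_counting_fd(curve)$fd)
  expect_lt(box_counting_fd(curve)$fd, filled$fd)
  # degenerate inputs
  expect_error(box_counting_fd(matrix(0, 81, 81)), "empty foreground")
  expect_error(box_counting_fd(matrix(1, 10, 10)), "27")
  # scalar input binarised at the soft-tissue threshold
  hu <- matrix(-850, 81, 81)
  hu[30:50, 30:50] <- 50
  res <- box_counting_fd(hu, pixel_size = 0.31, threshold = 30)
  expect_equal(res$fd, 2.0, tolerance = 0.3)
})

test_that("fbm textures land near their target dimension across seeds", {
  for (tgt in c(1.41, 1.68)) {
    est <- vapply(1:20, function(s) {
      tx <- make_fractal_texture(fractal_texture_spec("fbm", tgt, seed = s))
      box_counting_fd(tx$image)$fd
    }, numeric(1))
    expect_lt(abs(mean(est) - tgt), 0.08)
  }
})

test_that("the cuffing rule fires on qualifying rings only", {
  # 360-degree, 3 mm, 50 HU cuff on 5 consecutive of 8 sections -> positive
  cuffed <- c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  stack <- annulus_stack(rep(4, 8), cuffed = cuffed)
  res <- detect_cuffing(stack)
  expect_true(res$positive)
  expect_gte(res$consecutive_slices, 4L)
  expect_gt(res$coverage_fraction, 0.9)
  expect_lt(abs(res$cuff_thickness_mm - 3), 0.5)
  # 40% coverage fails the circumference criterion
  stack40 <- lapply(seq_len(8), function(i) {
    annulus_section(4, 1.04, cuff_thickness = if (cuffed[i]) 3 else 0,
      cuff_coverage = 0.4, arc_position = (i - 1) * 0.62)
  })
  expect_false(detect_cuffing(stack40)$positive)
  # a 1 mm ring fails the thickness criterion
  stack1mm <- lapply(seq_len(8), function(i) {
    annulus_section(4, 1.04, cuff_thickness = if (cuffed[i]) 1 else 0,
      arc_position = (i - 1) * 0.62)
  })
  expect_false(detect_cuffing(stack1mm)$positive)
  # only 3 consecutive cuffed sections fails "more than 3 slices"
  stack3 <- annulus_stack(rep(4, 8),
    cuffed = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_false(detect_cuffing(stack3)$positive)
  expect_error(detect_cuffing(stack[1:3]), "min_slices")
})

test_that("cuffing detection is monotone in every criterion", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 8
    cuffed <- runif(n) < 0.6
    thick <- runif(1, 0.5, 4)
    cov <- runif(1, 0.3, 1)
    stack <- lapply(seq_len(n), function(i) {
      annulus_section(4, 1.04, cuff_thickness = if (cuffed[i]) thick else 0,
        cuff_coverage = cov, arc_position = (i - 1) * 0.62,
        noise_sd = 5, seed = rep * 100 + i)
    })
    walls <- lapply(stack, measure_wall)
    base <- detect_cuffing(stack, walls = walls, reference_wt = 1.04)
    stricter <- list(
      detect_cuffing(stack, walls, hu_threshold = 45, reference_wt = 1.04),
      detect_cuffing(stack, walls, min_coverage = 0.7, reference_wt = 1.04),
      detect_cuffing(stack, walls, min_thickness_mm = 3, reference_wt = 1.04),
      detect_cuffing(stack, walls, min_slices = 5, reference_wt = 1.04)
    )
    if (!base$positive) {
      for (s in stricter) expect_false(s$positive)
    }
  }
})
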