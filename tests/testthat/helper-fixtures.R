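# Shared fixture builders: all synthetic, generated at test time.

# Axial cross-section of a straight z-axis airway phantom, measured via the
# real volume -> resample path.
phantom_axial_section <- function(lumen_d = 4.0, wall = 1.04, spacing = 0.31,
                                  noise_sd = 0, seed = 1L, extent = NULL,
                                  cuff = NULL) {
  ph <- make_airway_phantom(
    airway_phantom_spec(
      lumen_diameter = lumen_d, wall_thickness = wall,
      noise_sd = noise_sd, seed = seed, cuff = cuff
    ),
    spacing = rep(spacing, 3)
  )
  # keep the section inside the phantom (no fill contamination of the
  # parenchyma plateau) and make its extent a voxel-pitch multiple so the
  # reformation grid aligns with voxel centres: targeted recons are centred
  # on the structure, and alignment lets the wall plateau be sampled purely
  if (is.null(extent)) {
    extent <- 2 * spacing * ceiling((lumen_d / 2 + wall + 3.2) / spacing)
  }
  ctr <- ph$ground_truth$center_mm
  # reformat at half the voxel pitch: avoids a second voxel-sized blur
  pl <- oblique_plane(ctr, u_axis = c(0, 0, 1), v_axis = c(0, 1, 0),
    extent = c(extent, extent), pixel_size = spacing / 2)
  list(section = resample_plane(ph$volume, pl), phantom = ph)
}

# Analytic annulus cross-section built directly as an image (no volume):
# cheap building block for stacks. Optional cuff ring sector just outside
# the wall.
annulus_section <- function(lumen_d = 4.0, wall = 1.04, px = 0.2,
                            extent = 18, arc_position = NA_real_,
                            lumen_hu = -1000, wall_hu = 40, par_hu = -850,
                            cuff_thickness = 0, cuff_coverage = 1,
                            cuff_hu = 50, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(extent / px) + 1
  ctr <- (n - 1) / 2 * px
  x <- (seq_len(n) - 1) * px - ctr
  r <- sqrt(outer(x^2, x^2, `+`))
  ang <- atan2(matrix(x, n, n), matrix(x, n, n, byrow = TRUE))
  img <- matrix(par_hu, n, n)
  r_out <- lumen_d / 2 + wall
  if (cuff_thickness > 0) {
    sel <- r >= r_out & r < r_out + cuff_thickness &
      abs(ang) <= cuff_coverage * pi
    img[sel] <- cuff_hu
  }
  img[r < r_out] <- wall_hu
  img[r < lumen_d / 2] <- lumen_hu
  if (noise_sd > 0) img <- img + matrix(rnorm(n * n, 0, noise_sd), n, n)
  structure(
    list(image = img, pixel_size = px, center_world = c(0, ctr, ctr),
         normal = c(1, 0, 0), u_axis = c(0, 0, 1), v_axis = c(0, 1, 0),
         arc_position = arc_position),
    class = "cross_section"
  )
}

# Stack of analytic sections with per-section lumen diameter / cuff flags.
annulus_stack <- function(lumen_ds, wall = 1.04, cuffed = rep(FALSE, length(lumen_ds)),
                          arc_step = 0.62, ...) {
  lapply(seq_along(lumen_ds), function(i) {
    annulus_section(
      lumen_d = lumen_ds[i], wall = wall,
      cuff_thickness = if (cuffed[i]) 3 else 0,
      arc_position = (i - 1) * arc_step, ...
    )
  })
}

# Brute-force AUC oracle: mean over all case-control pairs, ties 1/2.
auc_oracle <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Direct-summation weighted-kappa oracle (explicit double loops).
kappa_oracle <- function(c1, c2, weights = "none") {
  lev <- sort(union(unique(as.character(c1)), unique(as.character(c2))))
  K <- length(lev)
  n <- length(c1)
  p <- matrix(0, K, K)
  for (t in seq_len(n)) {
    i <- match(as.character(c1[t]), lev)
    j <- match(as.character(c2[t]), lev)
    p[i, j] <- p[i, j] + 1 / n
  }
  w <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    w[i, j] <- switch(weights,
      none = as.numeric(i == j),
      linear = 1 - abs(i - j) / (K - 1),
      quadratic = 1 - ((i - j) / (K - 1))^2
    )
  }
  po <- 0; pe <- 0
  pi_ <- rowSums(p); pj_ <- colSums(p)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    po <- po + w[i, j] * p[i, j]
    pe <- pe + w[i, j] * pi_[i] * pj_[j]
  }
  (po - pe) / (1 - pe)
}
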