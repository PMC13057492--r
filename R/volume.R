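#' Voxel volume in Hounsfield units
#'
#' Container for a 3D scalar CT-like grid. The array is indexed `[z, y, x]`
#' with `z` the slice axis; `spacing` and `origin` are length-3 numerics in
#' the same `(z, y, x)` order, in millimetres. Voxel indices are 0-based for
#' the world transform: `world = origin + index * spacing` (axis-aligned; no
#' rotation matrix — phantoms are generated axis-aligned).
#'
#' @param data 3D numeric array of HU values, dimension `(nz, ny, nx)`.
#' @param spacing Length-3 positive numeric, voxel size in mm `(z, y, x)`.
#' @param origin Length-3 numeric, world position of voxel `(0,0,0)` in mm.
#'   Default `c(0, 0, 0)`.
#' @return An object of class `voxel_volume`.
#' @examples
#' vol <- voxel_volume(array(-1000, c(4, 4, 4)), spacing = c(0.62, 0.62, 0.62))
#' voxel_to_world(vol, c(1, 2, 3))
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("volume data must be finite (no NA/NaN/Inf voxels)", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%.2f, %.2f, %.2f) mm\n",
    min(x$data), max(x$data), x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

#' World/voxel coordinate transforms
#'
#' Affine diagonal transform between 0-based voxel indices and world mm, both
#' in `(z, y, x)` order. The two functions are exact mutual inverses.
#'
#' @param vol A [voxel_volume].
#' @param idx,point Numeric vector of length 3, or an `n x 3` matrix.
#' @return Same shape as the input, transformed.
#' @export
voxel_to_world <- function(vol, idx) {
  if (is.matrix(idx)) {
    sweep(sweep(idx, 2, vol$spacing, `*`), 2, vol$origin, `+`)
  } else {
    vol$origin + idx * vol$spacing
  }
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, point) {
  if (is.matrix(point)) {
    sweep(sweep(point, 2, vol$origin, `-`), 2, vol$spacing, `/`)
  } else {
    (point - vol$origin) / vol$spacing
  }
}

#' CT display window
#'
#' @param center Window centre in HU.
#' @param width Window width in HU, must be positive. The default
#'   centre/width of −600/1500 HU is a conventional lung window.
#' @return An object of class `window_setting`.
#' @export
window_setting <- function(center = -600, width = 1500) {
  if (!is.finite(width) || width <= 0) stop("window width must be > 0", call. = FALSE)
  if (!is.finite(center)) stop("window center must be finite", call. = FALSE)
  structure(list(center = center, width = width), class = "window_setting")
}

#' Apply a display window to a volume
#'
#' Maps HU value `v` to `clip((v - (center - width/2)) / width, 0, 1)`;
#' monotone non-decreasing in `v`.
#'
#' @param vol A [voxel_volume].
#' @param w A [window_setting].
#' @return A [voxel_volume] whose data lie in `[0, 1]`.
#' @export
apply_window <- function(vol, w = window_setting()) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(w, "window_setting"))
  lo <- w$center - w$width / 2
  out <- pmin(pmax((vol$data - lo) / w$width, 0), 1)
  dim(out) <- dim(vol$data)
  voxel_volume(out, vol$spacing, vol$origin)
}

#' Trilinear sampling of a volume at world points
#'
#' Interpolates the 8 surrounding voxels; exact at voxel centres and for
#' affine HU fields, bounded by the local min/max. Points outside the
#' volume's world bounding box receive `fill` (default −1024 HU, air) or
#' raise an error when `fill = NULL`.
#'
#' @param vol A [voxel_volume].
#' @param points Length-3 vector or `n x 3` matrix of world mm `(z, y, x)`.
#' @param fill HU value for out-of-bounds points, or `NULL` to error.
#' @return Numeric vector of sampled HU values.
#' @export
sample_trilinear <- function(vol, points, fill = -1024) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  v <- world_to_voxel(vol, points)
  d <- dim(vol$data)
  oob <- v[, 1] < 0 | v[, 1] > d[1] - 1 |
    v[, 2] < 0 | v[, 2] > d[2] - 1 |
    v[, 3] < 0 | v[, 3] > d[3] - 1
  if (any(oob) && is.null(fill)) {
    stop(sprintf("%d sample point(s) outside the volume", sum(oob)), call. = FALSE)
  }
  # clamp so the index arithmetic stays valid; overwritten with fill below
  vc <- v
  for (k in 1:3) vc[, k] <- pmin(pmax(vc[, k], 0), d[k] - 1)
  i0 <- floor(vc)
  # keep the upper corner in range on the top faces
  for (k in 1:3) i0[, k] <- pmin(i0[, k], d[k] - 2)
  i0[i0 < 0] <- 0
  f <- vc - i0
  if (any(d == 1L)) f[, d == 1L] <- 0
  idx8 <- function(dz, dy, dx) {
    vol$data[cbind(
      pmin(i0[, 1] + dz, d[1] - 1) + 1,
      pmin(i0[, 2] + dy, d[2] - 1) + 1,
      pmin(i0[, 3] + dx, d[3] - 1) + 1
    )]
  }
  fz <- f[, 1]; fy <- f[, 2]; fx <- f[, 3]
  out <-
    (1 - fz) * ((1 - fy) * ((1 - fx) * idx8(0, 0, 0) + fx * idx8(0, 0, 1)) +
      fy * ((1 - fx) * idx8(0, 1, 0) + fx * idx8(0, 1, 1))) +
    fz * ((1 - fy) * ((1 - fx) * idx8(1, 0, 0) + fx * idx8(1, 0, 1)) +
      fy * ((1 - fx) * idx8(1, 1, 0) + fx * idx8(1, 1, 1)))
  if (any(oob)) out[oob] <- fill
  out
}

#' Read / write volumes as raw-array + JSON sidecar pairs
#'
#' Volumes are stored losslessly as float64 little-endian raw data
#' (`<path>.raw`) next to a JSON sidecar (`<path>.json`) carrying dimensions,
#' spacing, origin and an md5 checksum of the raw payload. Optional
#' `ground_truth` metadata (e.g. phantom parameters) round-trips through the
#' sidecar.
#'
#' @param path File path without extension (or with `.json`, which is
#'   stripped).
#' @param vol A [voxel_volume].
#' @param ground_truth Optional list of ground-truth metadata stored in the
#'   sidecar.
#' @return `read_volume`: a [voxel_volume] (with a `ground_truth` attribute
#'   when present). `write_volume`: the sidecar path, invisibly.
#' @export
write_volume <- function(vol, path, ground_truth = NULL) {
  stopifnot(inherits(vol, "voxel_volume"))
  base <- sub("\\.json$", "", path)
  raw_path <- paste0(base, ".raw")
  con <- file(raw_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  close(con); on.exit()
  sidecar <- list(
    format = "bvbquant-raw-v1",
    dtype = "float64le",
    dim = dim(vol$data),
    spacing_mm = vol$spacing,
    origin_mm = vol$origin,
    hu_calibrated = TRUE,
    checksum_md5 = unname(tools::md5sum(raw_path))
  )
  if (!is.null(ground_truth)) sidecar$ground_truth <- ground_truth
  jsonlite::write_json(sidecar, paste0(base, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paste0(base, ".json"))
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  base <- sub("\\.json$", "", path)
  json_path <- paste0(base, ".json")
  raw_path <- paste0(base, ".raw")
  if (!file.exists(json_path)) stop("sidecar not found: ", json_path, call. = FALSE)
  if (!file.exists(raw_path)) stop("raw data not found: ", raw_path, call. = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(meta$spacing_mm) || any(!is.finite(as.numeric(meta$spacing_mm))) ||
    any(as.numeric(meta$spacing_mm) <= 0)) {
    stop("format error: missing or non-positive spacing metadata", call. = FALSE)
  }
  d <- as.integer(meta$dim)
  con <- file(raw_path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = prod(d), size = 8, endian = "little")
  if (length(vals) != prod(d)) stop("format error: truncated raw payload", call. = FALSE)
  vol <- voxel_volume(array(vals, d), as.numeric(meta$spacing_mm), as.numeric(meta$origin_mm))
  if (!is.null(meta$ground_truth)) attr(vol, "ground_truth") <- meta$ground_truth
  vol
}
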