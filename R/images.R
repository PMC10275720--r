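#' Spatial image volumes
#'
#' `image_volume()` is the universal spatial carrier of the package: a 3-D
#' scalar grid plus a 4x4 affine mapping homogeneous *0-based* voxel indices
#' to world coordinates in mm (the NIfTI voxel-to-world convention).
#' `time_series_image()` adds a time axis and a repetition time (TR).
#'
#' @param data numeric array, 3-D for `image_volume`, 4-D (x, y, z, time)
#'   for `time_series_image`.
#' @param affine 4x4 numeric matrix; must be invertible, last row
#'   `c(0, 0, 0, 1)`.
#' @param space free-text label of the coordinate frame the affine maps
#'   into (e.g. `"synthetic-mni"`); carried along, never interpreted.
#' @param tr repetition time in seconds (> 0).
#' @return An object of class `"image_volume"` (or
#'   `c("time_series_image", "image_volume")`) with elements `data`,
#'   `affine`, `space` and, for time series, `tr`.
#' @examples
#' vol <- image_volume(array(0, c(5, 5, 5)), diag(4))
#' dim(vol$data)
#' @export
image_volume <- function(data, affine, space = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  check_affine(affine)
  if (any(dim(data) <= 0L)) stop("data dimensions must be positive")
  structure(list(data = data, affine = affine, space = space),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
time_series_image <- function(data, affine, tr, space = "unknown") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("'data' must be a 4-D array (x, y, z, time)")
  if (dim(data)[4] < 2L) stop("time dimension must have at least 2 volumes")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a single positive number (seconds)")
  check_affine(affine)
  structure(list(data = data, affine = affine, tr = tr, space = space),
            class = c("time_series_image", "image_volume"))
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stop("last affine row must be c(0, 0, 0, 1)")
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12) stop("affine is singular")
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  kind <- if (inherits(x, "time_series_image")) "time_series_image" else "image_volume"
  cat(sprintf("<%s> %s voxels, space '%s'\n", kind,
              paste(d, collapse = " x "), x$space))
  cat("voxel spacing (mm):", paste(signif(voxel_spacing(x$affine), 4),
                                   collapse = " x "), "\n")
  if (inherits(x, "time_series_image"))
    cat(sprintf("TR: %g s (%d volumes)\n", x$tr, d[4]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

## per-axis voxel spacing in mm from the affine columns
voxel_spacing <- function(affine) {
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(sp <= 0)) stop("zero voxel spacing in affine")
  sp
}

is_binary <- function(x) all(x %in% c(0, 1))

#' Map points between voxel and world coordinates
#'
#' Applies the volume's affine (voxel to world) or its inverse (world to
#' voxel). Voxel indices are 0-based and may be fractional.
#'
#' @param volume an [image_volume()] (a 4x4 affine is also accepted).
#' @param points numeric 3-vector or n x 3 matrix of points.
#' @param direction `"voxel_to_world"` or `"world_to_voxel"`.
#' @return Points in the requested frame, same shape as the input.
#' @examples
#' vol <- image_volume(array(0, c(5, 5, 5)), diag(4))
#' voxel_world_transform(vol, c(1, 2, 3), "voxel_to_world")
#' @export
voxel_world_transform <- function(volume, points,
                                  direction = c("voxel_to_world",
                                                "world_to_voxel")) {
  direction <- match.arg(direction)
  affine <- if (is.matrix(volume)) volume else volume$affine
  check_affine(affine)
  vec_in <- is.null(dim(points))
  pts <- if (vec_in) matrix(points, nrow = 1L) else as.matrix(points)
  if (ncol(pts) != 3L) stop("'points' must be a 3-vector or n x 3 matrix")
  m <- if (direction == "voxel_to_world") affine else solve(affine)
  out <- cbind(pts, 1) %*% t(m)
  out <- out[, 1:3, drop = FALSE]
  if (vec_in) drop(out) else out
}

## world coordinates (n x 3) of every voxel center, 0-based grid, x fastest
grid_world_coords <- function(affine, shape) {
  idx <- as.matrix(expand.grid(x = seq_len(shape[1]) - 1L,
                               y = seq_len(shape[2]) - 1L,
                               z = seq_len(shape[3]) - 1L))
  voxel_world_transform(affine, idx, "voxel_to_world")
}

#' Resample a volume onto a target grid
#'
#' Pulls values from `source` at the world positions of the target grid's
#' voxel centers, by nearest-neighbour or trilinear interpolation in the
#' source's index space. Target voxels falling outside the source footprint
#' are filled with 0, so binary masks stay binary.
#'
#' @param source an [image_volume()].
#' @param target_affine 4x4 voxel-to-world affine of the target grid.
#' @param target_shape integer 3-vector of target dimensions.
#' @param method `"linear"` or `"nearest"`; use `"nearest"` for masks and
#'   label images.
#' @return An [image_volume()] on the target grid.
#' @export
resample_to_grid <- function(source, target_affine, target_shape,
                             method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(source, "image_volume"))
  check_affine(target_affine)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape <= 0L))
    stop("'target_shape' must be 3 positive integers")

  world <- grid_world_coords(target_affine, target_shape)
  sv <- voxel_world_transform(source$affine, world, "world_to_voxel")
  d <- dim(source$data)

  vals <- if (method == "nearest") {
    iv <- round(sv)
    inside <- iv[, 1] >= 0 & iv[, 1] <= d[1] - 1 &
              iv[, 2] >= 0 & iv[, 2] <= d[2] - 1 &
              iv[, 3] >= 0 & iv[, 3] <= d[3] - 1
    out <- numeric(nrow(iv))
    lin <- 1L + iv[inside, 1] + d[1] * (iv[inside, 2] + d[2] * iv[inside, 3])
    out[inside] <- source$data[lin]
    out
  } else {
    trilinear_sample(source$data, sv)
  }
  if (all(vals == 0) && any(source$data != 0))
    warning("target grid does not overlap the source footprint; output is all zero")
  image_volume(array(vals, dim = target_shape), target_affine, source$space)
}

## trilinear interpolation at fractional 0-based voxel coords (n x 3);
## outside the grid -> 0
trilinear_sample <- function(data, vox) {
  d <- dim(data)
  f <- floor(vox)
  w <- vox - f
  out <- numeric(nrow(vox))
  ## corners with clamped indices; corners outside contribute 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- f[, 1] + cx; iy <- f[, 2] + cy; iz <- f[, 3] + cz
    wt <- (if (cx == 1) w[, 1] else 1 - w[, 1]) *
          (if (cy == 1) w[, 2] else 1 - w[, 2]) *
          (if (cz == 1) w[, 3] else 1 - w[, 3])
    ok <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
          iz >= 0 & iz <= d[3] - 1 & wt > 0
    if (any(ok)) {
      lin <- 1L + ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok])
      out[ok] <- out[ok] + wt[ok] * data[lin]
    }
  }
  out
}

## convenience: affine for an axis-aligned grid with given spacing (mm) and
## world position of voxel (0,0,0)
make_affine <- function(spacing, origin) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(spacing, 3)
  a[1:3, 4] <- origin
  a
}

## grid centred on world 0 along each axis
centered_grid <- function(shape, spacing) {
  origin <- -(shape - 1) / 2 * spacing
  list(affine = make_affine(rep(spacing, 3), origin), shape = as.integer(shape))
}
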