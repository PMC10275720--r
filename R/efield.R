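#' Electrode description for stimulation-volume modeling
#'
#' A minimal DBS electrode model: a set of contact centers (world mm), a
#' common contact radius, and the active-contact configuration. The field
#' model treats each active contact as a spherical source in a uniform
#' medium; see [compute_efield()].
#'
#' @param contact_centers n x 3 matrix (or 3-vector) of contact centers, mm.
#' @param active data.frame with columns `contact` (1-based index into
#'   `contact_centers`), `polarity` (+1 or -1) and `amplitude`
#'   (V in voltage mode, mA in current mode), one row per active contact.
#' @param mode `"voltage"` or `"current"`.
#' @param contact_radius contact sphere radius in mm (default 0.635, a
#'   typical DBS contact radius).
#' @return Object of class `"electrode_model"`.
#' @export
electrode_model <- function(contact_centers, active,
                            mode = c("voltage", "current"),
                            contact_radius = 0.635) {
  mode <- match.arg(mode)
  if (is.null(dim(contact_centers)))
    contact_centers <- matrix(contact_centers, ncol = 3)
  contact_centers <- as.matrix(contact_centers)
  if (ncol(contact_centers) != 3L) stop("'contact_centers' must be n x 3 (mm)")
  active <- as.data.frame(active)
  if (!all(c("contact", "polarity", "amplitude") %in% names(active)))
    stop("'active' needs columns contact, polarity, amplitude")
  if (nrow(active) < 1L) stop("at least one active contact is required")
  if (any(active$amplitude <= 0)) stop("amplitudes must be positive")
  if (!all(active$polarity %in% c(-1, 1))) stop("polarity must be +1 or -1")
  if (any(active$contact < 1L | active$contact > nrow(contact_centers)))
    stop("active contact index out of range")
  if (contact_radius <= 0) stop("'contact_radius' must be positive")
  structure(list(contact_centers = contact_centers, active = active,
                 mode = mode, contact_radius = contact_radius),
            class = "electrode_model")
}

## E-field vectors (V/mm) of one electrode at arbitrary world points (n x 3).
## Each active contact is a spherical source:
##   current mode:  |E|(r) = I / (4 pi sigma r^2)   (I in mA, r in mm, sigma
##                  in S/m -- the mixed units cancel to V/mm exactly)
##   voltage mode:  |E|(r) = V r0 / r^2             (sphere of radius r0 at
##                  potential V)
## Inside the contact sphere the magnitude is held at its surface value.
## Contacts superpose as vectors with their polarity signs.
efield_vectors <- function(electrode, points, conductivity = 0.14) {
  if (conductivity <= 0) stop("'conductivity' must be positive (S/m)")
  pts <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  ev <- matrix(0, nrow(pts), 3)
  r0 <- electrode$contact_radius
  for (k in seq_len(nrow(electrode$active))) {
    a <- electrode$active[k, ]
    ctr <- electrode$contact_centers[a$contact, ]
    d <- sweep(pts, 2, ctr)
    r <- sqrt(rowSums(d^2))
    reff <- pmax(r, r0)
    mag <- if (electrode$mode == "current") {
      a$amplitude / (4 * pi * conductivity * reff^2)
    } else {
      a$amplitude * r0 / reff^2
    }
    unit <- d / pmax(r, 1e-9)
    unit[r < 1e-9, ] <- rep(c(1, 0, 0), each = sum(r < 1e-9))
    ev <- ev + a$polarity * mag * unit
  }
  ev
}

#' Simplified electric-field magnitude on a grid
#'
#' Evaluates the analytic spherical-source field of all active contacts at
#' every voxel center and returns the magnitude of the vector sum, in V/mm.
#' This stands in for a finite-element solve of the static Laplace equation
#' in a uniform medium (default conductivity 0.14 S/m); its thresholded
#' output is the quantity the downstream analysis consumes.
#'
#' @param electrode an [electrode_model()].
#' @param affine 4x4 voxel-to-world affine of the output grid.
#' @param shape integer 3-vector of grid dimensions.
#' @param conductivity medium conductivity in S/m (current mode only).
#' @return An [image_volume()] of |E| in V/mm.
#' @export
compute_efield <- function(electrode, affine, shape, conductivity = 0.14) {
  stopifnot(inherits(electrode, "electrode_model"))
  check_affine(affine)
  shape <- as.integer(shape)
  pts <- grid_world_coords(affine, shape)
  ## require the grid to enclose all active contacts
  ctrs <- electrode$contact_centers[electrode$active$contact, , drop = FALSE]
  vox <- voxel_world_transform(affine, ctrs, "world_to_voxel")
  if (any(vox < -0.5) || any(sweep(vox, 2, shape - 0.5) > 0))
    stop("grid does not enclose all active contacts")
  ev <- efield_vectors(electrode, pts, conductivity)
  mag <- sqrt(rowSums(ev^2))
  image_volume(array(mag, dim = shape), affine, space = "efield")
}

#' Threshold an E-field into a stimulation volume
#'
#' Voxels whose field magnitude is *strictly* above `threshold` form the
#' binary stimulation volume (VTA); the default 0.2 V/mm is the standard
#' activation threshold.
#'
#' @param efield [image_volume()] of |E| in V/mm (non-negative).
#' @param threshold activation threshold in V/mm.
#' @param patient_id,side identifiers carried on the result.
#' @return A `"stimulation_volume"`: list with binary `mask`
#'   ([image_volume()]), `patient_id`, `side`, `empty` flag.
#' @export
binarize_efield <- function(efield, threshold = 0.2, patient_id = NA_character_,
                            side = c("combined", "left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(efield, "image_volume"))
  if (any(efield$data < 0)) stop("E-field magnitudes must be non-negative")
  mask <- array(as.numeric(efield$data > threshold), dim = dim(efield$data))
  empty <- !any(mask == 1)
  if (empty) warning("no voxel exceeds the threshold: empty stimulation volume")
  stimulation_volume(image_volume(mask, efield$affine, efield$space),
                     patient_id = patient_id, side = side)
}

#' @rdname binarize_efield
#' @param mask binary [image_volume()].
#' @export
stimulation_volume <- function(mask, patient_id = NA_character_,
                               side = c("combined", "left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(mask, "image_volume"))
  if (!is_binary(mask$data)) stop("stimulation volume mask must be binary {0,1}")
  structure(list(mask = mask, patient_id = patient_id, side = side,
                 empty = !any(mask$data == 1)),
            class = "stimulation_volume")
}

#' @export
print.stimulation_volume <- function(x, ...) {
  cat(sprintf("<stimulation_volume> patient %s, side %s, %d voxels\n",
              x$patient_id, x$side, sum(x$mask$data)))
  invisible(x)
}

#' Union of left and right stimulation volumes
#'
#' @param left,right `stimulation_volume`s on the same grid.
#' @return The combined (voxel-wise OR) `stimulation_volume`.
#' @export
combine_bilateral <- function(left, right) {
  stopifnot(inherits(left, "stimulation_volume"),
            inherits(right, "stimulation_volume"))
  if (!isTRUE(all.equal(dim(left$mask$data), dim(right$mask$data))) ||
      max(abs(left$mask$affine - right$mask$affine)) > 1e-8)
    stop("left and right stimulation volumes are on different grids")
  m <- array(as.numeric(left$mask$data + right$mask$data > 0),
             dim = dim(left$mask$data))
  pid <- if (is.na(left$patient_id)) right$patient_id else left$patient_id
  stimulation_volume(image_volume(m, left$mask$affine, left$mask$space),
                     patient_id = pid, side = "combined")
}
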