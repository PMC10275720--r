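#' Framewise displacement from a motion trace
#'
#' Power-style framewise displacement: for each volume after the first,
#' the sum of absolute backward differences of the three translations (mm)
#' plus `head_radius` times the sum of absolute backward differences of
#' the three rotations (rad), i.e. rotations are converted to arc length
#' on a sphere of `head_radius` mm. The first volume has FD 0.
#'
#' @param motion numeric matrix with one row per volume and 6 columns:
#'   translations x, y, z in mm, then rotations about x, y, z in rad.
#' @param head_radius sphere radius in mm used for the rotation terms.
#' @return Numeric vector of per-volume FD values in mm.
#' @export
compute_fd <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L || nrow(motion) < 2L || !is.numeric(motion) ||
      anyNA(motion))
    stop("'motion' must be a numeric matrix with >= 2 rows and 6 columns")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' Motion quality control over a subject list
#'
#' Excludes a subject if and only if the fraction of its volumes with
#' FD *strictly* greater than `fd_threshold` is *strictly* greater than
#' `volume_fraction` (both boundaries read strictly, so a subject sitting
#' exactly on either limit is retained).
#'
#' @param subjects list of subjects; each element needs a `$motion` matrix
#'   (e.g. [simulate_connectome_subject()] output).
#' @param fd_threshold FD cut in mm (default 0.5).
#' @param volume_fraction fraction-of-volumes cut (default 0.5).
#' @param head_radius passed to [compute_fd()].
#' @return List with `retained`, `excluded` (subject lists) and `summary`
#'   (data.frame: subject_id, mean_fd, max_fd, frac_high, excluded).
#' @export
qc_filter <- function(subjects, fd_threshold = 0.5, volume_fraction = 0.5,
                      head_radius = 50) {
  if (!length(subjects)) stop("'subjects' must be a nonempty list")
  stats <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    fd <- compute_fd(s$motion, head_radius)
    id <- if (!is.null(s$subject_id)) s$subject_id else sprintf("sub-%03d", i)
    data.frame(subject_id = id, mean_fd = mean(fd), max_fd = max(fd),
               frac_high = mean(fd > fd_threshold),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, stats)
  summary$excluded <- summary$frac_high > volume_fraction
  list(retained = subjects[!summary$excluded],
       excluded = subjects[summary$excluded],
       summary = summary)
}

## OLS-residualize the columns of a time x voxels matrix against design X
## (which should contain an intercept); voxel means are re-added so the
## signal keeps its baseline. Collinear design columns are dropped with a
## warning.
residualize <- function(Y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient design: dropping ", ncol(X) - qx$rank,
            " collinear column(s)")
  }
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  mu <- colMeans(Y)
  R <- Y - Q %*% crossprod(Q, Y)
  sweep(R, 2, mu, "+")
}

## 4-D array <-> voxels x time matrix
bold_matrix <- function(bold) {
  d <- dim(bold$data)
  matrix(bold$data, prod(d[1:3]), d[4])
}
bold_from_matrix <- function(V, bold) {
  time_series_image(array(V, dim = dim(bold$data)), bold$affine,
                    tr = bold$tr, space = bold$space)
}

#' Regress motion parameters out of a BOLD series
#'
#' Per-voxel ordinary least-squares residualization against an intercept,
#' a linear trend, and the 6 motion parameters; voxel means are re-added.
#'
#' @param bold a [time_series_image()].
#' @param motion matrix of 6 motion parameters, one row per volume.
#' @return The residual [time_series_image()].
#' @export
regress_motion <- function(bold, motion) {
  stopifnot(inherits(bold, "time_series_image"))
  motion <- as.matrix(motion)
  nt <- dim(bold$data)[4]
  if (nrow(motion) != nt)
    stop("motion trace length (", nrow(motion),
         ") does not match the number of volumes (", nt, ")")
  X <- cbind(1, scale(seq_len(nt)), motion)
  V <- t(residualize(t(bold_matrix(bold)), X))
  bold_from_matrix(V, bold)
}

## 1-D convolution matrix for a symmetric normalized kernel; rows are
## renormalized at the edges so a constant field stays exactly constant
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- (j - r):(j + r)
    ok <- i >= 1 & i <= n
    K[i[ok], j] <- kernel[ok]
  }
  K / rowSums(K)
}

## convolve one array axis with a kernel matrix
conv_axis <- function(arr, axis, K) {
  d <- dim(arr)
  perm <- c(axis, seq_along(d)[-axis])
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, d[axis])
  aperm(array(m, d[perm]), order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Separable 3-D Gaussian convolution with
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))` mm, converted to voxels per
#' axis via the affine's spacings (anisotropic grids are handled
#' per-axis). For 4-D series each volume is smoothed independently.
#' The kernel is normalized and renormalized at the grid edges, so a
#' constant field is preserved exactly and sums are preserved away from
#' the boundary.
#'
#' @param bold an [image_volume()] or [time_series_image()].
#' @param fwhm full width at half maximum of the kernel, mm (default 6).
#' @return The smoothed image, same class and grid.
#' @export
smooth_spatial <- function(bold, fwhm = 6) {
  stopifnot(inherits(bold, "image_volume"))
  if (fwhm <= 0) stop("'fwhm' must be positive (mm)")
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  spacing <- voxel_spacing(bold$affine)
  arr <- bold$data
  for (ax in 1:3) {
    sig <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(4 * sig))
    k <- stats::dnorm(-r:r, sd = sig)
    k <- k / sum(k)
    arr <- conv_axis(arr, ax, conv_matrix(dim(arr)[ax], k))
  }
  if (inherits(bold, "time_series_image"))
    time_series_image(arr, bold$affine, tr = bold$tr, space = bold$space)
  else image_volume(arr, bold$affine, bold$space)
}

#' Band-pass Butterworth coefficients
#'
#' Second-order Butterworth band-pass design at the given cutoffs; the
#' single-pass amplitude response is 1/sqrt(2) at each cutoff by the
#' Butterworth definition. The pipeline applies it forward-backward
#' (zero phase), which squares the magnitude response.
#'
#' @param low_cut,high_cut passband edges in Hz.
#' @param tr sampling interval (repetition time) in seconds.
#' @return A `signal::butter` filter object (coefficients `b`, `a`).
#' @export
bandpass_coefficients <- function(low_cut = 0.01, high_cut = 0.08, tr = 2) {
  nyq <- 1 / (2 * tr)
  if (low_cut <= 0 || high_cut <= low_cut)
    stop("need 0 < low_cut < high_cut")
  if (high_cut >= nyq)
    stop("high_cut must be below the Nyquist frequency ", nyq, " Hz")
  signal::butter(2, c(low_cut, high_cut) / nyq, type = "pass")
}

#' Temporal band-pass filtering of a BOLD series
#'
#' Zero-phase (forward-backward) second-order Butterworth band-pass,
#' default 0.01-0.08 Hz, applied per voxel; per-voxel means are re-added
#' after filtering. An optional mask limits the work to in-brain voxels
#' (outside-mask voxels are passed through unchanged).
#'
#' @param bold a [time_series_image()].
#' @param low_cut,high_cut passband edges in Hz.
#' @param mask optional binary [image_volume()] restricting computation.
#' @return The filtered [time_series_image()].
#' @export
temporal_filter <- function(bold, low_cut = 0.01, high_cut = 0.08,
                            mask = NULL) {
  stopifnot(inherits(bold, "time_series_image"))
  bf <- bandpass_coefficients(low_cut, high_cut, bold$tr)
  V <- bold_matrix(bold)
  rows <- if (is.null(mask)) seq_len(nrow(V)) else which(mask$data == 1)
  mu <- rowMeans(V[rows, , drop = FALSE])
  filtered <- t(apply(V[rows, , drop = FALSE], 1,
                      function(x) signal::filtfilt(bf, x - mean(x))))
  V[rows, ] <- filtered + mu
  bold_from_matrix(V, bold)
}

#' Nuisance regression against CSF, white-matter and global signals
#'
#' Residualizes every voxel time course against the mean time course over
#' the CSF mask, the white-matter mask and (optionally) the whole-brain
#' mask, plus an intercept; voxel means are re-added.
#'
#' @param bold a [time_series_image()].
#' @param csf_mask,wm_mask binary [image_volume()]s on the BOLD grid.
#' @param global_signal if `TRUE` (default) also regress the global mean
#'   signal.
#' @param brain_mask mask defining the global signal (default: whole grid).
#' @return The residual [time_series_image()].
#' @export
nuisance_regress <- function(bold, csf_mask, wm_mask, global_signal = TRUE,
                             brain_mask = NULL) {
  stopifnot(inherits(bold, "time_series_image"))
  V <- bold_matrix(bold)
  mean_tc <- function(mask, what) {
    idx <- which(mask$data == 1)
    if (!length(idx)) stop("empty ", what, " mask")
    if (!identical(dim(mask$data), dim(bold$data)[1:3]))
      stop(what, " mask is not on the BOLD grid")
    colMeans(V[idx, , drop = FALSE])
  }
  X <- cbind(1, csf = mean_tc(csf_mask, "CSF"), wm = mean_tc(wm_mask, "WM"))
  if (global_signal) {
    g <- if (is.null(brain_mask)) colMeans(V)
         else mean_tc(brain_mask, "brain")
    X <- cbind(X, global = g)
  }
  V <- t(residualize(t(V), X))
  bold_from_matrix(V, bold)
}

#' Masked voxels-by-volumes matrix of a BOLD series
#'
#' Extracts the in-mask voxel time courses as a matrix with one row per
#' voxel, rows ordered by the grid's native raster order (x fastest, then
#' y, then z), which makes the extraction exactly invertible.
#'
#' @param bold a [time_series_image()].
#' @param brain_mask binary [image_volume()] on the BOLD grid.
#' @param subject_id identifier carried on the result.
#' @return A `"connectome_matrix"`: list with `values` (voxels x volumes),
#'   `voxel_index` (0-based n x 3), `linear_index`, `brain_mask`, `tr`,
#'   `subject_id`.
#' @export
build_matrix <- function(bold, brain_mask, subject_id = NA_character_) {
  stopifnot(inherits(bold, "time_series_image"),
            inherits(brain_mask, "image_volume"))
  if (!identical(dim(brain_mask$data), dim(bold$data)[1:3]))
    stop("brain mask is not on the BOLD grid")
  if (!is_binary(brain_mask$data)) stop("brain mask must be binary")
  lin <- which(brain_mask$data == 1)
  if (!length(lin)) stop("empty brain mask")
  V <- bold_matrix(bold)[lin, , drop = FALSE]
  structure(list(values = V,
                 voxel_index = arrayInd(lin, dim(brain_mask$data)) - 1L,
                 linear_index = lin, brain_mask = brain_mask, tr = bold$tr,
                 subject_id = subject_id),
            class = "connectome_matrix")
}

#' @export
print.connectome_matrix <- function(x, ...) {
  cat(sprintf("<connectome_matrix> %s: %d voxels x %d volumes, TR %g s\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

#' Put per-voxel values (or the full matrix) back on the grid
#'
#' @param cmat a [build_matrix()] result.
#' @param values per-voxel vector (returns an [image_volume()]) or a
#'   voxels x volumes matrix (returns a [time_series_image()]); default:
#'   the stored matrix.
#' @param fill value for out-of-mask voxels.
#' @return An [image_volume()] or [time_series_image()].
#' @export
matrix_to_volume <- function(cmat, values = cmat$values, fill = 0) {
  stopifnot(inherits(cmat, "connectome_matrix"))
  shp <- dim(cmat$brain_mask$data)
  if (is.matrix(values)) {
    arr <- array(fill, c(shp, ncol(values)))
    nvox <- prod(shp)
    for (t in seq_len(ncol(values)))
      arr[cmat$linear_index + (t - 1L) * nvox] <- values[, t]
    time_series_image(arr, cmat$brain_mask$affine, tr = cmat$tr,
                      space = cmat$brain_mask$space)
  } else {
    arr <- array(fill, shp)
    arr[cmat$linear_index] <- values
    image_volume(arr, cmat$brain_mask$affine, cmat$brain_mask$space)
  }
}

#' Full single-subject preprocessing chain
#'
#' Runs the standard order: motion regression, spatial smoothing,
#' band-pass filtering, nuisance regression (CSF + WM, optionally global),
#' then extracts the masked voxels-by-volumes matrix.
#'
#' @param subject a `connectome_subject` (needs `bold`, `motion`, `masks`).
#' @param fwhm smoothing kernel FWHM in mm.
#' @param band passband edges in Hz, length 2.
#' @param global_signal regress the global signal (default `TRUE`).
#' @return A `"connectome_matrix"`.
#' @export
preprocess_subject <- function(subject, fwhm = 6, band = c(0.01, 0.08),
                               global_signal = TRUE) {
  b <- regress_motion(subject$bold, subject$motion)
  b <- smooth_spatial(b, fwhm)
  b <- temporal_filter(b, band[1], band[2], mask = subject$masks$brain)
  b <- nuisance_regress(b, subject$masks$csf, subject$masks$wm,
                        global_signal = global_signal,
                        brain_mask = subject$masks$brain)
  build_matrix(b, subject$masks$brain, subject_id = subject$subject_id)
}
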