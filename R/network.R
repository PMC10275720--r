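#' Seed-based connectivity map of one connectome subject
#'
#' Correlates the average BOLD time course inside the seed (a stimulation
#' volume resampled to the connectome grid) with every in-mask voxel's
#' time course. Voxels with a constant time course get r = 0 and are
#' counted in the `n_constant` attribute rather than left undefined.
#'
#' @param seed a `stimulation_volume` or binary [image_volume()] on the
#'   connectome grid.
#' @param subject a `"connectome_matrix"` ([build_matrix()] output).
#' @return An [image_volume()] of r values (`NA` outside the brain mask),
#'   with attribute `n_constant`.
#' @export
seed_fingerprint <- function(seed, subject) {
  stopifnot(inherits(subject, "connectome_matrix"))
  m <- as_mask_array(seed)
  if (!identical(dim(m), dim(subject$brain_mask$data)) ||
      max(abs(mask_affine(seed) - subject$brain_mask$affine)) > 1e-8)
    stop("seed is not on the connectome grid; resample it first")
  rows <- which(m[subject$linear_index] == 1)
  if (!length(rows)) stop("seed does not intersect the brain mask")
  V <- subject$values
  seed_tc <- colMeans(V[rows, , drop = FALSE])
  st <- seed_tc - mean(seed_tc)
  ss <- sqrt(sum(st^2))
  if (ss == 0) stop("seed time course is constant")
  Vc <- V - rowMeans(V)
  sv <- sqrt(rowSums(Vc^2))
  const <- sv <= 1e-12 * max(sv, 1)
  r <- numeric(nrow(V))
  r[!const] <- (Vc[!const, , drop = FALSE] %*% st) / (sv[!const] * ss)
  r <- pmin(1, pmax(-1, r))
  arr <- array(NA_real_, dim(subject$brain_mask$data))
  arr[subject$linear_index] <- r
  out <- image_volume(arr, subject$brain_mask$affine,
                      subject$brain_mask$space)
  attr(out, "n_constant") <- sum(const)
  out
}

#' Group connectivity fingerprint of one patient
#'
#' Averages a patient's per-subject seed correlation maps across the
#' connectome subjects and Fisher-Z transforms the average
#' (average first, then `atanh`; the alternative order is available via
#' `order = "z-then-average"`).
#'
#' @param per_subject_maps list of r-value [image_volume()]s on a shared
#'   grid (one per connectome subject).
#' @param patient_id identifier carried on the result.
#' @param order averaging order; the default matches the group-average
#'   definition used throughout the package.
#' @return A `"fingerprint"`: list with `zmap` ([image_volume()]),
#'   `patient_id`, `n_subjects_used`.
#' @export
group_fingerprint <- function(per_subject_maps, patient_id = NA_character_,
                              order = c("average-then-z", "z-then-average")) {
  order <- match.arg(order)
  if (!length(per_subject_maps)) stop("need at least one subject map")
  shp <- dim(per_subject_maps[[1]]$data)
  stack <- vapply(per_subject_maps, function(v) {
    if (!identical(dim(v$data), shp)) stop("subject maps on different grids")
    as.numeric(v$data)
  }, numeric(prod(shp)))
  z <- if (order == "average-then-z") fisher_z(rowMeans(stack))
       else rowMeans(apply(stack, 2, fisher_z))
  structure(list(
    zmap = image_volume(array(z, shp), per_subject_maps[[1]]$affine,
                        per_subject_maps[[1]]$space),
    patient_id = patient_id,
    n_subjects_used = length(per_subject_maps)),
    class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> patient %s, averaged over %d connectome subjects\n",
              x$patient_id, x$n_subjects_used))
  invisible(x)
}

#' Fit the voxel-wise R-map network model
#'
#' For every voxel, correlates the patients' Fisher-Z connectivity values
#' with their clinical improvements (Pearson, across patients). Voxels
#' with zero across-patient variance, or undefined connectivity, are
#' excluded from the `included` mask and carry `NA`.
#'
#' @param fingerprints list of [group_fingerprint()] objects, one per
#'   patient (>= 5), on a shared grid.
#' @param improvements numeric vector of improvements (%), one per
#'   patient, not constant.
#' @return An object of class `"rmap"`: list with `rmap` ([image_volume()]
#'   of voxel-wise r), `included` (binary [image_volume()]),
#'   `improvements`, `n_patients`, `call`. Methods: `print`, `summary`,
#'   `predict` (spatial similarity of new fingerprints), `plot`.
#' @export
rmap_fit <- function(fingerprints, improvements) {
  n <- length(fingerprints)
  if (n < 5L) stop("rmap_fit needs at least 5 patients")
  if (length(improvements) != n)
    stop("'improvements' must have one value per fingerprint")
  if (stats::sd(improvements) == 0) stop("improvements are constant")
  shp <- dim(fingerprints[[1]]$zmap$data)
  Z <- vapply(fingerprints, function(f) {
    if (!identical(dim(f$zmap$data), shp))
      stop("fingerprints on different grids")
    as.numeric(f$zmap$data)
  }, numeric(prod(shp)))
  w <- as.numeric(improvements)
  wc <- w - mean(w)
  sw <- sqrt(sum(wc^2))
  finite <- rowSums(!is.finite(Z)) == 0
  Zc <- Z - rowMeans(Z)
  sz <- sqrt(rowSums(Zc^2))
  included <- finite & sz > 1e-12
  r <- rep(NA_real_, nrow(Z))
  r[included] <- (Zc[included, , drop = FALSE] %*% wc) / (sz[included] * sw)
  r[included] <- pmin(1, pmax(-1, r[included]))
  affine <- fingerprints[[1]]$zmap$affine
  space <- fingerprints[[1]]$zmap$space
  structure(list(
    rmap = image_volume(array(r, shp), affine, space),
    included = image_volume(array(as.numeric(included), shp), affine, space),
    improvements = w, n_patients = n, call = match.call()),
    class = "rmap")
}

#' @export
print.rmap <- function(x, ...) {
  cat(sprintf("<rmap> network model over %d patients; %d voxels included\n",
              x$n_patients, sum(x$included$data)))
  invisible(x)
}

#' @export
summary.rmap <- function(object, ...) {
  r <- object$rmap$data[object$included$data == 1]
  out <- list(n_patients = object$n_patients,
              n_included = sum(object$included$data),
              r_range = if (length(r)) range(r) else c(NA, NA),
              mean_abs_r = mean(abs(r)))
  class(out) <- "summary.rmap"
  out
}

#' @export
print.summary.rmap <- function(x, ...) {
  cat(sprintf("R-map: %d patients, %d included voxels\n",
              x$n_patients, x$n_included))
  cat(sprintf("voxel-wise r in [%.3f, %.3f], mean |r| = %.3f\n",
              x$r_range[1], x$r_range[2], x$mean_abs_r))
  invisible(x)
}

#' @export
plot.rmap <- function(x, slice = NULL, ...) {
  r <- x$rmap$data
  if (is.null(slice)) {
    nz <- which(apply(!is.na(r), 3, any))
    slice <- if (length(nz)) nz[ceiling(length(nz) / 2)] else dim(r)[3] %/% 2
  }
  img <- r[, , slice]
  img[is.na(img)] <- 0
  graphics::image(img, main = sprintf("R-map, axial slice %d", slice),
                  xlab = "x", ylab = "y", col = grDevices::hcl.colors(64),
                  ...)
  invisible(x)
}

#' Spatial similarity of a fingerprint to the R-map
#'
#' Pearson correlation over the voxels jointly included in both maps
#' (at least 10 required).
#'
#' @param fingerprint a [group_fingerprint()] object.
#' @param rmap a fitted [rmap_fit()] model.
#' @return The spatial correlation coefficient.
#' @export
spatial_similarity <- function(fingerprint, rmap) {
  stopifnot(inherits(fingerprint, "fingerprint"), inherits(rmap, "rmap"))
  z <- fingerprint$zmap$data
  if (!identical(dim(z), dim(rmap$rmap$data)))
    stop("fingerprint and R-map are on different grids")
  joint <- which(rmap$included$data == 1 & is.finite(z))
  if (length(joint) < 10L)
    stop("fewer than 10 jointly included voxels")
  pearson_r(z[joint], rmap$rmap$data[joint])
}

#' @rdname spatial_similarity
#' @param object a fitted `"rmap"` model.
#' @param newdata list of fingerprints to score.
#' @param ... unused.
#' @export
predict.rmap <- function(object, newdata, ...) {
  vapply(newdata, function(f) spatial_similarity(f, object), numeric(1))
}

#' Leave-one-out spatial similarities
#'
#' Out-of-sample variant of the fingerprint-to-R-map similarity: each
#' patient is scored against the R-map fitted on the other n - 1 patients.
#' This is *not* the default (in-sample) validation procedure — it is
#' provided as a stricter optional check, and needs n >= 6 so every
#' leave-one-out fit keeps at least 5 patients.
#'
#' @inheritParams rmap_fit
#' @return Numeric vector of out-of-sample similarities, one per patient.
#' @export
loo_similarities <- function(fingerprints, improvements) {
  n <- length(fingerprints)
  if (n < 6L) stop("leave-one-out similarities need at least 6 patients")
  vapply(seq_len(n), function(i) {
    fit <- rmap_fit(fingerprints[-i], improvements[-i])
    spatial_similarity(fingerprints[[i]], fit)
  }, numeric(1))
}

#' Permutation validation of the network model
#'
#' Fits the R-map on all patients, scores each patient's fingerprint by
#' its spatial similarity to that R-map, and correlates the similarities
#' with the improvements under a permutation test. The R-map is built on
#' the same patients it is evaluated on (deliberate in-sample design), so
#' the *whole statistic is recomputed under every permutation*: each
#' permuted improvement vector yields its own voxel-wise R-map, its own
#' per-patient similarities, and a null correlation from those. Observed
#' and null values share the circularity, making the test exact under
#' exchangeability. One-sided (positive) with the add-one rule, as in
#' [permutation_pvalue()].
#'
#' @inheritParams rmap_fit
#' @param n_perm number of permutations.
#' @param seed integer RNG seed for the shuffles.
#' @return A `"permutation_test"` object with the fitted model attached
#'   as attribute `model`.
#' @export
validate_network_model <- function(fingerprints, improvements,
                                   n_perm = 1000, seed = 1L) {
  model <- rmap_fit(fingerprints, improvements)
  sims <- predict(model, fingerprints)
  w <- as.numeric(improvements)
  n <- length(w)
  observed_r <- pearson_r(sims, w)

  inc <- which(model$included$data == 1)
  Z <- vapply(fingerprints, function(f) f$zmap$data[inc],
              numeric(length(inc)))
  ## across-patient centering (for the per-permutation R-maps)
  Zp <- Z - rowMeans(Z)
  sz <- sqrt(rowSums(Zp^2))
  ## across-voxel standardization (for the spatial similarities)
  Zv <- scale(Z)
  perms <- with_seed(seed, replicate(n_perm, sample.int(n)))
  W <- matrix(w[perms], n, n_perm)
  Wc <- sweep(W, 2, colMeans(W))
  sw <- sqrt(colSums(Wc^2))
  R <- (Zp %*% Wc) / (sz %o% sw)      # voxel-wise R-map per permutation
  Rv <- scale(R)
  S <- crossprod(Zv, Rv) / (length(inc) - 1)  # similarities, n x n_perm
  Sc <- sweep(S, 2, colMeans(S))
  den <- sqrt(colSums(Sc^2)) * sw
  null_values <- ifelse(den > 0, colSums(Sc * Wc) / den, 0)
  null_values[!is.finite(null_values)] <- 0
  p <- (1 + sum(null_values >= observed_r)) / (1 + n_perm)
  out <- structure(list(observed_r = observed_r, permuted_p = p,
                        null_values = null_values, n_perm = n_perm,
                        seed = seed),
                   class = "permutation_test")
  attr(out, "model") <- model
  out
}
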