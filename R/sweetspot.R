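#' Percentage clinical improvement from pre/post scores
#'
#' `100 * (pre - post) / pre`; negative when the patient worsens.
#' Vectorized over patients.
#'
#' @param pre,post clinical rating-scale scores (higher = more severe);
#'   `pre` must be positive.
#' @return Improvement in percent.
#' @examples
#' percent_improvement(100, 50)  # 50
#' percent_improvement(80, 100)  # -25
#' @export
percent_improvement <- function(pre, post) {
  if (any(pre <= 0)) stop("'pre' scores must be positive")
  100 * (pre - post) / pre
}

#' Fit the voxel-wise sweetspot model (T-model)
#'
#' For every voxel, collects the improvement scores of the stimulation
#' volumes that cover it and tests their mean against zero with a
#' one-sample t-test ([one_sample_t()]). A voxel enters the model only if
#' its coverage is *strictly* greater than `min_coverage * n` volumes
#' (with the default 0.2 and n = 20 this is the "more than 4 patients"
#' rule); non-covering volumes contribute nothing to a voxel's sample.
#' Voxels outside the inclusion mask carry `NA`.
#'
#' @param volumes list of `stimulation_volume`s (or binary
#'   [image_volume()]s) on a shared grid; length >= 5.
#' @param improvements numeric vector of improvement scores (%), one per
#'   volume; signed (worsening = negative), uncapped.
#' @param min_coverage minimum coverage fraction (default 0.2).
#' @return An object of class `"sweetspot"`: list with `t_map`, `coverage`,
#'   `included` ([image_volume()]s), `n_total`, `min_coverage`,
#'   `improvements`, `call`. Methods: `print`, `summary`, `coef`
#'   (centre of gravity), `predict` (sum-of-t overlap scores), `plot`.
#' @examples
#' ## five masks sharing a common core on a tiny grid
#' mk <- function(ix) {
#'   a <- array(0, c(6, 6, 6)); a[2:4, 2:4, 2:4] <- 1; a[ix, 1, 1] <- 1
#'   image_volume(a, diag(4))
#' }
#' fit <- sweetspot_fit(lapply(1:5, mk), c(50, 30, 40, 60, 20))
#' summary(fit)
#' @export
sweetspot_fit <- function(volumes, improvements, min_coverage = 0.2) {
  masks <- lapply(volumes, as_mask_array)
  n <- length(masks)
  if (n < 5L) stop("sweetspot_fit needs at least 5 stimulation volumes")
  if (length(improvements) != n)
    stop("'improvements' must have one value per volume")
  affine <- mask_affine(volumes[[1]])
  shp <- dim(masks[[1]])
  for (m in masks[-1])
    if (!identical(dim(m), shp)) stop("stimulation volumes are on different grids")
  for (v in volumes[-1])
    if (max(abs(mask_affine(v) - affine)) > 1e-8)
      stop("stimulation volumes are on different grids")

  w <- as.numeric(improvements)
  cov <- s1 <- s2 <- array(0, shp)
  for (i in seq_len(n)) {
    cov <- cov + masks[[i]]
    s1 <- s1 + w[i] * masks[[i]]
    s2 <- s2 + w[i]^2 * masks[[i]]
  }
  ## strict coverage gate; a t needs at least 2 covering volumes
  included <- cov > min_coverage * n & cov >= 2
  t_map <- array(NA_real_, shp)
  if (!any(included)) {
    warning("no voxel passes the coverage gate: empty sweetspot model")
  } else {
    k <- cov[included]
    m <- s1[included] / k
    v <- pmax((s2[included] - k * m^2) / (k - 1), 0)
    scale <- max(abs(w), 1)
    degen <- sqrt(v) <= 1e-12 * scale
    t <- numeric(length(k))
    t[!degen] <- m[!degen] / sqrt(v[!degen] / k[!degen])
    t[degen] <- ifelse(abs(m[degen]) <= 1e-12 * scale, 0,
                       sign(m[degen]) * 1e6)
    t_map[included] <- t
  }
  structure(list(
    t_map = image_volume(t_map, affine, mask_space(volumes[[1]])),
    coverage = image_volume(cov, affine, mask_space(volumes[[1]])),
    included = image_volume(array(as.numeric(included), shp), affine,
                            mask_space(volumes[[1]])),
    n_total = n, min_coverage = min_coverage, improvements = w,
    call = match.call()),
    class = "sweetspot")
}

as_mask_array <- function(v) {
  m <- if (inherits(v, "stimulation_volume")) v$mask$data
       else if (inherits(v, "image_volume")) v$data
       else stop("expected a stimulation_volume or image_volume")
  if (!is_binary(m)) stop("stimulation volumes must be binary {0,1}")
  m
}
mask_affine <- function(v)
  if (inherits(v, "stimulation_volume")) v$mask$affine else v$affine
mask_space <- function(v)
  if (inherits(v, "stimulation_volume")) v$mask$space else v$space

#' Sum-of-t overlap score of a stimulation volume with the sweetspot
#'
#' Sums the T-model's t-scores over the voxels that are both inside the
#' stimulation volume and included in the model; excluded voxels
#' contribute 0.
#'
#' @param tmodel a fitted [sweetspot_fit()] model.
#' @param volume a `stimulation_volume` (or binary [image_volume()]) on
#'   the model grid.
#' @return The sum-of-t score (scalar).
#' @export
overlap_score <- function(tmodel, volume) {
  stopifnot(inherits(tmodel, "sweetspot"))
  m <- as_mask_array(volume)
  if (!identical(dim(m), dim(tmodel$t_map$data)) ||
      max(abs(mask_affine(volume) - tmodel$t_map$affine)) > 1e-8)
    stop("stimulation volume is not on the model grid")
  sel <- m == 1 & tmodel$included$data == 1
  if (!any(sel)) return(0)
  sum(tmodel$t_map$data[sel])
}

#' @rdname overlap_score
#' @param object a `"sweetspot"` model.
#' @param newdata list of stimulation volumes to score.
#' @param ... unused.
#' @export
predict.sweetspot <- function(object, newdata, ...) {
  vapply(newdata, function(v) overlap_score(object, v), numeric(1))
}

#' Permutation validation of a sweetspot model
#'
#' Scores every cohort volume against the T-model with [overlap_score()],
#' correlates the scores with the improvements, and assesses the
#' correlation by permuting the improvement scores. Because the T-model is
#' built from the very improvements it is scored against (deliberate
#' in-sample design), the *whole statistic is recomputed under every
#' permutation*: the permuted improvements re-weight the voxel-wise
#' t-scores, new sum-of-t scores are drawn from the re-weighted map, and
#' the null correlation is computed from those. Observed and null values
#' therefore share the circularity and the test is exact under
#' exchangeability. The coverage-based inclusion mask does not depend on
#' the improvements, so it is fixed across permutations. One-sided
#' (positive) with the add-one rule, as in [permutation_pvalue()].
#'
#' @inheritParams sweetspot_fit
#' @param tmodel a fitted [sweetspot_fit()] model.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed for the shuffles.
#' @return A `"permutation_test"` object.
#' @export
validate_sweetspot <- function(tmodel, volumes, improvements,
                               n_perm = 1000, seed = 1L) {
  stopifnot(inherits(tmodel, "sweetspot"))
  w <- as.numeric(improvements)
  n <- length(w)
  if (length(volumes) != n) stop("input lengths differ")
  if (n < 5L) stop("permutation test needs at least 5 observations")
  if (stats::sd(w) == 0)
    stop("improvements are constant: correlation undefined under permutation")
  scores <- predict(tmodel, volumes)
  observed_r <- pearson_r(scores, w)

  inc <- which(tmodel$included$data == 1)
  if (!length(inc)) stop("empty sweetspot model: nothing to validate")
  Mi <- vapply(volumes, function(v) as_mask_array(v)[inc],
               numeric(length(inc)))
  k <- tmodel$coverage$data[inc]
  perms <- with_seed(seed, replicate(n_perm, sample.int(n)))
  W <- matrix(w[perms], n, n_perm)
  ## re-weighted t-map for every permutation, in one set of matrix products
  S1 <- Mi %*% W
  S2 <- Mi %*% W^2
  m <- S1 / k
  v <- pmax((S2 - k * m^2) / (k - 1), 0)
  scale <- max(abs(w), 1)
  t <- m / sqrt(v / k)
  degen <- sqrt(v) <= 1e-12 * scale
  t[degen] <- ifelse(abs(m[degen]) <= 1e-12 * scale, 0,
                     sign(m[degen]) * 1e6)
  S <- crossprod(Mi, t)  # per-permutation sum-of-t scores, n x n_perm
  Sc <- sweep(S, 2, colMeans(S))
  Wc <- sweep(W, 2, colMeans(W))
  den <- sqrt(colSums(Sc^2)) * sqrt(colSums(Wc^2))
  null_values <- ifelse(den > 0, colSums(Sc * Wc) / den, 0)
  p <- (1 + sum(null_values >= observed_r)) / (1 + n_perm)
  structure(list(observed_r = observed_r, permuted_p = p,
                 null_values = null_values, n_perm = n_perm, seed = seed),
            class = "permutation_test")
}

#' Centre of gravity of the sweetspot
#'
#' t-weighted centroid, in world mm, over included voxels with positive t
#' (optionally above a display threshold such as t >= 3).
#'
#' @param tmodel a fitted [sweetspot_fit()] model.
#' @param t_threshold optional extra threshold; the effective cut is
#'   `max(0, t_threshold)`.
#' @return World coordinates (mm) as a named 3-vector.
#' @export
sweetspot_cog <- function(tmodel, t_threshold = NULL) {
  stopifnot(inherits(tmodel, "sweetspot"))
  thr <- max(0, if (is.null(t_threshold)) 0 else t_threshold)
  t <- tmodel$t_map$data
  sel <- which(tmodel$included$data == 1 & !is.na(t) & t > thr)
  if (!length(sel)) stop("no included voxel with t above ", thr)
  vox <- arrayInd(sel, dim(t)) - 1L
  w <- voxel_world_transform(tmodel$t_map$affine, vox, "voxel_to_world")
  if (is.null(dim(w))) w <- matrix(w, 1)
  wt <- t[sel]
  cog <- colSums(w * wt) / sum(wt)
  stats::setNames(cog, c("x", "y", "z"))
}

#' @export
coef.sweetspot <- function(object, ...) sweetspot_cog(object)

#' @export
print.sweetspot <- function(x, ...) {
  cat(sprintf("<sweetspot> T-model over %d stimulation volumes; %d voxels included (coverage > %g%%)\n",
              x$n_total, sum(x$included$data), 100 * x$min_coverage))
  invisible(x)
}

#' @export
summary.sweetspot <- function(object, ...) {
  t <- object$t_map$data[object$included$data == 1]
  cog <- tryCatch(sweetspot_cog(object), error = function(e) rep(NA_real_, 3))
  out <- list(n_total = object$n_total,
              n_included = sum(object$included$data),
              t_range = if (length(t)) range(t) else c(NA, NA),
              n_positive = sum(t > 0), cog = cog)
  class(out) <- "summary.sweetspot"
  out
}

#' @export
print.summary.sweetspot <- function(x, ...) {
  cat(sprintf("Sweetspot T-model: %d patients, %d included voxels (%d with t > 0)\n",
              x$n_total, x$n_included, x$n_positive))
  cat(sprintf("t range: [%.2f, %.2f]\n", x$t_range[1], x$t_range[2]))
  cat(sprintf("centre of gravity (mm): x = %.2f, y = %.2f, z = %.2f\n",
              x$cog[1], x$cog[2], x$cog[3]))
  invisible(x)
}

#' @export
plot.sweetspot <- function(x, slice = NULL, ...) {
  t <- x$t_map$data
  if (is.null(slice)) {
    nz <- which(apply(!is.na(t), 3, any))
    slice <- if (length(nz)) nz[ceiling(length(nz) / 2)] else dim(t)[3] %/% 2
  }
  img <- t[, , slice]
  img[is.na(img)] <- 0
  graphics::image(img, main = sprintf("T-model, axial slice %d", slice),
                  xlab = "x", ylab = "y", col = grDevices::hcl.colors(64),
                  ...)
  invisible(x)
}
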