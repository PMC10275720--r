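#' Statistical primitives shared by the mapping analyses
#'
#' `one_sample_t()` is the voxel-level statistic of the sweetspot model:
#' the one-sample t of a set of improvement scores against zero,
#' t = mean / (sd / sqrt(n)) with the n-1 sample standard deviation.
#' A degenerate sample (sd = 0) returns 0 when the mean is also 0, and a
#' signed sentinel of magnitude 1e6 (with attribute `degenerate = TRUE`)
#' otherwise, so that constant non-zero samples sort above any finite t.
#'
#' @param values numeric vector, length >= 2.
#' @return The t statistic (scalar).
#' @examples
#' one_sample_t(c(50, 30, 40, 60, 20))  # 5.657
#' @export
one_sample_t <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("one_sample_t needs at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  scale <- max(abs(values), 1)
  if (s <= 1e-12 * scale) {
    if (abs(m) <= 1e-12 * scale) return(0)
    return(structure(sign(m) * 1e6, degenerate = TRUE))
  }
  m / (s / sqrt(n))
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with explicit degenerate handling: inputs must have
#' equal length at least 3 and non-zero variance.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("pearson_r needs at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: an input has zero variance")
  r <- stats::cor(x, y)
  min(1, max(-1, r))
}

#' Fisher Z transform
#'
#' Variance-stabilizing arctanh transform of a correlation coefficient.
#' Values with |r| >= 1 are clamped to +/- (1 - 1e-7) with a warning.
#'
#' @param r numeric vector of correlations.
#' @return `atanh(r)` after clamping.
#' @examples
#' fisher_z(0.5)  # 0.5493
#' @export
fisher_z <- function(r) {
  r <- as.numeric(r)
  out_of_range <- is.finite(r) & abs(r) >= 1
  if (any(out_of_range)) {
    warning("|r| >= 1 clamped to +/-(1 - 1e-7) before Fisher Z")
    r[out_of_range] <- sign(r[out_of_range]) * (1 - 1e-7)
  }
  atanh(r)
}

## evaluate expr under a given RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Permutation test of a Pearson correlation
#'
#' Correlates `scores` with `improvements` and assesses the correlation by
#' randomly permuting the improvement scores `n_perm` times (independent
#' uniform shuffles, seeded). The p-value is one-sided for a positive
#' correlation and uses the add-one rule
#' p = (1 + #\{null r >= observed r\}) / (1 + n_perm), so it is never 0.
#'
#' @param scores numeric vector (e.g. per-patient overlap or similarity).
#' @param improvements numeric vector of clinical improvements (%), same
#'   length as `scores` (>= 5), not constant.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer RNG seed for the shuffles.
#' @return An object of class `"permutation_test"`: a list with
#'   `observed_r`, `permuted_p`, `null_values`, `n_perm`, `seed`.
#' @export
permutation_pvalue <- function(scores, improvements, n_perm = 1000,
                               seed = 1L) {
  scores <- as.numeric(scores); improvements <- as.numeric(improvements)
  n <- length(scores)
  if (length(improvements) != n) stop("input lengths differ")
  if (n < 5L) stop("permutation test needs at least 5 observations")
  if (stats::sd(improvements) == 0)
    stop("improvements are constant: correlation undefined under permutation")
  observed_r <- pearson_r(scores, improvements)
  zs <- (scores - mean(scores)) / stats::sd(scores)
  zi <- (improvements - mean(improvements)) / stats::sd(improvements)
  null_values <- with_seed(seed, {
    perms <- replicate(n_perm, sample.int(n))
    colSums(zs * matrix(zi[perms], nrow = n)) / (n - 1)
  })
  p <- (1 + sum(null_values >= observed_r)) / (1 + n_perm)
  structure(list(observed_r = observed_r, permuted_p = p,
                 null_values = null_values, n_perm = n_perm, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test (one-sided, positive): R = %.3f, p = %.4g (%d permutations, seed %d)\n",
              x$observed_r, x$permuted_p, x$n_perm, x$seed))
  invisible(x)
}

## JSON-ready summary of a permutation test
permutation_report <- function(x) {
  list(observed_r = x$observed_r, permuted_p = x$permuted_p,
       n_perm = x$n_perm, seed = x$seed)
}
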