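## shared fixtures: everything is built in code at test time

## small axis-aligned grid helpers
iso_affine <- function(spacing = 1, origin = c(0, 0, 0)) {
  a <- diag(4); a[1:3, 1:3] <- diag(rep(spacing, 3)); a[1:3, 4] <- origin
  a
}

## binary mask volume from voxel index ranges (1-based)
mask_vol <- function(shape, ix, iy, iz, affine = iso_affine()) {
  a <- array(0, shape); a[ix, iy, iz] <- 1
  image_volume(a, affine)
}

## random micro-cohort of blob masks on a small grid, guaranteed overlap
## (a common core voxel region so some voxels pass the coverage gate)
micro_cohort <- function(n = 10, shape = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  vols <- lapply(seq_len(n), function(i) {
    a <- array(0, shape)
    a[3:5, 3:5, 3:5] <- 1  # shared core
    ## patient-specific random voxels
    extra <- sample(prod(shape), 40)
    a[extra] <- 1
    image_volume(a, iso_affine())
  })
  list(volumes = vols, improvements = rnorm(n, 25, 30))
}

## brute-force T-model recomputation: per-voxel loop over covering sets
brute_tmodel <- function(volumes, improvements, min_coverage = 0.2) {
  masks <- lapply(volumes, function(v) v$data)
  n <- length(masks)
  shape <- dim(masks[[1]])
  t_map <- array(NA_real_, shape)
  included <- array(0, shape)
  for (v in seq_len(prod(shape))) {
    covering <- which(vapply(masks, function(m) m[v] == 1, logical(1)))
    if (length(covering) > min_coverage * n && length(covering) >= 2) {
      w <- improvements[covering]
      if (sd(w) > 0) {
        t_map[v] <- mean(w) / (sd(w) / sqrt(length(w)))
        included[v] <- 1
      } else {
        t_map[v] <- if (mean(w) == 0) 0 else sign(mean(w)) * 1e6
        included[v] <- 1
      }
    }
  }
  list(t_map = t_map, included = included)
}

## brute-force R-map recomputation: per-voxel loop with stats::cor
brute_rmap <- function(fingerprints, improvements) {
  Z <- sapply(fingerprints, function(f) as.numeric(f$zmap$data))
  apply(Z, 1, function(z) {
    if (anyNA(z) || sd(z) == 0) NA_real_ else cor(z, improvements)
  })
}

## motion-trace builders for QC tests
motion_still <- function(n) matrix(0, n, 6)
## trace with given per-frame FD values, purely translational in x
motion_with_fd <- function(fd_steps) {
  n <- length(fd_steps) + 1
  m <- matrix(0, n, 6)
  m[, 1] <- cumsum(c(0, fd_steps))
  m
}

## brute-force finite-difference Laplace oracle: single Dirichlet node held
## at V0 at the grid centre, zero on the boundary, Jacobi iteration; returns
## the potential array. The discrete point source has effective radius
## h / (4 * pi * G0) with G0 = 0.252731098 the simple-cubic lattice Green's
## function at the origin.
fd_laplace_point_source <- function(n = 41, V0 = 3, sweeps = 3000) {
  V <- array(0, c(n, n, n))
  c0 <- (n + 1) / 2
  i <- 2:(n - 1)
  for (s in seq_len(sweeps)) {
    V[i, i, i] <- (V[i - 1, i, i] + V[i + 1, i, i] + V[i, i - 1, i] +
                   V[i, i + 1, i] + V[i, i, i - 1] + V[i, i, i + 1]) / 6
    V[c0, c0, c0] <- V0
  }
  V
}
fd_lattice_radius <- function(h) h / (4 * pi * 0.252731098)

## |grad V| by 4th-order central differences, valid 2 voxels from the edge
fd_gradient_magnitude <- function(V, h) {
  n <- dim(V)[1]
  idx <- as.matrix(expand.grid(i = 3:(n - 2), j = 3:(n - 2), k = 3:(n - 2)))
  comp <- function(a) {
    sh <- function(s) V[cbind(idx[, 1] + s * a[1], idx[, 2] + s * a[2],
                              idx[, 3] + s * a[3])]
    (-sh(2) + 8 * sh(1) - 8 * sh(-1) + sh(-2)) / (12 * h)
  }
  list(idx = idx,
       mag = sqrt(comp(c(1, 0, 0))^2 + comp(c(0, 1, 0))^2 +
                  comp(c(0, 0, 1))^2))
}
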