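test_that("framewise displacement follows the translation + 50 mm rotation rule", {
  ## single 0.6 mm jump in x
  m <- motion_still(5); m[3:5, 1] <- 0.6
  expect_equal(compute_fd(m), c(0, 0, 0.6, 0, 0))
  ## no motion at all
  expect_true(all(compute_fd(motion_still(10)) == 0))
  ## pure rotation step of 0.01 rad -> 50 mm * 0.01 = 0.5 mm
  m <- motion_still(4); m[2:4, 5] <- 0.01
  expect_equal(compute_fd(m), c(0, 0.5, 0, 0))
  expect_error(compute_fd(matrix(0, 3, 5)), "6 columns")
})

test_that("QC boundaries are read strictly, retaining edge cases", {
  ## FD exactly 0.5 in every volume -> never above threshold -> retained
  s_at_fd <- list(motion = motion_with_fd(rep(0.5, 20)), subject_id = "a")
  ## FD above threshold in exactly half the volumes -> retained
  steps <- rep(0, 19); steps[1:10] <- 0.6
  s_half <- list(motion = motion_with_fd(steps), subject_id = "b")
  ## clear violator: FD 0.6 in all but the first volume
  s_bad <- list(motion = motion_with_fd(rep(0.6, 19)), subject_id = "c")
  qc <- qc_filter(list(s_at_fd, s_half, s_bad))
  expect_equal(qc$summary$excluded, c(FALSE, FALSE, TRUE))
  expect_equal(length(qc$retained), 2)
})

test_that("107 subjects with 7 constructed violators leave 100 retained", {
  subjects <- lapply(1:107, function(i) {
    steps <- if (i <= 7) rep(0.8, 39) else rep(0.05, 39)
    list(motion = motion_with_fd(steps), subject_id = sprintf("s%03d", i))
  })
  qc <- qc_filter(subjects)
  expect_equal(length(qc$retained), 100)
  expect_equal(length(qc$excluded), 7)
})

test_that("motion regression removes motion-spanned signal and keeps orthogonal signal", {
  set.seed(31)
  nt <- 60
  motion <- matrix(rnorm(nt * 6, sd = 0.1), nt, 6)
  ## voxel 1: pure linear combination of motion parameters
  v1 <- motion %*% c(2, -1, 0.5, 3, 1, -2)
  ## voxel 2: signal orthogonalized against intercept, trend and motion
  raw <- sin(seq_len(nt) / 3) + rnorm(nt, sd = 0.1)
  X <- cbind(1, scale(seq_len(nt)), motion)
  v2 <- raw - X %*% solve(crossprod(X), crossprod(X, raw))
  bold <- time_series_image(
    array(rbind(as.numeric(v1), as.numeric(v2)), c(2, 1, 1, nt)),
    iso_affine(1), tr = 2)
  out <- regress_motion(bold, motion)
  r1 <- out$data[1, 1, 1, ]
  expect_lt(var(r1), 1e-10 * max(var(as.numeric(v1)), 1e-8))
  r2 <- out$data[2, 1, 1, ]
  expect_gt(cor(r2, as.numeric(v2)), 0.999)
  ## zero motion: only intercept and trend removed, with a warning about
  ## the collinear all-zero columns
  trend <- 5 + 0.2 * seq_len(nt)
  bold2 <- time_series_image(array(trend, c(1, 1, 1, nt)), iso_affine(1), 2)
  expect_warning(out2 <- regress_motion(bold2, motion_still(nt)),
                 "collinear")
  expect_lt(var(out2$data[1, 1, 1, ]), 1e-20)
})

test_that("smoothing preserves constants and total mass", {
  vol <- image_volume(array(2.5, c(12, 12, 12)), iso_affine(2))
  sm <- smooth_spatial(vol, 6)
  expect_equal(sm$data, vol$data, tolerance = 1e-9)
  ## impulse away from boundaries keeps its total sum
  a <- array(0, c(21, 21, 21)); a[11, 11, 11] <- 1
  sm2 <- smooth_spatial(image_volume(a, iso_affine(2)), 6)
  expect_equal(sum(sm2$data), 1, tolerance = 1e-3)
  expect_error(smooth_spatial(vol, 0), "positive")
})

test_that("smoothing a 4-D series equals smoothing each volume", {
  set.seed(5)
  arr <- array(rnorm(6 * 6 * 6 * 3), c(6, 6, 6, 3))
  ts <- time_series_image(arr, iso_affine(2), tr = 2)
  sm <- smooth_spatial(ts, 6)
  one <- smooth_spatial(image_volume(arr[, , , 2], iso_affine(2)), 6)
  expect_equal(sm$data[, , , 2], one$data, tolerance = 1e-12)
})

test_that("band-pass filtering removes DC and keeps mid-passband amplitude", {
  nt <- 600; tr <- 2
  tt <- (seq_len(nt) - 1) * tr
  dc <- rep(7, nt)
  mid <- sin(2 * pi * 0.04 * tt)
  bold <- time_series_image(array(rbind(dc, mid), c(2, 1, 1, nt)),
                            iso_affine(1), tr = tr)
  out <- temporal_filter(bold)
  ## DC course: all fluctuation removed (mean re-added)
  expect_lt(var(out$data[1, 1, 1, ]), 1e-10)
  expect_equal(mean(out$data[1, 1, 1, ]), 7, tolerance = 1e-6)
  ## 0.04 Hz sits in the passband: amplitude kept above 0.9
  y <- out$data[2, 1, 1, 100:500]
  expect_gt(max(abs(y)), 0.9)
  ## invalid cutoffs
  expect_error(temporal_filter(bold, 0.08, 0.01), "low_cut")
  expect_error(temporal_filter(bold, 0.01, 0.3), "Nyquist")
})

test_that("the single-pass filter response is -3 dB at the printed cutoff", {
  bf <- bandpass_coefficients(0.01, 0.08, tr = 2)
  nt <- 1200; tt <- (seq_len(nt) - 1) * 2
  x <- sin(2 * pi * 0.08 * tt)
  y <- as.numeric(signal::filter(bf, x))
  ratio <- max(abs(y[400:nt])) / max(abs(x[400:nt]))
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.02)
})

test_that("nuisance regression removes tissue-mean signal, keeps orthogonal signal", {
  set.seed(41)
  nt <- 50
  shape <- c(4, 1, 1)
  csf_tc <- as.numeric(scale(cumsum(rnorm(nt))))
  wm_tc <- as.numeric(scale(cumsum(rnorm(nt))))
  other <- rnorm(nt)
  ## voxel1 = csf course; voxel2 = csf; voxel3 = wm; voxel4 = other signal
  V <- rbind(csf_tc, csf_tc, wm_tc, other)
  bold <- time_series_image(array(V, c(shape, nt)), iso_affine(1), tr = 2)
  csf_mask <- mask_vol(shape, 1:2, 1, 1)
  wm_mask <- mask_vol(shape, 3, 1, 1)
  out <- nuisance_regress(bold, csf_mask, wm_mask, global_signal = FALSE)
  expect_lt(var(out$data[1, 1, 1, ]), 1e-20)
  expect_lt(var(out$data[3, 1, 1, ]), 1e-20)
  ## orthogonal voxel barely changes
  X <- cbind(1, csf_tc, wm_tc)
  v4 <- other - X %*% solve(crossprod(X), crossprod(X, other))
  bold$data[4, 1, 1, ] <- v4
  out2 <- nuisance_regress(bold, csf_mask, wm_mask, global_signal = FALSE)
  expect_gt(cor(out2$data[4, 1, 1, ], as.numeric(v4)), 0.999)
  ## global signal regression removes the whole-brain mean course
  gbold <- time_series_image(array(rep(csf_tc, each = 4), c(shape, nt)),
                             iso_affine(1), tr = 2)
  ## identical CSF/WM/global courses: collinear columns must be dropped
  ## with a warning, and the shared course still removed
  expect_warning(
    gout <- nuisance_regress(gbold, csf_mask, wm_mask, global_signal = TRUE),
    "collinear")
  expect_lt(var(gout$data[4, 1, 1, ]), 1e-20)
  expect_error(nuisance_regress(bold, mask_vol(shape, 1, 1, 1) |>
                                  (\(m) {m$data[] <- 0; m})(), wm_mask),
               "empty")
})

test_that("the connectome matrix is exactly invertible and excludes masked voxels", {
  set.seed(51)
  shape <- c(5, 4, 3)
  nt <- 20
  arr <- array(rnorm(prod(shape) * nt), c(shape, nt))
  bold <- time_series_image(arr, iso_affine(2), tr = 2)
  mask <- image_volume(array(rbinom(prod(shape), 1, 0.5), shape),
                       iso_affine(2))
  mask$data[1, 1, 1] <- 0
  cm <- build_matrix(bold, mask)
  expect_equal(dim(cm$values), c(sum(mask$data), nt))
  ## round trip matrix -> volume -> matrix is exact
  back <- build_matrix(matrix_to_volume(cm), mask)
  expect_identical(back$values, cm$values)
  ## masked-out voxel values never appear in any row
  arr[1, 1, 1, ] <- 1e9
  cm2 <- build_matrix(time_series_image(arr, iso_affine(2), tr = 2), mask)
  expect_true(all(cm2$values < 1e8))
  ## raster order: x fastest
  expect_true(all(diff(cm$linear_index) > 0))
  expect_error(build_matrix(bold, image_volume(array(0, shape),
                                               iso_affine(2))), "empty")
})

test_that("full preprocessing keeps planted networks separable", {
  spec <- connectome_spec(n_subjects = 6, n_violators = 0, n_volumes = 60)
  nets <- dbsmap:::planted_networks(spec)
  p1 <- which(nets[[1]]$data > 0.7)
  p2 <- which(nets[[2]]$data > 0.7)
  within <- between <- numeric(0)
  for (i in 0:5) {
    cm <- preprocess_subject(simulate_connectome_subject(spec, i))
    r1 <- which(cm$linear_index %in% p1)[1:4]
    r2 <- which(cm$linear_index %in% p2)[1:4]
    C11 <- cor(t(cm$values[r1, ])); C12 <- cor(t(cm$values[r1, ]),
                                               t(cm$values[r2, ]))
    within <- c(within, mean(C11[upper.tri(C11)]))
    between <- c(between, mean(C12))
  }
  expect_gt(mean(within) - mean(between), 0.2)
})
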