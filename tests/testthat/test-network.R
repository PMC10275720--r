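## small synthetic connectome matrix: known time courses on a tiny grid
tiny_cmat <- function(V, shape = c(4, 3, 2), tr = 2, seed = 1) {
  nv <- prod(shape)
  stopifnot(nrow(V) == nv)
  bold <- time_series_image(array(V, c(shape, ncol(V))), iso_affine(2),
                            tr = tr)
  mask <- image_volume(array(1, shape), iso_affine(2))
  build_matrix(bold, mask)
}

test_that("a single-voxel seed correlates perfectly with itself", {
  set.seed(61)
  V <- matrix(rnorm(24 * 30), 24, 30)
  cm <- tiny_cmat(V)
  seed <- mask_vol(c(4, 3, 2), 2, 2, 1, affine = iso_affine(2))
  fp <- seed_fingerprint(seed, cm)
  expect_equal(fp$data[2, 2, 1], 1)
  expect_true(all(abs(fp$data) <= 1, na.rm = TRUE))
})

test_that("constant voxels get r = 0 and are flagged, not undefined", {
  set.seed(62)
  V <- matrix(rnorm(24 * 30), 24, 30)
  V[5, ] <- 3  # constant voxel
  cm <- tiny_cmat(V)
  seed <- mask_vol(c(4, 3, 2), 1, 1, 1, affine = iso_affine(2))
  fp <- seed_fingerprint(seed, cm)
  expect_equal(fp$data[5], 0)  # linear index of the constant voxel
  expect_equal(attr(fp, "n_constant"), 1L)
})

test_that("seeds sharing a planted network light up that network", {
  spec <- connectome_spec(n_subjects = 4, n_violators = 0, n_volumes = 60)
  nets <- dbsmap:::planted_networks(spec)
  net1 <- which(nets[[1]]$data > 0.6)
  other <- which(nets[[1]]$data < 0.05 & nets[[2]]$data < 0.05 &
                   dbsmap:::connectome_masks(spec)$gray$data == 1)
  rs_in <- rs_out <- numeric(0)
  seed_arr <- array(0, spec$shape); seed_arr[net1[1:3]] <- 1
  seed <- image_volume(seed_arr, spec$affine)
  for (i in 0:3) {
    cm <- preprocess_subject(simulate_connectome_subject(spec, i))
    fp <- seed_fingerprint(seed, cm)
    rs_in <- c(rs_in, mean(fp$data[net1], na.rm = TRUE))
    rs_out <- c(rs_out, mean(fp$data[other], na.rm = TRUE))
  }
  expect_gt(mean(rs_in), mean(rs_out))
})

test_that("group fingerprints average first and Fisher-Z second", {
  shape <- c(3, 2, 1)
  mk <- function(val) image_volume(array(val, shape), iso_affine(2))
  z0 <- group_fingerprint(list(mk(0), mk(0)))
  expect_true(all(z0$zmap$data == 0))
  z5 <- group_fingerprint(list(mk(0.5), mk(0.5)))
  expect_equal(z5$zmap$data[1, 1, 1], 0.5493, tolerance = 1e-4)
  ## mean-then-transform: {0.3, 0.7} -> atanh(0.5), not mean(atanh)
  zm <- group_fingerprint(list(mk(0.3), mk(0.7)))
  expect_equal(zm$zmap$data[1, 1, 1], atanh(0.5), tolerance = 1e-12)
  za <- group_fingerprint(list(mk(0.3), mk(0.7)), order = "z-then-average")
  expect_equal(za$zmap$data[1, 1, 1], mean(atanh(c(0.3, 0.7))),
               tolerance = 1e-12)
  expect_gt(za$zmap$data[1, 1, 1], zm$zmap$data[1, 1, 1])
})

## fingerprint builder from a voxels-long vector of z values
fp_from <- function(z, shape, id = NA) {
  structure(list(zmap = image_volume(array(z, shape), iso_affine(2)),
                 patient_id = id, n_subjects_used = 1L),
            class = "fingerprint")
}

test_that("the R-map recovers exact linear relations per voxel", {
  shape <- c(2, 2, 1)
  ## voxel 1: z proportional to improvement; voxel 2: reversed; voxel 3:
  ## constant across patients; voxel 4: noise
  imp <- c(10, 20, 30, 40, 50)
  set.seed(63)
  Z <- rbind(imp / 10, rev(imp) / 5, rep(2, 5), rnorm(5))
  fps <- lapply(1:5, function(i) fp_from(Z[, i], shape))
  fit <- rmap_fit(fps, imp)
  expect_equal(fit$rmap$data[1, 1, 1], 1)
  expect_equal(fit$rmap$data[2, 1, 1], -1)
  expect_equal(fit$included$data[1, 2, 1], 0)  # constant voxel excluded
  expect_true(is.na(fit$rmap$data[1, 2, 1]))
  expect_error(rmap_fit(fps, rep(1, 5)), "constant")
  expect_error(rmap_fit(fps[1:4], imp[1:4]), "at least 5")
})

test_that("the R-map matches brute-force per-voxel recomputation", {
  shape <- c(5, 5, 4)  # 100 voxels
  for (seed in 1:3) {
    set.seed(seed)
    Z <- matrix(rnorm(100 * 5), 100, 5)
    imp <- rnorm(5, 25, 30)
    fps <- lapply(1:5, function(i) fp_from(Z[, i], shape))
    fit <- rmap_fit(fps, imp)
    ref <- brute_rmap(fps, imp)
    expect_lt(max(abs(as.numeric(fit$rmap$data) - ref)), 1e-10)
  }
})

test_that("spatial similarity detects proportional and reversed fingerprints", {
  shape <- c(5, 5, 4)
  set.seed(64)
  base <- rnorm(100)
  Z <- cbind(base + rnorm(100, sd = 0.1), base + rnorm(100, sd = 0.1),
             base + rnorm(100, sd = 0.1), rnorm(100), rnorm(100))
  imp <- c(30, 25, 28, 5, 2)
  fps <- lapply(1:5, function(i) fp_from(Z[, i], shape))
  fit <- rmap_fit(fps, imp)
  prop <- fp_from(2 * as.numeric(fit$rmap$data) + 1, shape)
  expect_equal(spatial_similarity(prop, fit), 1)
  neg <- fp_from(-as.numeric(fit$rmap$data), shape)
  expect_equal(spatial_similarity(neg, fit), -1)
})

test_that("independent random maps have near-zero similarity on average", {
  shape <- c(25, 20, 20)  # 10^4 voxels
  sims <- vapply(1:50, function(s) {
    set.seed(s)
    Z <- matrix(rnorm(prod(shape) * 5), ncol = 5)
    fps <- lapply(1:5, function(i) fp_from(Z[, i], shape))
    fit <- rmap_fit(fps, c(12, 30, 7, 22, 18))
    probe <- fp_from(rnorm(prod(shape)), shape)
    spatial_similarity(probe, fit)
  }, numeric(1))
  expect_lt(mean(abs(sims)), 0.05)
})

test_that("network validation is deterministic and returns the model", {
  shape <- c(4, 4, 3)
  set.seed(65)
  Z <- matrix(rnorm(48 * 6), 48, 6)
  imp <- rnorm(6, 20, 10)
  fps <- lapply(1:6, function(i) fp_from(Z[, i], shape))
  a <- validate_network_model(fps, imp, n_perm = 100, seed = 9)
  b <- validate_network_model(fps, imp, n_perm = 100, seed = 9)
  expect_identical(a$permuted_p, b$permuted_p)
  expect_identical(a$observed_r, b$observed_r)
  expect_s3_class(attr(a, "model"), "rmap")
})

test_that("leave-one-out similarities are out-of-sample and finite", {
  shape <- c(5, 5, 4)
  set.seed(66)
  base <- rnorm(100)
  Z <- sapply(1:6, function(i) base * i / 3 + rnorm(100, sd = 0.5))
  imp <- c(5, 15, 25, 35, 45, 55)
  fps <- lapply(1:6, function(i) fp_from(Z[, i], shape))
  loo <- loo_similarities(fps, imp)
  expect_length(loo, 6)
  expect_true(all(is.finite(loo)))
  ## in-sample similarity of a patient differs from their loo similarity
  fit <- rmap_fit(fps, imp)
  expect_false(isTRUE(all.equal(predict(fit, fps), loo)))
  expect_error(loo_similarities(fps[1:5], imp[1:5]), "at least 6")
})
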