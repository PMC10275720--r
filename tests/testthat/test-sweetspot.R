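test_that("percentage improvement follows the score-difference ratio", {
  expect_equal(percent_improvement(100, 50), 50)
  expect_equal(percent_improvement(80, 80), 0)
  expect_equal(percent_improvement(80, 100), -25)
  expect_error(percent_improvement(0, 10), "positive")
})

test_that("the coverage gate is strict: 4 of 20 is out, 5 of 20 is in", {
  shape <- c(4, 4, 4)
  ## voxel [1,1,1] covered by 4 volumes, voxel [2,1,1] by 5; a common
  ## core at [3:4, 3:4, 3:4] keeps every cohort volume non-degenerate
  vols <- lapply(1:20, function(i) {
    a <- array(0, shape)
    a[3:4, 3:4, 3:4] <- 1
    if (i <= 4) a[1, 1, 1] <- 1
    if (i <= 5) a[2, 1, 1] <- 1
    image_volume(a, diag(4))
  })
  set.seed(2)
  fit <- sweetspot_fit(vols, rnorm(20, 25, 30), min_coverage = 0.2)
  expect_equal(fit$included$data[1, 1, 1], 0)  # exactly 20% -> excluded
  expect_equal(fit$included$data[2, 1, 1], 1)  # > 20% -> included
  expect_true(is.na(fit$t_map$data[1, 1, 1]))
  expect_equal(fit$coverage$data[1, 1, 1], 4)
  expect_equal(fit$coverage$data[2, 1, 1], 5)
})

test_that("an included voxel's t equals the one-sample t of its coverers", {
  shape <- c(3, 3, 3)
  imps <- c(50, 30, 40, 60, 20, 999, 999, 999, 999, 999)
  ## voxel [1,1,1] covered by exactly patients 1..5; core by everyone
  vols <- lapply(1:10, function(i) {
    a <- array(0, shape)
    a[3, 3, ] <- 1
    if (i <= 5) a[1, 1, 1] <- 1
    image_volume(a, diag(4))
  })
  fit <- sweetspot_fit(vols, imps, min_coverage = 0.2)
  expect_equal(fit$t_map$data[1, 1, 1], 5.657, tolerance = 1e-3)
})

test_that("all-zero improvements give t = 0 at every included voxel", {
  mc <- micro_cohort(n = 8, seed = 3)
  fit <- sweetspot_fit(mc$volumes, rep(0, 8))
  inc <- fit$included$data == 1
  expect_true(any(inc))
  expect_true(all(fit$t_map$data[inc] == 0))
})

test_that("the T-model matches brute-force per-voxel recomputation", {
  for (seed in 1:3) {
    mc <- micro_cohort(n = 10, seed = seed)
    fit <- sweetspot_fit(mc$volumes, mc$improvements)
    ref <- brute_tmodel(mc$volumes, mc$improvements)
    expect_equal(fit$included$data, ref$included, ignore_attr = TRUE)
    sel <- ref$included == 1
    expect_lt(max(abs(fit$t_map$data[sel] - ref$t_map[sel])), 1e-10)
  }
})

test_that("raising the coverage fraction never adds included voxels", {
  mc <- micro_cohort(n = 10, seed = 11)
  fracs <- c(0.1, 0.2, 0.3, 0.5, 0.7)
  incs <- lapply(fracs, function(f)
    suppressWarnings(sweetspot_fit(mc$volumes, mc$improvements,
                                   min_coverage = f))$included$data)
  for (k in seq_len(length(fracs) - 1))
    expect_true(all(incs[[k + 1]] <= incs[[k]]))
})

test_that("overlap scores sum t over included voxels only", {
  shape <- c(3, 3, 3)
  vols <- lapply(1:5, function(i) {
    a <- array(0, shape); a[1:2, 1, 1] <- 1
    image_volume(a, diag(4))
  })
  fit <- suppressWarnings(sweetspot_fit(vols, c(10, 20, 30, 25, 15),
                                        min_coverage = 0.2))
  ## force a known t-field: two included voxels with t = 2 and 3
  fit$t_map$data[] <- NA
  fit$t_map$data[1, 1, 1] <- 2; fit$t_map$data[2, 1, 1] <- 3
  fit$included$data[] <- 0
  fit$included$data[1:2, 1, 1] <- 1
  probe <- mask_vol(shape, 1:2, 1, 1)
  expect_equal(overlap_score(fit, probe), 5)
  ## a volume overlapping only excluded voxels scores 0
  off <- mask_vol(shape, 3, 3, 3)
  expect_equal(overlap_score(fit, off), 0)
  ## an empty volume scores 0
  empty <- image_volume(array(0, shape), diag(4))
  expect_equal(overlap_score(fit, empty), 0)
  ## predict() vectorizes overlap_score
  expect_equal(predict(fit, list(probe, off, empty)), c(5, 0, 0))
})

test_that("the centre of gravity is the t-weighted centroid in world mm", {
  shape <- c(5, 1, 1)
  vols <- lapply(1:5, function(i) mask_vol(shape, 1:5, 1, 1))
  fit <- sweetspot_fit(vols, c(10, 20, 30, 25, 15), min_coverage = 0.2)
  ## single positive voxel
  fit$t_map$data[] <- NA; fit$included$data[] <- 0
  fit$t_map$data[2, 1, 1] <- 4; fit$included$data[2, 1, 1] <- 1
  expect_equal(unname(sweetspot_cog(fit)), c(1, 0, 0))
  ## two voxels with equal t -> midpoint
  fit$t_map$data[4, 1, 1] <- 4; fit$included$data[4, 1, 1] <- 1
  expect_equal(unname(sweetspot_cog(fit)), c(2, 0, 0))
  ## weights 1 and 3 at world x = 0 and 4 -> weighted mean 3
  fit$t_map$data[] <- NA; fit$included$data[] <- 0
  fit$t_map$data[1, 1, 1] <- 1; fit$t_map$data[5, 1, 1] <- 3
  fit$included$data[c(1, 5), 1, 1] <- 1
  expect_equal(unname(sweetspot_cog(fit))[1], 3)
  ## thresholding away all voxels is an error
  expect_error(sweetspot_cog(fit, t_threshold = 10), "no included voxel")
})

test_that("validation is deterministic under a fixed seed", {
  mc <- micro_cohort(n = 10, seed = 21)
  fit <- sweetspot_fit(mc$volumes, mc$improvements)
  a <- validate_sweetspot(fit, mc$volumes, mc$improvements,
                          n_perm = 100, seed = 5)
  b <- validate_sweetspot(fit, mc$volumes, mc$improvements,
                          n_perm = 100, seed = 5)
  expect_identical(a$permuted_p, b$permuted_p)
  expect_identical(a$null_values, b$null_values)
})

test_that("grid mismatches and short cohorts are rejected", {
  mc <- micro_cohort(n = 5, seed = 2)
  expect_error(sweetspot_fit(mc$volumes[1:4], rnorm(4)), "at least 5")
  bad <- mc$volumes
  bad[[2]] <- image_volume(array(0, c(4, 4, 4)), diag(4))
  expect_error(sweetspot_fit(bad, rnorm(5)), "different grids")
  fit <- sweetspot_fit(mc$volumes, rnorm(5))
  expect_error(overlap_score(fit, image_volume(array(0, c(4, 4, 4)), diag(4))),
               "not on the model grid")
})
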