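test_that("erosion matches the unit-ball definition and the per-voxel oracle", {
  cube <- cube_mask(c(9, 9, 9), c(3, 3, 3), c(7, 7, 7))
  eroded <- erode_mask(cube, 100)
  expect_equal(sum(eroded$values), 27)
  expect_true(all(eroded$values[4:6, 4:6, 4:6]))

  empty <- mask_from(array(FALSE, dim = c(4, 4, 4)))
  expect_equal(sum(erode_mask(empty, 300)$values), 0)

  m <- random_mask(c(7, 7, 7), p = 0.6)
  expect_identical(erode_mask(m, 0)$values, m$values)

  set.seed(11)
  for (s in 1:3) {
    m <- random_mask(c(7, 6, 8), p = 0.7)
    expect_identical(erode_mask(m, 100)$values, erode_oracle(m, 100)$values)
  }
  # anisotropic voxels honored per axis
  aniso <- binary_mask(cube_mask(c(9, 9, 9), c(3, 3, 3), c(7, 7, 7))$values,
                       c(100, 200, 100))
  expect_identical(erode_mask(aniso, 100)$values,
                   erode_oracle(aniso, 100)$values)
  expect_error(erode_mask(cube, -1), "nonnegative")
})

test_that("repeated erosion composes over distances on isotropic grids", {
  set.seed(3)
  m <- cube_mask(c(12, 12, 12), c(2, 2, 2), c(11, 11, 11))
  once <- erode_mask(m, 200)
  twice <- erode_mask(erode_mask(m, 100), 100)
  expect_identical(once$values, twice$values)
})

test_that("coverage_fraction follows set algebra and rejects empty targets", {
  a <- cube_mask(c(6, 6, 6), c(1, 1, 1), c(2, 2, 2))  # 8 voxels
  expect_equal(coverage_fraction(a, a), 1)
  b <- cube_mask(c(6, 6, 6), c(4, 4, 4), c(6, 6, 6))
  expect_equal(coverage_fraction(a, b), 0)
  probe <- cube_mask(c(6, 6, 6), c(1, 1, 1), c(2, 1, 1))  # overlaps 2 of 8
  expect_equal(coverage_fraction(a, probe), 0.25)
  empty <- mask_from(array(FALSE, dim = c(6, 6, 6)))
  expect_error(coverage_fraction(empty, a), "empty target")
  # monotone nondecreasing in the probe under set inclusion
  set.seed(5)
  t <- random_mask(c(6, 6, 6), 0.5)
  p1 <- random_mask(c(6, 6, 6), 0.3)
  p2 <- binary_mask(p1$values | random_mask(c(6, 6, 6), 0.3)$values, 100)
  expect_gte(coverage_fraction(t, p2), coverage_fraction(t, p1))
})

test_that("subtract_mask zeroes exactly the excluded voxels", {
  v <- array(0, dim = c(4, 4, 4))
  v[2, 2, 2] <- 0.7
  v[3, 3, 3] <- 0.4
  vol <- projection_volume(v, 100)
  ex <- array(FALSE, dim = c(4, 4, 4))
  ex[2, 2, 2] <- TRUE
  out <- subtract_mask(vol, mask_from(ex))
  expect_equal(out$values[2, 2, 2], 0)
  expect_equal(out$values[3, 3, 3], 0.4)
  all_ex <- mask_from(array(TRUE, dim = c(4, 4, 4)))
  expect_true(all(subtract_mask(vol, all_ex)$values == 0))
  no_ex <- mask_from(array(FALSE, dim = c(4, 4, 4)))
  expect_identical(subtract_mask(vol, no_ex)$values, vol$values)
})

test_that("downsample_fraction mean-pools and conserves mass exactly", {
  v <- array(FALSE, dim = c(2, 2, 2))
  v[1, 1, 1] <- v[1, 1, 2] <- v[1, 2, 1] <- v[2, 1, 1] <- TRUE  # 4 of 8
  expect_equal(downsample_fraction(mask_from(v), 200)$values[1, 1, 1], 0.5)

  allt <- mask_from(array(TRUE, dim = c(4, 4, 4)))
  expect_true(all(downsample_fraction(allt, 200)$values == 1))

  set.seed(7)
  m <- random_mask(c(6, 8, 4), p = 0.4)
  coarse <- downsample_fraction(m, 200)
  # independent mean-pool per coarse voxel
  for (i in 1:3) for (j in 1:4) for (k in 1:2) {
    block <- m$values[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                      (2 * k - 1):(2 * k)]
    expect_equal(coarse$values[i, j, k], mean(block))
  }
  expect_equal(sum(coarse$values) * 8, sum(m$values))
  expect_error(downsample_fraction(m, 150), "integer multiple")
})

test_that("connected components agree with an igraph flood-fill oracle", {
  two <- array(FALSE, dim = c(8, 8, 8))
  two[1:2, 1:2, 1:2] <- TRUE
  two[6:8, 6:8, 6:8] <- TRUE
  expect_equal(connected_components(mask_from(two))$n_components, 2)
  expect_equal(
    connected_components(mask_from(array(FALSE, c(4, 4, 4))))$n_components, 0)

  set.seed(21)
  for (s in 1:20) {
    m <- random_mask(c(6, 6, 6), p = stats::runif(1, 0.1, 0.5))
    expect_equal(connected_components(m)$n_components, components_oracle(m))
  }
})

test_that("upsample then downsample round-trips a mask", {
  set.seed(9)
  m <- random_mask(c(4, 5, 6), p = 0.5)
  up <- upsample_mask(m, 2)
  expect_equal(dim(up$values), dim(m$values) * 2)
  back <- downsample_fraction(up, 100)
  expect_identical(back$values > 0.5, m$values)
})

test_that("volume IO round-trips through NIfTI and TIFF", {
  set.seed(13)
  vol <- projection_volume(array(stats::runif(60), dim = c(3, 4, 5)), 100)
  f <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, f)
  back <- read_volume_nifti(f, "volume")
  expect_equal(back$values, vol$values, tolerance = 1e-6)
  expect_equal(back$voxel_size_um, vol$voxel_size_um, tolerance = 1e-6)

  m <- random_mask(c(3, 4, 5))
  fm <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(m, fm)
  expect_identical(read_volume_nifti(fm, "mask")$values, m$values)

  ft <- tempfile(fileext = ".tif")
  write_volume_tiff(vol, ft)
  backt <- read_volume_tiff(ft)
  expect_equal(backt$values, vol$values, tolerance = 1e-6)
})

test_that("type constructors enforce their invariants", {
  expect_error(projection_volume(array(1.5, dim = c(2, 2, 2)), 100), "0, 1")
  expect_error(binary_mask(array(TRUE, dim = c(2, 2, 2)), -5), "positive")
  lab <- array(0L, dim = c(3, 3, 3))
  lab[1, 1, 1] <- 2L
  expect_error(atlas_partition(lab, c("1" = "a"), 100), "exactly match")
  full <- cube_mask(c(5, 5, 5), c(2, 2, 2), c(4, 4, 4))
  not_core <- cube_mask(c(5, 5, 5), c(1, 1, 1), c(2, 2, 2))
  expect_error(injection("x", "thalamic", full, not_core,
                         projection = full), "subset")
})
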