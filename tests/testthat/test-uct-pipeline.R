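test_that("gaussian kernel is unit-sum, matches direct construction, identity at support 0", {
  taps <- perfusim:::gaussian_taps(1.2, 1)
  k3 <- outer(outer(taps, taps), taps)
  expect_equal(sum(k3), 1, tolerance = 1e-12)
  expect_equal(k3, gauss_kernel3_oracle(1.2), tolerance = 1e-14)

  # unit impulse: centre tap equals the renormalized kernel centre weight
  arr <- array(0, c(9, 9, 9)); arr[5, 5, 5] <- 1
  v <- voxel_volume(arr, 36e-6)
  f <- gaussian_filter_vol(v, 1.2, 1)
  expect_equal(f$data[5, 5, 5], gauss_kernel3_oracle(1.2)[2, 2, 2],
               tolerance = 1e-14)
  expect_equal(f$data[4:6, 4:6, 4:6], gauss_kernel3_oracle(1.2),
               tolerance = 1e-14)

  # constant volume is preserved; support 0 is the identity
  cst <- voxel_volume(array(7.7, c(6, 6, 6)), 36e-6)
  expect_equal(gaussian_filter_vol(cst, 1.2, 1)$data, cst$data)
  expect_identical(gaussian_filter_vol(v, 1.2, 0)$data, arr)
  expect_error(gaussian_filter_vol(v, 1.2, 0.5), "integer")
})

test_that("filtering commutes with affine density rescaling of volume and threshold", {
  set.seed(42)
  arr <- array(stats::runif(8^3, 0, 300), c(8, 8, 8))
  v <- voxel_volume(arr, 36e-6)
  a <- 2.5
  v2 <- voxel_volume(a * arr, 36e-6)
  m1 <- segment(gaussian_filter_vol(v, 1.2, 1), 97.5)
  m2 <- segment(gaussian_filter_vol(v2, 1.2, 1), a * 97.5)
  expect_identical(m1$mask, m2$mask)
})

test_that("grey/density calibration maps 12.7% to 97.5 mg/cm^3", {
  expect_equal(grey_to_density(12.7), 97.5)
  expect_equal(grey_to_density(0), 0)
  expect_equal(grey_to_density(100), 767.7, tolerance = 1e-3)
  expect_equal(density_to_grey(grey_to_density(33)), 33, tolerance = 1e-12)
  expect_error(grey_to_density(101), "\\[0, 100\\]")
})

test_that("segmentation uses the >= convention and counts constructed blobs exactly", {
  arr <- array(50, c(12, 12, 12))
  v <- voxel_volume(arr, 36e-6)
  expect_equal(sum(segment(v)$mask), 0L)
  arr[3, 3, 3] <- 97.5
  expect_equal(sum(segment(voxel_volume(arr, 36e-6))$mask), 1L)
  # 1000-voxel blob at 200 in zero background
  arr2 <- array(0, c(20, 20, 20))
  arr2[1:10, 1:10, 1:10] <- 200
  expect_equal(sum(segment(voxel_volume(arr2, 36e-6))$mask), 1000L)
})

test_that("particle filtering is strict below 50 and keeps 50-voxel components", {
  d <- c(20, 20, 20)
  m49 <- array(FALSE, d); m49[1:7, 1:7, 1] <- TRUE; m49[1, 1, 1] <- FALSE
  m50 <- array(FALSE, d); m50[1:10, 1:5, 1] <- TRUE
  expect_equal(sum(filter_components(binary_mask(m49, 36e-6))$mask), 0L)
  expect_identical(filter_components(binary_mask(m50, 36e-6))$mask, m50)
})

test_that("corner-touching voxels are one component at 26- but not 6-connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_equal(max(label_components(m, 26L)), 1L)
  expect_equal(max(label_components(m, 6L)), 2L)
})

test_that("component labeling matches brute-force flood fill on random masks", {
  set.seed(11)
  for (conn in c(26L, 6L)) {
    for (rep in 1:10) {
      m <- array(stats::runif(16^3) < 0.15, c(16, 16, 16))
      expect_true(same_partition(label_components(m, conn),
                                 flood_fill_oracle(m, conn)))
    }
  }
})

test_that("filtering output is a subset of the input and BV is monotone", {
  set.seed(3)
  m <- array(stats::runif(24^3) < 0.1, c(24, 24, 24))
  bm <- binary_mask(m, 36e-6)
  f <- filter_components(bm, 10L)
  expect_true(all(m[f$mask]))
  tv <- binary_mask(array(TRUE, dim(m)), 36e-6)
  expect_lte(morphometry(f, tv)$BV_mm3, morphometry(bm, tv)$BV_mm3)
})

test_that("morphometry arithmetic and phantom fills are exact", {
  d <- c(30, 30, 10)
  tv <- binary_mask(array(TRUE, d), 36e-6)
  full <- binary_mask(array(TRUE, d), 36e-6)
  expect_equal(morphometry(full, tv)$BVTV_percent, 100)
  # 1000 voxels at 36 um -> 0.046656 mm^3
  m <- array(FALSE, d); m[seq_len(1000)] <- TRUE
  expect_equal(morphometry(binary_mask(m, 36e-6), tv)$BV_mm3, 0.046656,
               tolerance = 1e-12)
  # constructed 1.0% fill of a cylindrical TV region
  tvc <- scaffold_tv_region(c(60, 60, 20), 36e-6, radius = 1e-3, height = 0.5e-3)
  n_fill <- round(0.01 * sum(tvc$mask))
  mm <- array(FALSE, c(60, 60, 20))
  mm[which(tvc$mask)[seq_len(n_fill)]] <- TRUE
  got <- morphometry(binary_mask(mm, 36e-6), tvc)$BVTV_percent
  expect_equal(got, 1.0, tolerance = 100 / sum(tvc$mask))  # one-voxel quantum
  expect_error(morphometry(binary_mask(mm, 36e-6),
                           binary_mask(array(FALSE, c(60, 60, 20)), 36e-6)),
               "empty")
})

test_that("segmentation is idempotent on re-cast binary content", {
  set.seed(8)
  arr <- array(stats::runif(10^3, 0, 200), c(10, 10, 10))
  m1 <- segment(voxel_volume(arr, 36e-6), 97.5)
  recast <- voxel_volume(array(ifelse(m1$mask, 200, 0), dim(m1$mask)), 36e-6)
  m2 <- segment(recast, 97.5)
  expect_identical(m1$mask, m2$mask)
})

test_that("time-lapse morphometry is ordered, consistent, and validates input", {
  set.seed(5)
  mk_vol <- function(week, n_blobs) {
    arr <- array(0, c(24, 24, 24))
    arr[5:12, 5:12, 3:(2 + n_blobs)] <- 200
    voxel_volume(arr, 36e-6, week = week)
  }
  vols <- list(mk_vol(2L, 2), mk_vol(3L, 4), mk_vol(4L, 6))
  tv <- binary_mask(array(TRUE, c(24, 24, 24)), 36e-6)
  tab <- timelapse_bvtv(vols, tv)
  expect_equal(tab$week, c(2, 3, 4))
  expect_true(all(diff(tab$BVTV_percent) >= 0))
  # single week equals direct morphometry
  one <- timelapse_bvtv(vols[1], tv)
  direct <- morphometry(process_volume(vols[[1]]), tv)
  expect_equal(one$BV_mm3, direct$BV_mm3)
  expect_error(timelapse_bvtv(list(), tv), "empty")
  bad <- list(vols[[1]], voxel_volume(array(0, c(10, 10, 10)), 36e-6))
  expect_error(timelapse_bvtv(bad, tv), "inconsistent")
})
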