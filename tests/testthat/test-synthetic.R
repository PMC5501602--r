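# reduced-size phantom parameters used throughout (fast but non-trivial)
small_phantom <- function(seed = 1L)
  phantom_params(radius = 1.5e-3, height = 1.2e-3, voxel_size = 36e-6,
                 seed = seed)

test_that("phantom porosity lands within the target band and is seed-reproducible", {
  p1 <- gen_scaffold_phantom(small_phantom(seed = 4L))
  expect_lt(abs(p1$porosity - 0.55), 0.02)
  expect_equal(sum(p1$pores$mask & !p1$envelope$mask), 0L)
  p2 <- gen_scaffold_phantom(small_phantom(seed = 4L))
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$pores$mask, p2$pores$mask)
  p3 <- gen_scaffold_phantom(small_phantom(seed = 5L))
  expect_false(identical(p1$pores$mask, p3$pores$mask))
  # scaffold material is sub-threshold: invisible to segmentation
  expect_equal(sum(segment(p1$volume)$mask), 0L)
})

test_that("phantom parameter validation rejects degenerate inputs", {
  expect_error(phantom_params(porosity = 1.2), "porosity")
  expect_error(phantom_params(pore_diameter_range = c(4e-4, 3e-4)), "ordered")
  expect_error(gen_scaffold_phantom(small_phantom(), max_spheres = 2L),
               "unreachable")
})

test_that("mineralization series are nested, seeded, and respect the band link exactly", {
  ph <- gen_scaffold_phantom(small_phantom())
  d <- dim(ph$pores$mask)
  set.seed(99)
  tau <- array(stats::rlnorm(prod(d), log(2e-3), 1.5), d)
  ss <- structure(list(tau = tau, valid = array(TRUE, d),
                       voxel_size = 36e-6, origin = c(0, 0, 0)),
                  class = "voxel_field_sample")
  link <- mineralization_link(rate = 0.3, bonus = 0.2)
  ser <- gen_mineralization(ss, ph$pores, link, weeks = 2:5, seed = 7L)
  for (i in 2:4)
    expect_true(all(ser[[i]]$mask[ser[[i - 1]]$mask]))
  ser2 <- gen_mineralization(ss, ph$pores, link, weeks = 2:5, seed = 7L)
  expect_identical(ser[[4]]$mask, ser2[[4]]$mask)

  # rate 0 and bonus 0 -> nothing ever mineralizes
  none <- gen_mineralization(ss, ph$pores,
                             mineralization_link(rate = 0, bonus = 0),
                             weeks = 2:3, seed = 1L)
  expect_equal(sum(none[[2]]$mask), 0L)

  # band link, no noise, bonus 0, rate 1 -> exactly the in-band pore voxels
  exact <- gen_mineralization(ss, ph$pores,
                              mineralization_link(rate = 1, bonus = 0),
                              weeks = 2L, seed = 1L)[[1]]
  expected <- ph$pores$mask & tau >= 0.55e-3 & tau <= 24e-3
  expect_identical(exact$mask, expected)

  expect_error(gen_mineralization(ss, ph$pores, link, weeks = c(3, 3)),
               "strictly increasing")
})

test_that("uniform link mineralizes uniformly (static culture) with AUC ~ 0.5", {
  ph <- gen_scaffold_phantom(small_phantom())
  d <- dim(ph$pores$mask)
  set.seed(12)
  tau <- array(stats::rlnorm(prod(d), log(2e-3), 1), d)
  ss <- structure(list(tau = tau, valid = array(TRUE, d),
                       voxel_size = 36e-6, origin = c(0, 0, 0)),
                  class = "voxel_field_sample")
  ser <- gen_mineralization(ss, ph$pores,
                            mineralization_link(type = "uniform", rate = 0.3,
                                                bonus = 0),
                            weeks = 2L, seed = 3L)
  pd <- superimpose(ss, ser[[1]], ph$pores)
  expect_equal(roc_curve(pd)$auc, 0.5, tolerance = 0.02)
})

test_that("forward scan model inverts exactly without noise and blur", {
  ph <- gen_scaffold_phantom(small_phantom())
  ser <- gen_mineralization(NULL, ph$pores,
                            mineralization_link(type = "uniform", rate = 0.2,
                                                bonus = 0),
                            weeks = 2L, seed = 5L)
  scan0 <- scan_params(psf_sigma = 0, noise_sd = 0, mineral_density = 200)
  vol <- simulate_uct_scan(ser[[1]], scan0, scaffold_volume = ph$volume,
                           week = 2L, seed = 1L)
  expect_identical(segment(vol, 97.5)$mask, ser[[1]]$mask)
  # seeded reproducibility with noise
  scanN <- scan_params(psf_sigma = 0.8, noise_sd = 25)
  v1 <- simulate_uct_scan(ser[[1]], scanN, seed = 10L)
  v2 <- simulate_uct_scan(ser[[1]], scanN, seed = 10L)
  expect_identical(v1$data, v2$data)
  expect_error(scan_params(noise_sd = -1), ">= 0")
})

test_that("the processing chain recovers a 500-voxel blob under realistic noise", {
  d <- c(40, 40, 40)
  co <- expand.grid(x = 1:40, y = 1:40, z = 1:40)
  r2 <- (co$x - 20.5)^2 + (co$y - 20.5)^2 + (co$z - 20.5)^2
  m <- array(FALSE, d)
  m[order(r2)[1:500]] <- TRUE      # compact 500-voxel spherical blob
  blob <- binary_mask(m, 36e-6)
  vol <- simulate_uct_scan(blob, scan_params(psf_sigma = 0, noise_sd = 30),
                           seed = 42L)
  rec <- process_volume(vol, filter_params())
  expect_gte(sum(rec$mask & m) / sum(m), 0.95)
  # empty background scan yields no spurious >= 50-voxel component
  empty <- simulate_uct_scan(binary_mask(array(FALSE, d), 36e-6),
                             scan_params(psf_sigma = 0, noise_sd = 30),
                             seed = 43L)
  expect_equal(sum(process_volume(empty, filter_params())$mask), 0L)
})
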