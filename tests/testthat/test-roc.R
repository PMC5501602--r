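make_sample <- function(dim = c(10, 10, 10), tau = NULL, mineral = NULL,
                        vs = 36e-6, invalid = 0L) {
  n <- prod(dim)
  if (is.null(tau)) tau <- array(stats::runif(n, 0, 30e-3), dim)
  valid <- array(TRUE, dim)
  if (invalid > 0L) valid[seq_len(invalid)] <- FALSE
  ss <- structure(list(tau = ifelse(valid, tau, NA_real_), valid = valid,
                       voxel_size = vs, origin = c(0, 0, 0)),
                  class = "voxel_field_sample")
  ss$tau <- array(ss$tau, dim); ss$valid <- array(ss$valid, dim)
  if (is.null(mineral)) mineral <- array(FALSE, dim)
  list(ss = ss, mineral = binary_mask(array(mineral, dim), vs),
       region = binary_mask(array(TRUE, dim), vs))
}

test_that("superimposition pairs voxels, counts P/N and tallies exclusions", {
  set.seed(1)
  mineral <- array(FALSE, c(10, 10, 10)); mineral[1:10] <- TRUE
  s <- make_sample(mineral = mineral, invalid = 4L)
  pd <- superimpose(s$ss, s$mineral, s$region)
  expect_equal(pd$excluded, 4L)
  expect_equal(pd$P + pd$N, 1000L - 4L)
  expect_equal(pd$P, sum(mineral) - 4L)  # the invalid voxels were mineralized
  # lattice mismatch errors
  bad <- binary_mask(array(FALSE, c(9, 10, 10)), 36e-6)
  expect_error(superimpose(s$ss, bad, s$region), "lattice")
  none <- s$region; none$mask[] <- FALSE
  expect_error(superimpose(s$ss, s$mineral, none), "no region voxels")
})

test_that("pooling concatenates, sums counts, and is order-invariant", {
  set.seed(2)
  a <- paired_voxels(runif(50), runif(50) < 0.3, "s1")
  b <- paired_voxels(runif(80), runif(80) < 0.5, "s2")
  expect_identical(pool(list(a))$tau, a$tau)
  ab <- pool(list(a, b)); ba <- pool(list(b, a))
  expect_equal(ab$P, a$P + b$P)
  expect_equal(ab$N, a$N + b$N)
  expect_equal(roc_curve(ab)$auc, roc_curve(ba)$auc)
  expect_equal(least_random_point(roc_curve(ab)),
               least_random_point(roc_curve(ba)))
  expect_error(pool(list()), "empty")
})

test_that("the six-voxel worked example gives AUC 8/9 and tau* = 3 mPa", {
  pd <- paired_voxels(tau = c(1, 2, 3, 4, 5, 6) * 1e-3,
                      mineralized = c(0, 0, 1, 0, 1, 1))
  curve <- roc_curve(pd)
  expect_equal(curve$auc, 8 / 9, tolerance = 1e-12)
  # against exhaustive enumeration
  enum <- roc_enumeration_oracle(pd$tau, pd$mineralized)
  expect_equal(curve$sweep$TPR[-1], enum$TPR)
  expect_equal(curve$sweep$FPR[-1], enum$FPR)
  lr <- least_random_point(curve)
  expect_equal(lr$tau_star, 3e-3)
  expect_equal(lr$TPR, 1.0)
  expect_equal(lr$FPR, 1 / 3)
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic on random instances", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    tau <- sample(seq(0.5, 12, by = 0.5) * 1e-3, n, replace = TRUE)  # with ties
    lab <- stats::runif(n) < 0.4
    if (!any(lab) || all(lab)) next
    curve <- roc_curve(paired_voxels(tau, lab))
    expect_equal(curve$auc, mw_auc_oracle(tau, lab), tolerance = 1e-12)
  }
})

test_that("perfect separation and degenerate labels behave correctly", {
  pd <- paired_voxels(c(1, 2, 3, 10, 11, 12) * 1e-3,
                      c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  curve <- roc_curve(pd)
  expect_equal(curve$auc, 1)
  expect_equal(least_random_point(curve)$TPR, 1)
  expect_equal(least_random_point(curve)$FPR, 0)
  expect_error(roc_curve(paired_voxels(1:5 * 1e-3, rep(TRUE, 5))), "undefined")
  expect_error(roc_curve(paired_voxels(1:5 * 1e-3, rep(FALSE, 5))), "undefined")
})

test_that("the ROC is invariant under strictly monotone transforms of tau", {
  set.seed(9)
  tau <- stats::rlnorm(300, log(2e-3), 1)
  lab <- stats::runif(300) < stats::plogis(log(tau / 2e-3))
  c1 <- roc_curve(paired_voxels(tau, lab))
  c2 <- roc_curve(paired_voxels(log(tau), lab))
  c3 <- roc_curve(paired_voxels(tau^3, lab))
  expect_equal(c1$auc, c2$auc, tolerance = 1e-12)
  expect_equal(c1$auc, c3$auc, tolerance = 1e-12)
  expect_equal(c1$sweep$TPR, c2$sweep$TPR)
  expect_equal(c1$sweep$FPR, c3$sweep$FPR)
})

test_that("flipping the highest-tau negative to positive never decreases AUC", {
  set.seed(13)
  for (rep in 1:20) {
    tau <- stats::runif(60, 0, 30e-3)
    lab <- stats::runif(60) < 0.5
    if (!any(lab) || all(!lab)) next
    auc0 <- roc_curve(paired_voxels(tau, lab))$auc
    i <- which(!lab)[which.max(tau[!lab])]
    lab2 <- lab; lab2[i] <- TRUE
    if (all(lab2)) next
    expect_gte(roc_curve(paired_voxels(tau, lab2))$auc, auc0 - 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  tau <- stats::rlnorm(500, log(1e-3), 1.2)
  lab <- stats::runif(500) < stats::plogis(2 * log(tau / 1e-3))
  ours <- roc_curve(paired_voxels(tau, lab))$auc
  theirs <- suppressMessages(as.numeric(pROC::auc(pROC::roc(lab, tau,
                                                            direction = "<"))))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("a fixed threshold grid approximates the exact unique-value sweep", {
  set.seed(31)
  tau <- stats::rlnorm(2000, log(2e-3), 0.8)
  lab <- stats::runif(2000) < stats::plogis(log(tau / 2e-3))
  exact <- roc_curve(paired_voxels(tau, lab))
  grid <- roc_curve(paired_voxels(tau, lab),
                    thresholds = exp(seq(log(min(tau)), log(max(tau)),
                                         length.out = 200)))
  expect_equal(grid$auc, exact$auc, tolerance = 0.01)
})
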