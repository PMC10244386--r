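gauss_ridge <- function(n = 33L, s = 3, A = 100, axis = 1L) {
  ctr <- (n + 1) / 2
  x <- seq_len(n)
  cross <- A * exp(-(outer((x - ctr)^2, (x - ctr)^2, "+")) / (2 * s^2))
  a <- array(NA_real_, rep(n, 3L))
  for (i in seq_len(n)) {
    if (axis == 1L) a[i, , ] <- cross
    else if (axis == 2L) a[, i, ] <- cross
    else a[, , i] <- cross
  }
  image_volume(a, c(1, 1, 1))
}

test_that("tubeness vanishes on constant volumes", {
  vol <- image_volume(array(7, c(16, 16, 16)), c(1, 1, 1))
  tub <- compute_tubeness(vol, tubeness_config(gaussian_sigma = 1))
  expect_lt(max(tub), 1e-9)   # zero up to floating cancellation
})

test_that("a bright Gaussian ridge scores the analytic on-axis tubeness", {
  # ridge of width s smoothed by sigma: amplitude A s^2/(s^2+sigma^2),
  # cross-axis curvatures both -A s^2/(s^2+sigma^2)^2, axial curvature 0,
  # so on-axis tubeness ~ A s^2 / (s^2 + sigma^2)^2
  n <- 33L; s <- 3; A <- 100
  vol <- gauss_ridge(n, s, A)
  tub <- compute_tubeness(vol, tubeness_config(gaussian_sigma = 1))
  ctr <- (n + 1L) / 2L
  expected <- A * s^2 / (s^2 + 1)^2
  expect_equal(tub[ctr, ctr, ctr], expected, tolerance = 0.05)
  # the score is maximal on the axis
  expect_equal(max(tub), max(tub[, ctr, ctr]), tolerance = 1e-8)
  # interior axis voxels all score equally (translation invariance along tube)
  expect_lt(diff(range(tub[10:24, ctr, ctr])), 1e-8 * expected)
})

test_that("a dark tube on a bright background scores zero on the axis", {
  vol <- gauss_ridge()
  dark <- image_volume(max(vol) - unclass(vol), voxel_spacing(vol))
  tub <- compute_tubeness(dark, tubeness_config(gaussian_sigma = 1))
  ctr <- 17L
  expect_equal(tub[ctr, ctr, ctr], 0)
  expect_equal(max(tub[10:24, ctr, ctr]), 0)
})

test_that("tubeness is covariant under axis permutation of the volume", {
  t1 <- compute_tubeness(gauss_ridge(axis = 1L), tubeness_config(gaussian_sigma = 1))
  t2 <- compute_tubeness(gauss_ridge(axis = 2L), tubeness_config(gaussian_sigma = 1))
  # degenerate on-axis eigenvalues (l2 ~ l3) limit the closed-form
  # eigensolver to ~sqrt(machine eps) relative accuracy
  expect_lt(max(abs(aperm(unclass(t1), c(2, 1, 3)) - unclass(t2))),
            1e-6 * max(t1))
})

test_that("tubeness scales linearly with image intensity", {
  set.seed(9)
  vol <- image_volume(array(rnorm(18^3, 100, 10), rep(18, 3)), c(1, 1, 1))
  cfg <- tubeness_config(gaussian_sigma = 1.5)
  t1 <- compute_tubeness(vol, cfg)
  t3 <- compute_tubeness(image_volume(3 * unclass(vol), c(1, 1, 1)), cfg)
  expect_equal(unclass(t3), 3 * unclass(t1), tolerance = 1e-12)
})

test_that("the Gaussian-derivative Hessian mode agrees with smooth-then-difference", {
  vol <- gauss_ridge(n = 25L, s = 3)
  tc <- compute_tubeness(vol, tubeness_config(gaussian_sigma = 1, derivative = "central"))
  tg <- compute_tubeness(vol, tubeness_config(gaussian_sigma = 1, derivative = "gaussian"))
  ctr <- 13L
  expect_equal(tg[ctr, ctr, ctr], tc[ctr, ctr, ctr], tolerance = 0.05)
})

test_that("intensity remapping aligns histogram peaks", {
  set.seed(21)
  sp <- c(0.04, 0.04, 0.04)
  brain <- seg_mask(array(TRUE, c(24, 24, 24)), sp)
  for (m in c(100, 400)) {
    vol <- image_volume(array(rnorm(24^3, m, m / 12), c(24, 24, 24)), sp)
    out <- remap_intensity(vol, brain, 200)
    expect_equal(attr(out, "scale_factor"), 200 / m, tolerance = 0.05)
    # post-remap mode back at the reference within a couple of histogram bins
    expect_lt(abs(intensity_mode(out[brain]) - 200), 3)
  }
  # already-aligned volume keeps scale ~1
  vol <- image_volume(array(rnorm(24^3, 200, 15), c(24, 24, 24)), sp)
  expect_equal(attr(remap_intensity(vol, brain, 200), "scale_factor"), 1,
               tolerance = 0.05)
  expect_error(remap_intensity(image_volume(array(1, c(8, 8, 8)), sp),
                               seg_mask(array(TRUE, c(8, 8, 8)), sp), 100),
               "degenerate|constant")
})

test_that("naive-calibrated thresholds equal the sorted-array percentile mean", {
  sp <- c(1, 1, 1)
  reg <- list(all = seg_mask(array(TRUE, c(10, 10, 10)), sp))
  set.seed(14)
  v1 <- image_volume(array(rexp(1000, 1), c(10, 10, 10)), sp)
  expect_equal(unname(calibrate_threshold(list(v1), reg, 0.95)),
               sorted_percentile(as.vector(v1), 0.95))
  # mean across controls: per-volume 95th percentiles 3.0 and 4.5 average 3.75
  c1 <- image_volume(array(3.0, c(10, 10, 10)), sp)
  c2 <- image_volume(array(4.5, c(10, 10, 10)), sp)
  expect_equal(unname(calibrate_threshold(list(c1, c2), reg, 0.95)), 3.75)
  # convergence to the population quantile for growing samples
  big <- image_volume(array(rexp(24^3, 2), c(24, 24, 24)), sp)
  regb <- list(all = seg_mask(array(TRUE, c(24, 24, 24)), sp))
  expect_equal(unname(calibrate_threshold(list(big), regb, 0.95)),
               qexp(0.95, 2), tolerance = 0.05)
  expect_error(calibrate_threshold(list(v1),
                                   list(all = seg_mask(array(FALSE, c(10, 10, 10)), sp)),
                                   0.95), "empty")
})

test_that("segmentation respects thresholds, masks, and monotonicity", {
  set.seed(31)
  sp <- c(1, 1, 1)
  tub <- image_volume(array(rexp(16^3), c(16, 16, 16)), sp)
  brain <- seg_mask(array(TRUE, c(16, 16, 16)), sp)
  vent <- seg_mask(array(FALSE, c(16, 16, 16)), sp)
  vent[8:10, 8:10, 8:10] <- TRUE
  regions <- list(all = brain)
  empty <- segment_pvs(tub, c(all = max(tub) + 1), regions, brain, vent)
  expect_equal(sum(empty), 0)
  lo <- segment_pvs(tub, c(all = 1), regions, brain, vent)
  hi <- segment_pvs(tub, c(all = 2), regions, brain, vent)
  expect_true(all(!(hi & !lo)))          # raising the threshold never adds voxels
  expect_equal(sum(lo & vent), 0)        # ventricle voxels never segmented
  # exclusion masks are honored
  excl <- seg_mask(array(FALSE, c(16, 16, 16)), sp); excl[1:4, , ] <- TRUE
  seg <- segment_pvs(tub, c(all = 1), regions, brain, vent, list(excl))
  expect_equal(sum(seg & excl), 0)
  # geometry mismatches are errors
  expect_error(segment_pvs(tub, c(all = 1), regions,
                           seg_mask(array(TRUE, c(8, 8, 8)), sp)), "geometry")
})

test_that("calibrated segmentation preserves scale invariance", {
  # scaling image intensities scales tubeness and thresholds alike, leaving
  # the segmentation unchanged
  spec <- small_phantom_spec(seed = 8L)
  ph <- generate_phantom(spec)
  naive <- generate_naive({s <- spec; s$seed <- 99L; s})
  cfg <- tubeness_config()
  regions <- brain_regions(ph$truth$brain_mask, 3)
  tub1 <- compute_tubeness(ph$volume, cfg)
  ntub1 <- compute_tubeness(naive, cfg)
  thr1 <- calibrate_threshold(list(ntub1), regions, 0.95)
  seg1 <- segment_pvs(tub1, thr1, regions, ph$truth$brain_mask, ph$truth$ventricle_mask)
  c_ <- 2.5
  scale_vol <- function(v) image_volume(c_ * unclass(v), voxel_spacing(v))
  tub2 <- compute_tubeness(scale_vol(ph$volume), cfg)
  ntub2 <- compute_tubeness(scale_vol(naive), cfg)
  thr2 <- calibrate_threshold(list(ntub2), regions, 0.95)
  expect_equal(unname(thr2), c_ * unname(thr1), tolerance = 1e-10)
  seg2 <- segment_pvs(tub2, thr2, regions, ph$truth$brain_mask, ph$truth$ventricle_mask)
  expect_identical(as.vector(seg1), as.vector(seg2))
})

test_that("percent volume matches exhaustive voxel counting", {
  sp <- c(1, 1, 1)
  pvs <- seg_mask(array(FALSE, c(10, 10, 10)), sp)
  voi <- seg_mask(array(FALSE, c(10, 10, 10)), sp)
  voi[1:10, 1:10, 1] <- TRUE
  expect_equal(percent_volume(pvs, voi), 0)
  pvs[5, 5, 1] <- TRUE
  expect_equal(percent_volume(pvs, voi), 1)
  set.seed(12)
  pvs2 <- seg_mask(array(runif(1000) < 0.3, c(10, 10, 10)), sp)
  voi2 <- seg_mask(array(runif(1000) < 0.5, c(10, 10, 10)), sp)
  expect_equal(percent_volume(pvs2, voi2),
               100 * sum(pvs2 & voi2) / sum(voi2))
  expect_error(percent_volume(pvs, seg_mask(array(FALSE, c(10, 10, 10)), sp)),
               "empty")
})

test_that("a well-resolved tube is recovered from a naive-calibrated segmentation", {
  res <- run_recovery_experiment(1L)
  expect_gte(res$dice_interior, 0.7)
  # detection is essentially complete: interior truth voxels are segmented
  tr <- res$phantom$truth
  interior_truth <- unclass(tr$pvs_mask) & unclass(res$regions$interior)
  expect_gt(sum(res$pvs & interior_truth) / sum(interior_truth), 0.9)
  # the surface threshold exceeds the interior threshold
  expect_gt(res$thresholds[["surface"]], res$thresholds[["interior"]])
})
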