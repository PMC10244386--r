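test_that("degenerate noiseless phantom has empty PVS and exactly three levels", {
  spec <- small_phantom_spec(noise_sd = 0, bias = 0, tubes = list())
  ph <- generate_phantom(spec)
  expect_equal(sum(ph$truth$pvs_mask), 0)
  vals <- sort(unique(as.vector(ph$volume)))
  expect_length(vals, 3L)
  expect_equal(vals, c(0, 100 * spec$parenchyma_enhancement, 500))
})

test_that("tube truth length is the Euclidean polyline length", {
  tb <- tube_spec(rbind(c(0, 0, 0), c(2, 0, 0)), radius = 0.05)
  expect_equal(tube_length(tb), 2)
  bent <- tube_spec(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), radius = 0.05)
  expect_equal(tube_length(bent), 2)
})

test_that("thin axis-aligned tube rasterizes one voxel per layer", {
  # radius 0.02 mm on a 0.04 mm grid: only voxel centers exactly on the axis
  # fall within the radius, so an axis-aligned tube through 50 layers fills
  # exactly 50 voxels
  sp <- c(0.04, 0.04, 0.04)
  shape <- c(60L, 24L, 24L)
  ctr <- shape * sp / 2
  p0 <- c(4.5 * sp[1], 11.5 * sp[2], 11.5 * sp[3])   # on voxel-center row
  p1 <- p0 + c(49 * sp[1], 0, 0)
  spec <- phantom_spec(grid_shape = shape, spacing = sp,
                       brain = list(center = ctr, semi_axes = c(1.18, 0.46, 0.46)),
                       tubes = list(tube_spec(rbind(p0, p1), radius = 0.02)),
                       noise_sd = 0)
  ph <- generate_phantom(spec)
  expect_equal(sum(ph$truth$pvs_mask), 50)

  # brute-force point-in-cylinder oracle over all voxel centers
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  pts <- cbind((g$i - 0.5) * sp[1], (g$j - 0.5) * sp[2], (g$k - 0.5) * sp[3])
  d <- q <- p1 - p0
  tt <- pmin(pmax(as.vector(sweep(pts, 2, p0, "-") %*% d) / sum(d^2), 0), 1)
  proj <- sweep(outer(tt, d), 2, p0, "+")
  inside <- sqrt(rowSums((pts - proj)^2)) <= 0.02
  expect_equal(which(as.vector(ph$truth$pvs_mask)),
               which(inside))
})

test_that("rasterized voxel count is at least ceil(length/spacing) for wide tubes", {
  sp <- c(0.04, 0.04, 0.04)
  shape <- c(60L, 24L, 24L)
  ctr <- shape * sp / 2
  axis_pt <- c(10.5 * sp[1], 11.5 * sp[2], 11.5 * sp[3])  # on a voxel-center row
  for (r in c(0.02, 0.03, 0.06)) {
    len <- 1.6
    spec <- phantom_spec(grid_shape = shape, spacing = sp,
                         brain = list(center = ctr, semi_axes = c(1.18, 0.46, 0.46)),
                         tubes = list(tube_spec(rbind(axis_pt,
                                                      axis_pt + c(len, 0, 0)),
                                                radius = r)),
                         noise_sd = 0)
    ph <- generate_phantom(spec)
    expect_gte(sum(ph$truth$pvs_mask), ceiling(len / sp[1]))
  }
})

test_that("phantom generation is deterministic under the spec seed", {
  spec <- small_phantom_spec(seed = 42L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(as.vector(a$volume), as.vector(b$volume))
  expect_identical(as.vector(generate_naive(spec)), as.vector(generate_naive(spec)))
})

test_that("truth masks are mutually consistent", {
  ph <- generate_phantom(small_phantom_spec())
  tr <- ph$truth
  expect_true(all(!(tr$pvs_mask & tr$ventricle_mask)))
  expect_true(all(tr$pvs_mask[tr$tube_labels > 0]))
  expect_true(all(tr$brain_mask[tr$tube_labels > 0]))
  expect_true(all(!(tr$ventricle_mask & !tr$brain_mask)))
})

test_that("naive control is constant inside the brain without noise and bias", {
  spec <- small_phantom_spec(noise_sd = 0, bias = 0)
  nv <- generate_naive(spec)
  ph <- generate_phantom(spec)
  expect_true(all(nv[ph$truth$brain_mask] == spec$parenchyma_level))
})

test_that("naive within-brain intensities match the Gaussian noise model", {
  spec <- small_phantom_spec(noise_sd = 8, bias = 0, seed = 11L)
  nv <- generate_naive(spec)
  brain <- generate_phantom(spec)$truth$brain_mask
  v <- nv[brain]
  se <- spec$noise_sd / sqrt(length(v))
  expect_lt(abs(mean(v) - spec$parenchyma_level), 3 * se)
  expect_lt(abs(sd(v) - spec$noise_sd), 0.05 * spec$noise_sd)
})

test_that("invalid specs are rejected with informative errors", {
  sp <- c(0.04, 0.04, 0.04)
  shape <- c(40L, 40L, 40L)
  ctr <- shape * sp / 2
  expect_error(tube_spec(rbind(c(0, 0, 0), c(1, 0, 0)), radius = 0),
               "radius")
  expect_error(tube_spec(rbind(c(0, 0, 0)), radius = 0.1), "control points")
  spec <- phantom_spec(grid_shape = shape, spacing = sp,
                       brain = list(center = ctr, semi_axes = c(0.5, 0.5, 0.5)),
                       tubes = list(tube_spec(rbind(ctr, ctr + c(2, 0, 0)),
                                              radius = 0.05)),
                       noise_sd = 0)
  expect_error(generate_phantom(spec), "tube 1.*exits the brain")
  expect_error(phantom_spec(grid_shape = shape, spacing = sp,
                            brain = list(center = ctr, semi_axes = c(0.5, 0.5, 0.5)),
                            parenchyma_level = 10, background_level = 20),
               "levels")
})

test_that("phantom round-trips through NIfTI and CSV outputs", {
  spec <- small_phantom_spec(seed = 5L)
  ph <- generate_phantom(spec)
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir)
  vol <- read_volume(paths[["volume"]])
  expect_equal(voxel_spacing(vol), spec$spacing, tolerance = 1e-6)
  expect_equal(as.vector(vol), as.vector(ph$volume), tolerance = 1e-6)
  pvs <- read_mask(paths[["pvs"]])
  expect_identical(as.vector(pvs), as.vector(ph$truth$pvs_mask))
  man <- read.csv(paths[["manifest"]])
  expect_equal(man$length_mm, ph$truth$tube_lengths)
  expect_equal(man$connects_ventricle, ph$truth$connects_ventricle)
})
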