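test_that("identical spec and seed reproduce bit-identical volumes", {
  sp <- phantom_spec(grid_shape = c(32, 32, 32),
                     lesion_center_mm = c(8, 0, 0),
                     lesion_radii_mm = c(6, 8, 8), noise_seed = 7)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask, b$mask)
})

test_that("zero-contrast lesion region matches its mirror image", {
  sp <- phantom_spec(grid_shape = c(40, 40, 40), lesion_delta_hu = 0,
                     lesion_center_mm = c(12, 0, 0),
                     lesion_radii_mm = c(8, 8, 8), noise_seed = 2)
  ph <- generate_phantom(sp)
  v <- ph$volume$voxels
  m_in <- mean(v[ph$mask])
  mirror <- ph$mask[rev(seq_len(dim(v)[1])), , ]
  m_mirror <- mean(v[mirror])
  # same anatomy on both sides; difference is only noise-of-the-mean
  tol <- 4 * sp$parenchyma_hu_sd / sqrt(sum(ph$mask))
  expect_lt(abs(m_in - m_mirror), 5 * tol)
})

test_that("mask voxel count matches the analytic ellipsoid volume", {
  sp <- phantom_spec(grid_shape = c(128, 128, 128), spacing_mm = 0.5,
                     lesion_center_mm = c(0, 0, 0),
                     lesion_radii_mm = c(10, 8, 8))
  ph <- generate_phantom(sp)
  expected <- (4 / 3) * pi * 10 * 8 * 8 / 0.5^3   # 21,447 voxels
  expect_lt(abs(sum(ph$mask) - expected) / expected, 0.05)
})

test_that("mask volume converges to the analytic volume under refinement", {
  analytic <- (4 / 3) * pi * 9 * 8 * 8 / 1000
  errs <- vapply(c(4, 2, 1), function(h) {
    n <- as.integer(96 / h)  # fixed 96 mm extent
    sp <- phantom_spec(grid_shape = rep(n, 3), spacing_mm = h,
                       lesion_center_mm = c(0, 0, 0),
                       lesion_radii_mm = c(9, 8, 8))
    abs(mask_volume_ml(generate_phantom(sp)$mask, h) - analytic) / analytic
  }, 1)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})

test_that("lesion-free artifact-free phantom is mirror-symmetric up to noise", {
  sp <- phantom_spec(grid_shape = c(40, 40, 40), lesion_radii_mm = NULL,
                     noise_seed = 5)
  ph <- generate_phantom(sp)
  v <- ph$volume$voxels
  flipped <- flip_lr(ph$volume)$voxels
  geom <- phantom_geometry(sp$grid_shape, sp$spacing_mm)
  xs <- (seq_len(40) - 20.5) * 2
  brain <- outer(outer((xs / geom$brain_semi_mm[1])^2,
                       (xs / geom$brain_semi_mm[2])^2, `+`),
                 (xs / geom$brain_semi_mm[3])^2, `+`) <= 1
  expect_lt(mean(abs(v - flipped)[brain]), 2 * sp$parenchyma_hu_sd)
})

test_that("a lesion crossing the skull is rejected with a geometry error", {
  expect_error(generate_phantom(
    phantom_spec(grid_shape = c(32, 32, 32),
                 lesion_center_mm = c(24, 0, 0),
                 lesion_radii_mm = c(10, 10, 10))),
    "outside the brain")
})

test_that("parenchyma outside the 10-80 HU soft-tissue band is rejected", {
  expect_error(phantom_spec(parenchyma_hu_mean = 75, parenchyma_hu_sd = 4),
               "soft-tissue band")
  expect_error(phantom_spec(parenchyma_hu_mean = 15, parenchyma_hu_sd = 4),
               "soft-tissue band")
})

test_that("control-only cohorts have empty masks", {
  cohort <- generate_cohort(0, 3, NULL, seed = 7,
                            grid_shape = c(32, 32, 32))
  expect_length(cohort, 3)
  expect_true(all(vapply(cohort, function(cs) !any(cs$mask), TRUE)))
  expect_true(all(vapply(cohort, function(cs) cs$label == "control", TRUE)))
})

test_that("stroke lesion volumes land in the requested range", {
  cohort <- generate_cohort(2, 2, c(20, 40), seed = 1)
  vols <- vapply(cohort[1:2], function(cs) cs$lesion_volume_ml, 1)
  # voxelization moves the realized volume off the continuous target slightly
  expect_true(all(vols > 20 * 0.95 & vols < 40 * 1.05))
  expect_true(all(vapply(cohort[3:4], function(cs) cs$lesion_volume_ml == 0, TRUE)))
})

test_that("cohorts regenerate identically from the same seed", {
  a <- generate_cohort(3, 2, c(15, 30), seed = 42, grid_shape = c(40, 40, 40))
  b <- generate_cohort(3, 2, c(15, 30), seed = 42, grid_shape = c(40, 40, 40))
  expect_identical(lapply(a, function(cs) cs$volume$voxels),
                   lapply(b, function(cs) cs$volume$voxels))
  expect_identical(lapply(a, function(cs) cs$mask),
                   lapply(b, function(cs) cs$mask))
})

test_that("an empty volume range with stroke cases requested is an error", {
  expect_error(generate_cohort(1, 0, NULL, seed = 1), "volume_range_ml")
})

test_that("cohorts round-trip through NIfTI and a CSV manifest", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(1, 1, c(8, 12), seed = 3,
                            grid_shape = c(32, 32, 32))
  manifest <- write_cohort(cohort, dir)
  df <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(df), 2)
  vol <- read_volume(file.path(dir, df$volume_path[1]))
  expect_equal(dim(vol$voxels), c(32, 32, 32))
  expect_equal(vol$spacing_mm, cohort[[1]]$volume$spacing_mm)
  expect_equal(vol$voxels, cohort[[1]]$volume$voxels, tolerance = 1e-6)
})
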