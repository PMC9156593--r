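test_that("tiles partition a multiple-of-edge volume", {
  cfg <- network_config(depth_C = 40)   # output edge 26
  tiles <- plan_tiles(c(52, 52, 52), cfg)
  expect_equal(nrow(tiles), 8)
  expect_equal(plan_tiles(c(26, 26, 26), cfg)$o1, 1L)
  expect_equal(nrow(plan_tiles(c(26, 26, 26), cfg)), 1)
})

test_that("write regions cover every voxel exactly once for random shapes", {
  cfg <- tiny_config(depth_C = 2, input_patch = 11)   # output edge 6
  e <- output_edge(cfg)
  set.seed(8)
  for (rep in 1:20) {
    d <- sample(e:(3 * e + 2), 3, replace = TRUE)
    tiles <- plan_tiles(d, cfg)
    cover <- array(0L, d)
    for (t in seq_len(nrow(tiles))) {
      hi <- pmin(c(tiles$o1[t], tiles$o2[t], tiles$o3[t]) + e - 1L, d)
      cover[tiles$w1[t]:hi[1], tiles$w2[t]:hi[2], tiles$w3[t]:hi[3]] <-
        cover[tiles$w1[t]:hi[1], tiles$w2[t]:hi[2], tiles$w3[t]:hi[3]] + 1L
    }
    expect_true(all(cover == 1L))
  }
})

test_that("input corners sit depth_C voxels before the output corners", {
  cfg <- tiny_config(depth_C = 3, input_patch = 11)
  tiles <- plan_tiles(c(10, 10, 10), cfg)
  expect_true(all(tiles$i1 == tiles$o1 - 3))
})

test_that("stitched prediction equals the single whole-volume pass", {
  cfg <- tiny_config(depth_C = 2, width_F = 3, input_patch = 13)
  net <- build_network(cfg, seed = 4)
  tc <- fake_tc(c(30, 25, 21), seed = 6)
  pm <- stitch_predict(net, tc)
  expect_equal(dim(pm$probs), dim(tc$channel_original))
  oracle <- single_pass_probs(net, tc)
  expect_lt(max(abs(pm$probs - oracle)), 1e-5)
  expect_true(all(pm$probs >= 0 & pm$probs <= 1))
})

test_that("a constant input yields spatially constant interior probabilities", {
  cfg <- tiny_config(depth_C = 2, input_patch = 9)
  net <- build_network(cfg, seed = 2)
  d <- c(20, 20, 20)
  tc <- fake_tc(d)
  tc$channel_original[] <- 0.3
  tc$channel_mirrored[] <- 0.3
  pm <- stitch_predict(net, tc)
  interior <- pm$probs[6:15, 6:15, 6:15]  # outside the padding's influence
  expect_lt(diff(range(interior)), 1e-12)
})

test_that("stitching rejects a model whose config disagrees", {
  net <- build_network(tiny_config(depth_C = 2, input_patch = 9))
  expect_error(stitch_predict(net, fake_tc(c(12, 12, 12)),
                              tiny_config(depth_C = 3, input_patch = 11)),
               "mismatch")
})

test_that("colormap calibration takes the 5/95 percent quantiles above 0.5", {
  set.seed(1)
  cal <- calibrate_colormap(runif(200000, 0.5, 1.0))
  expect_equal(cal$vmin, 0.525, tolerance = 0.01)
  expect_equal(cal$vmax, 0.975, tolerance = 0.01)
})

test_that("degenerate probability samples fall back to (0.5, 1)", {
  cal <- calibrate_colormap(rep(0.9, 100))
  expect_equal(cal$vmin, 0.5)
  expect_equal(cal$vmax, 1.0)
})

test_that("the lower display bound is cut off at 0.5", {
  set.seed(2)
  cal <- calibrate_colormap(runif(10000, 0, 1))
  expect_equal(cal$vmin, 0.5)
  expect_error(calibrate_colormap(numeric(0)), "empty")
})

test_that("an all-zero probability map renders as the bare grayscale base", {
  ph <- small_symmetric_phantom()
  pm <- structure(list(probs = array(0, dim(ph$volume$voxels)),
                       spacing_mm = ph$volume$spacing_mm,
                       provenance = list()), class = "prob_map")
  cal <- calibrate_colormap(rep(0.9, 10))
  imgs <- render_overlay(ph$volume, pm, cal, slices = 20)
  g <- pmin(pmax((ph$volume$voxels[, , 20] - 0) / 80, 0), 1)
  expect_equal(imgs[[1]][, , 1], g)
  expect_equal(imgs[[1]][, , 2], g)
})

test_that("probabilities at the calibration endpoints hit the palette ends", {
  base <- ct_volume(array(0, c(4, 4, 1)), spacing_mm = 1)
  probs <- array(0, c(4, 4, 1))
  probs[1, 1, 1] <- 0.6   # vmin
  probs[2, 1, 1] <- 0.9   # vmax
  probs[3, 1, 1] <- 0.75  # midpoint
  pm <- structure(list(probs = probs, spacing_mm = rep(1, 3),
                       provenance = list()), class = "prob_map")
  cal <- structure(list(vmin = 0.6, vmax = 0.9), class = "color_calibration")
  img <- render_overlay(base, pm, cal, slices = 1)[[1]]
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256, "plasma"))) / 255
  expect_equal(img[1, 1, ], unname(pal[1, ]))
  expect_equal(img[2, 1, ], unname(pal[256, ]))
  mid_idx <- 1 + round(0.5 * 255)
  expect_equal(img[3, 1, ], unname(pal[mid_idx, ]))
  # below-0.5 voxels stay transparent (bare base)
  expect_equal(img[4, 1, ], rep(0, 3))
})

test_that("overlay rendering rejects mismatched geometries", {
  base <- ct_volume(array(0, c(4, 4, 2)), spacing_mm = 1)
  pm <- structure(list(probs = array(0, c(5, 4, 2)), spacing_mm = rep(1, 3),
                       provenance = list()), class = "prob_map")
  cal <- structure(list(vmin = 0.5, vmax = 1), class = "color_calibration")
  expect_error(render_overlay(base, pm, cal), "mismatch")
})
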