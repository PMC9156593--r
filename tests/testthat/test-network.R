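test_that("the default architecture reproduces the published geometry", {
  cfg <- network_config()
  expect_equal(output_edge(cfg, 107), 26L)
  expect_equal(receptive_field(cfg), 81L)
  expect_equal(round(count_parameters(cfg) / 1000) * 1000, 528000)
})

test_that("output_edge follows the valid-padding arithmetic", {
  expect_equal(output_edge(network_config(terminal_crop = 0), 107), 27L)
  cfg2 <- network_config(depth_C = 2, input_patch = 7)
  expect_equal(output_edge(cfg2, 7), 2L)  # 7 - 4 - 1
  expect_error(output_edge(network_config(), 80), "minimum")
})

test_that("receptive field is 2C + 1", {
  expect_equal(receptive_field(network_config(depth_C = 1, input_patch = 5)), 3L)
  expect_equal(receptive_field(network_config(depth_C = 10, input_patch = 30)), 21L)
})

test_that("parameter count matches the per-layer closed form", {
  # 2 conv layers (no skips), fc 50, 2 classes: 55 + 28 + 100 + 102
  cfg <- network_config(depth_C = 2, width_F = 1, fc_width = 50,
                        skip_start = 3, in_channels = 2, input_patch = 8)
  expect_equal(count_parameters(cfg), 285L)
  # doubling the width strictly increases the count
  for (C in c(2, 5)) {
    narrow <- network_config(depth_C = C, width_F = 4, input_patch = 2 * C + 4)
    wide <- network_config(depth_C = C, width_F = 8, input_patch = 2 * C + 4)
    expect_gt(count_parameters(wide), count_parameters(narrow))
  }
})

test_that("count_parameters equals tensor enumeration across the search grid", {
  for (C in c(10, 20, 30, 40)) for (F in c(8, 16)) {
    cfg <- network_config(depth_C = C, width_F = F)
    expect_identical(count_parameters(cfg),
                     enumerate_parameters(build_network(cfg, seed = C + F)))
  }
})

test_that("softmax outputs sum to one for any configuration and input", {
  set.seed(1)
  for (rep in 1:3) {
    C <- sample(1:4, 1)
    cfg <- network_config(depth_C = C, width_F = sample(1:4, 1),
                          fc_width = sample(1:5, 1),
                          skip_start = sample(rep(2:(C + 1), 2), 1),
                          input_patch = 2 * C + 1 + sample(1:4, 1))
    net <- build_network(cfg, seed = rep)
    x <- array(rnorm(cfg$input_patch^3 * 2), c(rep(cfg$input_patch, 3), 2))
    p <- network_forward(net, x)$probs
    expect_lt(max(abs(apply(p, 1:3, sum) - 1)), 1e-6)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("a minimal one-layer network maps 3^3 to a single voxel", {
  cfg <- network_config(depth_C = 1, width_F = 1, fc_width = 1,
                        terminal_crop = 0, input_patch = 3)
  net <- build_network(cfg)
  p <- network_forward(net, array(rnorm(27 * 2), c(3, 3, 3, 2)))$probs
  expect_equal(dim(p), c(1L, 1L, 1L, 2L))
  expect_equal(sum(p), 1)
})

test_that("inputs below the minimum edge are rejected with the minimum named", {
  cfg <- tiny_config(depth_C = 3)   # minimum edge 8
  net <- build_network(cfg)
  expect_error(network_forward(net, array(0, c(7, 7, 7, 2))), "8")
})

test_that("the built network's output shape matches output_edge", {
  set.seed(42)
  for (rep in 1:50) {
    C <- sample(1:4, 1)
    crop <- sample(0:1, 1)
    edge <- 2 * C + crop + sample(1:3, 1)
    cfg <- network_config(depth_C = C, width_F = sample(1:3, 1),
                          fc_width = 2,
                          skip_start = sample(rep(2:(C + 1), 2), 1),
                          terminal_crop = crop, input_patch = edge)
    net <- build_network(cfg, seed = rep)
    p <- network_forward(net, array(rnorm(edge^3 * 2), c(edge, edge, edge, 2)))$probs
    expect_equal(dim(p)[1], output_edge(cfg, edge))
  }
})

test_that("shifting the input by one voxel shifts the output by one voxel", {
  cfg <- tiny_config(depth_C = 2, input_patch = 8)
  net <- build_network(cfg, seed = 3)
  n <- 12
  set.seed(9)
  x <- array(rnorm((n + 1)^3 * 2), c(n + 1, n + 1, n + 1, 2))
  p1 <- network_forward(net, x[1:n, 1:n, 1:n, , drop = FALSE])$probs
  p2 <- network_forward(net, x[2:(n + 1), 2:(n + 1), 2:(n + 1), , drop = FALSE])$probs
  e <- dim(p1)[1]
  expect_identical(p1[2:e, 2:e, 2:e, ], p2[1:(e - 1), 1:(e - 1), 1:(e - 1), ])
})

test_that("invalid configurations are rejected", {
  expect_error(network_config(depth_C = 0), "depth_C")
  expect_error(network_config(depth_C = 3, input_patch = 7), "input_patch")
  expect_error(network_config(depth_C = 3, skip_start = 5, input_patch = 9),
               "skip_start")
  expect_error(network_config(depth_C = 3, skip_start = 1, input_patch = 9),
               "skip_start")
})

test_that("initialization is reproducible from the seed", {
  cfg <- tiny_config()
  expect_identical(build_network(cfg, seed = 11)$weights,
                   build_network(cfg, seed = 11)$weights)
  expect_false(identical(build_network(cfg, seed = 11)$weights,
                         build_network(cfg, seed = 12)$weights))
})
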