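test_that("the default configuration builds a 52-convolution network", {
  net <- build_network(network_config(), seed = 1)
  expect_equal(count_conv_layers(net), 52L)
})

test_that("layer counts match independent arithmetic for small configs", {
  # counting rule: stem + 2 convs per residual block + downs + ups +
  # head block (2) + output conv; shortcut projections excluded
  for (L in 2:3) {
    for (B in 1:2) {
      cfg <- network_config(n_levels = L, base_channels = 4L,
                            blocks_per_level = B, gn_groups = 2L,
                            conv_layer_count_target = NULL)
      net <- build_network(cfg, seed = 1)
      expected <- 1 + 2 * B * L + (L - 1) + (L - 1) + 2 * B * (L - 1) + 2 + 1
      expect_equal(count_conv_layers(net), expected)
    }
  }
  one_conv <- list(registry = list(list(name = "stem", kind = "conv",
                                        counted = TRUE)))
  class(one_conv) <- "resunet"
  expect_equal(count_conv_layers(one_conv), 1L)
})

test_that("forward pass preserves shape, stays in [0,1], and is seed-deterministic", {
  net <- build_network(tiny_network_config(), seed = 3)
  for (shape in list(c(16, 16, 16), c(32, 32, 32), c(20, 24, 16))) {
    x <- array(0, shape)
    p <- forward(net, x)
    expect_equal(dim(p), shape)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(is.finite(p)))
  }
  x <- with_seed_arr(11, array(rnorm(16^3), c(16, 16, 16)))
  net_a <- build_network(tiny_network_config(), seed = 7)
  net_b <- build_network(tiny_network_config(), seed = 7)
  expect_identical(forward(net_a, x), forward(net_b, x))
  net_c <- build_network(tiny_network_config(), seed = 8)
  expect_false(identical(forward(net_a, x), forward(net_c, x)))
})

test_that("incompatible input sizes raise a shape error naming the axis", {
  net <- build_network(tiny_network_config(), seed = 1)
  expect_error(forward(net, array(0, c(15, 16, 16))), "axis 1")
  expect_error(forward(net, array(0, c(16, 16, 17))), "axis 3")
  expect_error(network_config(n_levels = 2, base_channels = 6,
                              blocks_per_level = 1, gn_groups = 4),
               "gn_groups")
})

test_that("group normalization standardizes each group before the affine map", {
  set.seed(21)
  x <- array(rnorm(8 * 8 * 8 * 4, mean = 3, sd = 2), c(8, 8, 8, 4))
  out <- lesionseg:::gn_fwd(x, gamma = c(1, 1, 1, 1), beta = numeric(4),
                            groups = 2)
  m <- matrix(out$y, ncol = 4)
  for (g in 1:2) {
    vals <- c(m[, (g - 1) * 2 + 1:2])
    expect_lt(abs(mean(vals)), 1e-10)
    expect_equal(sd(vals), 1, tolerance = 1e-3)
  }
})

test_that("every parameter receives gradient from the combined loss", {
  net <- build_network(tiny_network_config(), seed = 5)
  set.seed(33)
  x <- array(rnorm(12 * 12 * 12), c(12, 12, 12, 1))
  y <- array(0, c(12, 12, 12))
  y[4:8, 4:8, 4:8] <- 1
  fw <- lesionseg:::net_forward(net, x, want_cache = TRUE)
  p <- fw$prob
  dim(p) <- dim(y)
  dp <- lesionseg:::combined_loss_grad(p, y, loss_config())
  dim(dp) <- dim(fw$prob)
  gr <- lesionseg:::net_backward(net, fw$cache, dp)
  expect_setequal(ls(gr), ls(net$params))
  for (nm in ls(gr)) {
    expect_gt(sum(abs(gr[[nm]])), 0)
  }
})

test_that("checkpoints round-trip parameters, config, and epoch", {
  net <- build_network(tiny_network_config(), seed = 2)
  net$epoch <- 7L
  net$stage <- "zoom_out"
  td <- withr::local_tempdir()
  ck <- file.path(td, "model.rds")
  save_checkpoint(net, ck)
  back <- load_checkpoint(ck)
  expect_equal(back$epoch, 7L)
  expect_equal(back$stage, "zoom_out")
  x <- with_seed_arr(2, array(rnorm(16^3), c(16, 16, 16)))
  expect_identical(forward(net, x), forward(back, x))
})
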