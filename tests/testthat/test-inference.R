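test_that("center crop offsets use floor((shape - crop) / 2)", {
  sp <- center_crop_spec(c(197, 233, 189), c(144, 172, 168))
  expect_equal(sp$offset, c(26L, 30L, 10L))
  expect_equal(center_crop_spec(c(10, 10, 10), c(10, 10, 10))$offset,
               c(0L, 0L, 0L))
  expect_equal(center_crop_spec(c(10, 10, 10), c(8, 8, 8))$offset,
               c(1L, 1L, 1L))
  expect_error(center_crop_spec(c(10, 10, 10), c(12, 8, 8)), "larger")
})

test_that("voxels outside the center crop are exactly zero for random sizes", {
  net <- build_network(tiny_network_config(), seed = 6)
  set.seed(19)
  for (i in 1:4) {
    shape <- sample(seq(18, 30), 3)
    crop <- rep(16L, 3)
    vol <- les_volume(array(rnorm(prod(shape)), shape), c(1, 1, 1), "rnd")
    pm <- predict(net, vol, crop_size = crop)
    expect_equal(dim(pm$data), shape)
    sp <- center_crop_spec(shape, crop)
    inside <- array(FALSE, shape)
    inside[sp$offset[1] + seq_len(16), sp$offset[2] + seq_len(16),
           sp$offset[3] + seq_len(16)] <- TRUE
    expect_true(all(pm$data[!inside] == 0))
    expect_true(any(pm$data[inside] != 0))
    em <- ensemble_predict(list(net, net), vol, crop_size = crop)
    expect_true(all(em$data[!inside] == 0))
  }
})

test_that("a lesion entirely outside the crop window gets TPR zero", {
  net <- build_network(tiny_network_config(), seed = 6)
  shape <- c(24, 24, 24)
  vol <- les_volume(array(0.5, shape), c(1, 1, 1), "edge")
  ref <- array(0, shape)
  ref[1:2, 1:2, 1:2] <- 1  # outside the centered 16^3 window
  ref <- les_mask(ref, c(1, 1, 1), "edge")
  pm <- predict(net, vol, crop_size = c(16, 16, 16))
  expect_equal(tpr(binarize(pm), ref), 0)
})

test_that("ensembles average member maps and are permutation invariant", {
  n1 <- build_network(tiny_network_config(), seed = 1)
  n2 <- build_network(tiny_network_config(), seed = 2)
  vol <- les_volume(with_seed_arr(3, array(rnorm(16^3), c(16, 16, 16))),
                    c(1, 1, 1), "e")
  p1 <- predict(n1, vol)
  p2 <- predict(n2, vol)
  e12 <- ensemble_predict(list(n1, n2), vol)
  expect_equal(e12$data, (p1$data + p2$data) / 2, tolerance = 1e-12)
  e21 <- ensemble_predict(list(n2, n1), vol)
  expect_equal(e12$data, e21$data, tolerance = 1e-12)
  e1 <- ensemble_predict(list(n1), vol)
  expect_identical(e1$data, p1$data)
  expect_true(all(e12$data >= 0 & e12$data <= 1))
  expect_error(ensemble_predict(list(), vol), "empty")
})

test_that("binarization thresholds with ties mapping to positive", {
  p <- array(c(0.5, 0.49, 0, 1), c(4, 1, 1))
  m <- binarize(les_probmap(p, c(1, 1, 1), "t"))
  expect_equal(c(m$data), c(1, 0, 0, 1))
  expect_equal(sum(binarize(les_probmap(array(0, c(3, 3, 3)),
                                        c(1, 1, 1), "z"))$data), 0)
  k_map <- array(runif(27), c(3, 3, 3))
  expect_equal(sum(binarize(k_map, 0.5)), sum(k_map >= 0.5))
  expect_error(binarize(k_map, 1.2), "threshold")
})
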