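test_that("crop sampling covers exactly the valid offsets uniformly", {
  # single valid position
  set.seed(1)
  sp <- sample_crop(c(10, 12, 14), c(10, 12, 14))
  expect_equal(sp$offset, c(0L, 0L, 0L))
  # axis with 3 valid offsets: empirical frequencies near 1/3
  set.seed(2)
  offs <- replicate(3000, sample_crop(c(10, 16, 16), c(8, 16, 16))$offset[1])
  freq <- table(factor(offs, levels = 0:2)) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.05))
  # reproducibility
  set.seed(7)
  a <- replicate(20, sample_crop(c(30, 30, 30), c(8, 8, 8))$offset)
  set.seed(7)
  b <- replicate(20, sample_crop(c(30, 30, 30), c(8, 8, 8))$offset)
  expect_identical(a, b)
  expect_error(sample_crop(c(10, 10, 10), c(12, 10, 10)), "larger than")
})

test_that("crop fractions reproduce the reference sub-volume percentages", {
  scan <- c(197, 233, 189)
  expect_equal(crop_fraction(c(128, 128, 128), scan), 24)
  expect_equal(crop_fraction(c(144, 172, 168), scan), 48)
  expect_equal(crop_fraction(scan, scan), 100)
})

test_that("cosine warm-restart schedule matches its closed form", {
  expect_equal(cosine_warm_restart_lr(0, 10, 1e-3), 1e-3)
  expect_equal(cosine_warm_restart_lr(10, 10, 1e-3), 0)
  expect_equal(cosine_warm_restart_lr(5, 10, 1e-3, 0), 5e-4)
  expect_equal(cosine_warm_restart_lr(5, 10, 1e-3, 1e-5),
               1e-5 + 0.5 * (1e-3 - 1e-5))
  expect_error(cosine_warm_restart_lr(11, 10, 1e-3), "t_cur")

  st <- stage_config(crop_size = c(8, 8, 8), epochs = 40, initial_lr = 1e-3,
                     restart_period_T0 = 5, restart_mult_Tmult = 2)
  lrs <- vapply(0:39, lr_at_epoch, numeric(1), stage = st)
  # restarts at epochs 0, 5, 15 (cycle lengths 5, 10, 20)
  expect_equal(lrs[c(1, 6, 16)], rep(1e-3, 3))
  expect_true(all(lrs <= 1e-3 + 1e-15 & lrs >= 0))
  # midpoint of the second cycle (epoch 10 = 5 epochs into a 10-cycle)
  expect_equal(lrs[11], 5e-4)
})

test_that("train_stage bookkeeping: one record per epoch, schedule start, legal crops", {
  cfg <- small_phantom_config()
  cohort <- generate_cohort(2, cfg, seed = 3)
  net <- build_network(tiny_network_config(), seed = 1)
  st <- stage_config(crop_size = c(16, 16, 16), epochs = 1,
                     initial_lr = 1e-3, seed = 5)
  tr <- train_stage(net, cohort, st, loss_config())
  expect_equal(nrow(tr$history), 1)
  expect_true(is.finite(tr$history$loss))
  expect_equal(tr$history$lr[1], 1e-3)
  expect_error(
    train_stage(net, cohort, stage_config(crop_size = c(64, 64, 64),
                                          epochs = 1, initial_lr = 1e-3),
                loss_config()),
    "crop_size")
  expect_error(train_stage(net, list(), st, loss_config()), "empty")
})

test_that("training drives the loss down on a single phantom", {
  cfg <- phantom_config(grid_shape = c(24, 24, 24),
                        lesion_volume_range_mm3 = c(300, 600))
  cohort <- generate_cohort(1, cfg, seed = 13)
  net <- build_network(tiny_network_config(), seed = 2)
  st <- stage_config(crop_size = c(16, 16, 16), epochs = 120,
                     initial_lr = 1e-3, restart_period_T0 = 40,
                     restart_mult_Tmult = 2, seed = 21)
  tr <- train_stage(net, cohort, st, loss_config())
  expect_lt(tail(tr$history$loss, 1), 0.5 * tr$history$loss[1])
})

test_that("training is reproducible under identical seeds", {
  cfg <- small_phantom_config()
  cohort <- generate_cohort(2, cfg, seed = 3)
  st <- stage_config(crop_size = c(16, 16, 16), epochs = 2,
                     initial_lr = 1e-3, seed = 5)
  net <- build_network(tiny_network_config(), seed = 1)
  t1 <- train_stage(net, cohort, st, loss_config())
  t2 <- train_stage(net, cohort, st, loss_config())
  expect_identical(t1$history, t2$history)
  nm <- ls(t1$network$params)[1]
  expect_identical(mget(ls(t1$network$params), envir = t1$network$params),
                   mget(ls(t2$network$params), envir = t2$network$params))
})

test_that("zoom_in_out hands off parameters, captures snapshots, handles edge cases", {
  cfg <- small_phantom_config()
  cohort <- generate_cohort(2, cfg, seed = 6)
  net <- build_network(tiny_network_config(), seed = 4)
  si <- stage_config(crop_size = c(16, 16, 16), epochs = 2,
                     initial_lr = 1e-3, seed = 8)
  so <- stage_config(crop_size = c(24, 24, 24), epochs = 3,
                     initial_lr = 1e-4, restart_period_T0 = 3, seed = 9)
  zz <- zoom_in_out(net, cohort, si, so, snapshot_epochs = c(1, 2, 3))
  expect_named(zz$snapshots, c("epoch1", "epoch2", "epoch3"))
  # final model identical to the last snapshot
  expect_identical(
    mget(ls(zz$network$params), envir = zz$network$params),
    mget(ls(zz$snapshots$epoch3$params), envir = zz$snapshots$epoch3$params))
  expect_equal(nrow(zz$history), 5)
  expect_equal(unique(zz$history$stage), c("zoom_in", "zoom_out"))

  # degenerate first stage: zoom-in with 0 epochs
  si0 <- stage_config(crop_size = c(16, 16, 16), epochs = 0,
                      initial_lr = 1e-3, seed = 8)
  z0 <- zoom_in_out(net, cohort, si0, so)
  expect_equal(unique(z0$history$stage), "zoom_out")

  expect_error(zoom_in_out(net, cohort, si, so, snapshot_epochs = 4),
               "snapshot epoch")
  so_small <- stage_config(crop_size = c(8, 8, 8), epochs = 1,
                           initial_lr = 1e-4)
  expect_error(zoom_in_out(net, cohort, si, so_small), "zoom-out crop")
})
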