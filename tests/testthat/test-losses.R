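test_that("BCE matches closed forms", {
  y <- array(c(1, 0, 1, 0), c(2, 2, 1))
  # perfect prediction: only the clamp keeps the loss from exactly 0
  expect_equal(bce_loss(y, y), -log(1 - 1e-7), tolerance = 1e-12)
  # uninformative prediction: log 2 regardless of target
  half <- array(0.5, dim(y))
  expect_equal(bce_loss(half, y), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(half, array(0, dim(y))), log(2), tolerance = 1e-12)
  # two-voxel hand computation
  p2 <- array(c(0.9, 0.2), c(2, 1, 1))
  y2 <- array(c(1, 0), c(2, 1, 1))
  expect_equal(bce_loss(p2, y2), -(log(0.9) + log(0.8)) / 2,
               tolerance = 1e-12)
  expect_error(bce_loss(p2, y), "shapes differ")
})

test_that("Dice loss matches closed forms including empty cases", {
  y <- array(0, c(4, 4, 4))
  y[1:2, 1:2, 1] <- 1  # k = 4 positives
  expect_equal(dice_loss(y, y), 0)
  zero <- array(0, dim(y))
  k <- sum(y)
  expect_equal(dice_loss(zero, y), 1 - 1 / (k + 1), tolerance = 1e-12)
  expect_equal(dice_loss(zero, zero), 0)
  expect_true(dice_loss(array(runif(64), c(4, 4, 4)), y) >= 0)
})

test_that("combined loss is the affine combination with exact endpoints", {
  set.seed(9)
  p <- array(runif(60), c(5, 4, 3))
  y <- array(rbinom(60, 1, 0.3), c(5, 4, 3))
  expect_identical(combined_loss(p, y, loss_config(lambda_bce = 1)),
                   bce_loss(p, y))
  expect_identical(combined_loss(p, y, loss_config(lambda_bce = 0)),
                   dice_loss(p, y))
  expect_equal(combined_loss(p, y, loss_config(lambda_bce = 0.5)),
               (bce_loss(p, y) + dice_loss(p, y)) / 2, tolerance = 1e-12)
})

test_that("loss decreases along the segment from random prediction to target", {
  lcfg <- loss_config()
  for (seed in 1:5) {
    set.seed(seed)
    y <- array(rbinom(125, 1, 0.2), c(5, 5, 5))
    p0 <- array(runif(125, 0.05, 0.95), c(5, 5, 5))
    ts <- seq(0, 1, by = 0.25)
    losses <- vapply(ts, function(t)
      combined_loss(p0 + t * (y - p0), y, lcfg), numeric(1))
    expect_true(all(diff(losses) <= 1e-10))
  }
})

test_that("loss values stay in their ranges for arbitrary inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- array(runif(64), c(4, 4, 4))
    y <- array(rbinom(64, 1, runif(1)), c(4, 4, 4))
    expect_gte(bce_loss(p, y), 0)
    dl <- dice_loss(p, y)
    expect_true(dl >= 0 && dl <= 1)
    expect_true(is.finite(combined_loss(p, y)))
  }
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(14)
  p <- array(runif(27, 0.1, 0.9), c(3, 3, 3))
  y <- array(rbinom(27, 1, 0.4), c(3, 3, 3))
  lcfg <- loss_config(lambda_bce = 0.7)
  g <- lesionseg:::combined_loss_grad(p, y, lcfg)
  eps <- 1e-6
  for (i in c(1, 9, 27)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    num <- (combined_loss(pp, y, lcfg) - combined_loss(pm, y, lcfg)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})
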