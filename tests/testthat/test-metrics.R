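mk <- function(arr) les_mask(arr, c(1, 1, 1), "m")

test_that("DSC matches hand counts and conventions", {
  a <- array(0, c(4, 4, 4)); a[1:2, 1, 1] <- 1
  expect_equal(dsc(a, a), 1)
  b <- array(0, c(4, 4, 4)); b[4, 4, 4] <- 1
  expect_equal(dsc(a, b), 0)
  # |P| = 1 inside R with |R| = 2
  p <- array(0, c(4, 4, 4)); p[1, 1, 1] <- 1
  expect_equal(dsc(p, a), 2 / 3, tolerance = 1e-12)
  expect_equal(dsc(array(0, c(4, 4, 4)), array(0, c(4, 4, 4))), 1)
  expect_error(dsc(a, array(0, c(3, 3, 3))), "differ")
})

test_that("maximal DSC dominates the default threshold and finds rescaled masks", {
  ref <- array(0, c(5, 5, 5)); ref[2:4, 2:4, 2:4] <- 1
  pm <- ref * 0.4
  expect_equal(dsc(binarize(pm, 0.5), ref), 0)
  expect_equal(max_dsc(pm, ref), 1)
  # binary map: threshold-invariant
  expect_equal(max_dsc(ref, ref), dsc(ref, ref))
  set.seed(4)
  soft <- array(runif(125), c(5, 5, 5))
  expect_gte(max_dsc(soft, ref), dsc(binarize(soft, 0.5), ref))
  expect_error(max_dsc(soft, ref, thresholds = numeric(0)), "empty")
})

test_that("surface extraction matches enumerated solids", {
  one <- array(0, c(5, 5, 5)); one[3, 3, 3] <- 1
  expect_equal(nrow(surface_voxels(one)), 1)
  cube3 <- array(0, c(5, 5, 5)); cube3[2:4, 2:4, 2:4] <- 1
  expect_equal(nrow(surface_voxels(cube3)), 26)
  cube4 <- array(0, c(6, 6, 6)); cube4[1:4, 2:5, 2:5] <- 1  # touches border
  expect_equal(nrow(surface_voxels(cube4)), 56)
  expect_equal(nrow(surface_voxels(array(0, c(4, 4, 4)))), 0)
})

test_that("surface distances match closed forms and handle empty masks", {
  a <- array(0, c(6, 6, 6)); a[1, 1, 1] <- 1
  b <- array(0, c(6, 6, 6)); b[4, 1, 1] <- 1
  expect_equal(hausdorff_mm(a, b, c(1, 1, 1)), 3)
  expect_equal(assd_mm(a, b, c(1, 1, 1)), 3)
  expect_equal(hausdorff_mm(a, a, c(1, 1, 1)), 0)
  expect_equal(assd_mm(a, a, c(1, 1, 1)), 0)
  empty <- array(0, c(6, 6, 6))
  expect_true(is.na(hausdorff_mm(a, empty, c(1, 1, 1))))
  expect_true(is.na(assd_mm(empty, a, c(1, 1, 1))))
})

test_that("TPR and precision match voxel counts with degenerate conventions", {
  r <- array(0, c(4, 4, 4)); r[1:2, 1:2, 1] <- 1
  expect_equal(tpr(r, r), 1)
  expect_equal(precision(r, r), 1)
  p <- array(0, c(4, 4, 4)); p[1:2, 1:2, 1:2] <- 1  # superset, double size
  expect_equal(tpr(p, r), 1)
  expect_equal(precision(p, r), 0.5)
  empty <- array(0, c(4, 4, 4))
  expect_equal(tpr(empty, r), 0)
  expect_true(is.na(precision(empty, r)))
  expect_true(is.na(tpr(p, empty)))
})

test_that("micro DSC pools voxel counts across scans", {
  a <- array(0, c(4, 4, 4)); a[1:10] <- 1
  pairs1 <- list(list(pred = a, ref = a))
  expect_equal(micro_dsc(pairs1), dsc(a, a))
  # (TP,FP,FN) = (10,0,0) and (0,10,10)
  b_pred <- array(0, c(4, 4, 4)); b_pred[11:20] <- 1
  b_ref <- array(0, c(4, 4, 4)); b_ref[21:30] <- 1
  expect_equal(micro_dsc(list(list(pred = a, ref = a),
                              list(pred = b_pred, ref = b_ref))), 0.5)
  expect_equal(micro_dsc(rep(pairs1, 5)), dsc(a, a))
  expect_error(micro_dsc(list()), "empty")
})

test_that("bootstrap CI is seeded, degenerate on constants, and covers the mean", {
  expect_equal(bootstrap_ci(rep(3.5, 10), seed = 1), c(lo = 3.5, hi = 3.5))
  for (seed in 1:5) {
    set.seed(seed)
    v <- rnorm(25)
    ci <- bootstrap_ci(v, n_boot = 1000, level = 0.95, seed = seed)
    expect_lte(ci[["lo"]], mean(v))
    expect_gte(ci[["hi"]], mean(v))
  }
  expect_identical(bootstrap_ci(1:10, seed = 3), bootstrap_ci(1:10, seed = 3))
  expect_error(bootstrap_ci(numeric(0)), "empty")
})

test_that("size stratification uses quartile ranks with stable ties", {
  df <- data.frame(scan_id = sprintf("s%02d", 1:8),
                   dsc = runif(8), lesion_voxels_ref = c(5, 3, 8, 1, 9, 2, 7, 4))
  gr <- stratify_by_size(df, n_boot = 50, seed = 1)
  expect_length(gr, 4)
  expect_equal(vapply(gr, function(g) length(g$scan_ids), numeric(1)),
               rep(2, 4))
  df31 <- data.frame(scan_id = sprintf("s%02d", 1:31), dsc = runif(31),
                     lesion_voxels_ref = sample(1000, 31))
  gr31 <- stratify_by_size(df31, n_boot = 50, seed = 1)
  expect_equal(vapply(gr31, function(g) length(g$scan_ids), numeric(1)),
               c(8, 8, 8, 7))
  # ties broken by scan_id: identical inputs give identical groupings
  dft <- data.frame(scan_id = sprintf("s%02d", 8:1), dsc = runif(8),
                    lesion_voxels_ref = rep(10, 8))
  g1 <- stratify_by_size(dft, n_boot = 50, seed = 1)
  g2 <- stratify_by_size(dft, n_boot = 50, seed = 1)
  expect_identical(lapply(g1, `[[`, "scan_ids"), lapply(g2, `[[`, "scan_ids"))
  expect_equal(g1[[1]]$scan_ids, c("s01", "s02"))
  expect_error(stratify_by_size(df[1:3, ]), "at least 4")
})

test_that("DSC-size regression matches the closed-form coefficient of determination", {
  # perfectly linear in log10 size
  n <- c(10, 100, 1000, 10000)
  df <- data.frame(scan_id = letters[1:4], dsc = 0.1 * log10(n) + 0.2,
                   lesion_voxels_ref = n)
  expect_equal(as.numeric(size_dsc_regression(df)), 1, tolerance = 1e-12)
  # constant DSC
  dfc <- data.frame(scan_id = letters[1:4], dsc = rep(0.5, 4),
                    lesion_voxels_ref = n)
  expect_equal(as.numeric(size_dsc_regression(dfc)), 0)
  # 5 hand points: r^2 equals squared correlation
  df5 <- data.frame(scan_id = letters[1:5],
                    dsc = c(0.2, 0.5, 0.4, 0.8, 0.7),
                    lesion_voxels_ref = c(12, 340, 87, 5100, 960))
  expect_equal(as.numeric(size_dsc_regression(df5)),
               cor(df5$dsc, log10(df5$lesion_voxels_ref))^2,
               tolerance = 1e-12)
  # zero lesion counts excluded with a recorded count
  df0 <- rbind(df5, data.frame(scan_id = "z", dsc = 0.1,
                               lesion_voxels_ref = 0))
  r2 <- size_dsc_regression(df0)
  expect_equal(attr(r2, "n_excluded"), 1L)
  expect_equal(as.numeric(r2), as.numeric(size_dsc_regression(df5)))
})

test_that("metrics are symmetric, translation invariant, and spacing-covariant", {
  set.seed(8)
  for (i in 1:6) {
    a <- random_mask_array(c(9, 9, 9), "box")
    b <- random_mask_array(c(9, 9, 9), "box")
    expect_equal(dsc(a, b), dsc(b, a))
    expect_equal(hausdorff_mm(a, b, c(1, 1, 1)), hausdorff_mm(b, a, c(1, 1, 1)))
    expect_equal(assd_mm(a, b, c(1, 1, 1)), assd_mm(b, a, c(1, 1, 1)))
    # translate both masks by one voxel inside a larger grid
    big_a <- array(0, c(12, 12, 12)); big_b <- array(0, c(12, 12, 12))
    big_a[1:9 + 1, 1:9 + 1, 1:9 + 1] <- a
    big_b[1:9 + 1, 1:9 + 1, 1:9 + 1] <- b
    big_a2 <- array(0, c(12, 12, 12)); big_b2 <- array(0, c(12, 12, 12))
    big_a2[1:9 + 2, 1:9 + 2, 1:9 + 2] <- a
    big_b2[1:9 + 2, 1:9 + 2, 1:9 + 2] <- b
    expect_equal(dsc(big_a, big_b), dsc(big_a2, big_b2))
    expect_equal(hausdorff_mm(big_a, big_b, c(1, 1, 1)),
                 hausdorff_mm(big_a2, big_b2, c(1, 1, 1)))
    expect_equal(assd_mm(big_a, big_b, c(1, 1, 1)),
                 assd_mm(big_a2, big_b2, c(1, 1, 1)))
    # spacing scales surface distances linearly, leaves overlap metrics alone
    s <- 2.5
    expect_equal(hausdorff_mm(a, b, c(s, s, s)),
                 s * hausdorff_mm(a, b, c(1, 1, 1)), tolerance = 1e-9)
    expect_equal(assd_mm(a, b, c(s, s, s)),
                 s * assd_mm(a, b, c(1, 1, 1)), tolerance = 1e-9)
    expect_equal(tpr(a, b), tpr(big_a, big_b))
  }
})

test_that("per-scan evaluation satisfies the mDSC >= DSC invariant", {
  set.seed(10)
  ref <- mk(random_mask_array(c(10, 10, 10), "box"))
  pm <- les_probmap(pmin(pmax(ref$data * 0.7 +
                                array(runif(1000, 0, 0.3), c(10, 10, 10)),
                              0), 1), c(1, 1, 1), "m")
  row <- evaluate_scan(pm, ref)
  expect_gte(row$mdsc, row$dsc)
  expect_equal(row$lesion_voxels_ref, sum(ref$data))
})

test_that("cohort evaluation aggregates, stratifies, and excludes undefined values", {
  set.seed(12)
  cfg <- small_phantom_config()
  co <- generate_cohort(6, cfg, seed = 91)
  # fake "predictions": the truth corrupted by noise, one empty map
  pms <- lapply(seq_along(co), function(i) {
    d <- co[[i]]$mask$data
    if (i == 6) d <- d * 0
    les_probmap(pmin(pmax(d * 0.9, 0), 1), co[[i]]$mask$spacing,
                co[[i]]$scan_id)
  })
  refs <- lapply(co, `[[`, "mask")
  rep_ <- evaluate_cohort(pms, refs, n_boot = 100, seed = 5)
  expect_s3_class(rep_, "cohort_report")
  expect_equal(nrow(rep_$scans), 6)
  # scan 6 has an empty prediction: HD/ASSD undefined there
  expect_equal(rep_$summary$hd_mm$n_excluded, 1L)
  # five perfect reconstructions and one empty prediction: mean DSC = 5/6
  expect_equal(rep_$summary$dsc$mean, 5 / 6, tolerance = 1e-12)
  expect_lte(rep_$summary$dsc$lo, rep_$summary$dsc$mean)
  expect_gte(rep_$summary$dsc$hi, rep_$summary$dsc$mean)
  expect_length(rep_$size_groups, 4)
  expect_true(rep_$micro_dsc > 0.8)
  sm <- summary(rep_)
  expect_true("micro_dsc" %in% sm$metric)
})
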