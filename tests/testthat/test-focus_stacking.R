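test_that("the focus function is the windowed sum of squared deviations", {
  expect_equal(focus_function(matrix(5, 3, 3)), 0)
  expect_equal(focus_function(c(1, 3, 1, 3)), 4)       # mean 2, 4 * 1^2
  w <- matrix(runif(81), 9, 9)
  expect_equal(focus_function(w + 17.3), focus_function(w), tolerance = 1e-9)
  # the map agrees with direct evaluation away from borders
  m <- matrix(sin(1:400), 20, 20)
  fm <- focus_map(m, 5)
  expect_equal(fm[10, 10], focus_function(m[8:12, 8:12]), tolerance = 1e-9)
})

test_that("Gaussian fits locate the best-focus depth", {
  d <- c(0.1, 1:30)
  fc <- 3 * exp(-(d - 7)^2 / (2 * 2.5^2)) + 0.2
  for (m in c("nls", "fast")) {
    fit <- fit_focus_gaussian(d, fc, method = m)
    expect_false(fit$fallback)
    expect_equal(fit$dmax, 7, tolerance = 1e-6)
    expect_equal(fit$sigma, 2.5, tolerance = 1e-4)
  }
  expect_error(fit_focus_gaussian(d, rep(1, 31)), class = "ti3d_no_peak")
  expect_error(fit_focus_gaussian(1:3, 1:3), "at least 4")
})

test_that("fits survive moderate noise on the focus curve", {
  d <- c(0.1, 1:30)
  g0 <- 3 * exp(-(d - 7.3)^2 / (2 * 2.5^2)) + 0.2
  errs <- vapply(1:51, function(s) {
    fc <- g0 * (1 + transillum3d:::with_seed(s, stats::rnorm(31, sd = 0.05)))
    fit_focus_gaussian(d, pmax(fc, 0), method = "nls")$dmax - 7.3
  }, numeric(1))
  expect_lt(abs(stats::median(errs)), 0.3)
})

test_that("selectivity is the capped peak-to-residual ratio in dB", {
  d <- c(0.1, 1:30)
  fc <- 3 * exp(-(d - 7)^2 / 8) + 0.2
  curve <- fit_focus_gaussian(d, fc, method = "nls")
  curve$fc <- fc / max(fc) * 10
  curve$residual_rms <- 1
  expect_equal(selectivity(curve), 20, tolerance = 1e-9)
  # scale invariance
  curve2 <- curve
  curve2$fc <- curve$fc * 10; curve2$residual_rms <- 10
  expect_equal(selectivity(curve2), selectivity(curve))
  # perfect fit hits the cap
  curve$residual_rms <- 0
  expect_equal(selectivity(curve), 120)
})

test_that("the sharpening parameter follows its closed form", {
  expect_equal(sharpening_param(10, alpha = 2, s_th = 10), 1 / 4)
  expect_equal(sharpening_param(1e6, alpha = 2, s_th = 10), 1 / 2,
               tolerance = 1e-9)
  expect_equal(sharpening_param(11, alpha = 2, s_th = 10), ORACLE_PHI_2_10_11,
               tolerance = 1e-9)
  s <- seq(8, 22, 0.5)                 # strictly increasing around s_th
  expect_true(all(diff(sharpening_param(s, 1.5, 15)) > 0))
  expect_error(sharpening_param(10, alpha = 0), "alpha")
})

test_that("fusion weights are bounded, monotone and peak at 0.5+ on max", {
  fc <- c(0.1, 0.4, 1.0, 3.0, 0.8)
  w <- fusion_weights(fc, phi = 2)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(w[which.max(fc)], 0.5)       # fc_bar = 1 at the peak
  expect_true(all(diff(w[order(fc)]) >= 0))
  # large phi with a sharp peak concentrates the weight
  fc2 <- c(0.01, 0.02, 1, 0.02, 0.01)
  w2 <- fusion_weights(fc2, phi = 50)
  expect_gt(w2[3], 0.49)
  expect_lt(max(w2[-3]), 0.01)
  expect_warning(w0 <- fusion_weights(rep(0, 5), 1), "all-zero")
  expect_true(all(w0 == w0[1]))
})

test_that("fusion is a convex per-pixel combination of the stack", {
  g <- image_grid(16, 16, 0.1)
  imgs <- lapply(1:4, function(i) matrix(i / 4 + sin(1:256 + i) / 10, 16, 16))
  stk <- structure(list(depths = 1:4, images = imgs, grid = g, config = NULL),
                   class = "focus_stack")
  # single layer: unchanged
  stk1 <- stk; stk1$images <- imgs[1]; stk1$depths <- 1
  expect_equal(fuse(stk1, 0.37)$values, imgs[[1]])
  # uniform weights: plain mean
  expect_equal(fuse(stk, rep(1, 4))$values, Reduce(`+`, imgs) / 4,
               tolerance = 1e-12)
  # identical layers: any weights return the layer
  stki <- stk; stki$images <- rep(imgs[1], 4)
  expect_equal(fuse(stki, c(0.9, 0.1, 0.3, 0.7))$values, imgs[[1]])
  # bounds
  f <- fuse(stk, c(0.2, 0.9, 0.4, 0.1))$values
  lo <- Reduce(pmin, imgs); hi <- Reduce(pmax, imgs)
  expect_true(all(f >= lo - 1e-12 & f <= hi + 1e-12))
  # zero weights fall back to the mean
  fz <- fuse(stk, rep(0, 4))
  expect_equal(fz$values, Reduce(`+`, imgs) / 4)
  expect_true(all(attr(fz, "zero_weight")))
})

test_that("depth calibration recovers affine distortions exactly", {
  x <- seq(1, 13, 0.5)
  cal <- calibrate_depths(x, x)
  expect_equal(cal$slope, 1, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  cal2 <- calibrate_depths(x, 0.8 * x + 1)
  expect_equal(cal2$slope, 0.8, tolerance = 1e-12)
  expect_equal(cal2$intercept, 1, tolerance = 1e-12)
  expect_equal(cal2$corrected, x, tolerance = 1e-9)
  expect_error(calibrate_depths(3, 4), "at least 2")
})

test_that("the per-row blur metric measures bar widths", {
  g <- image_grid(64, 128, 0.1)
  ph <- make_cylinder_phantom(3, 5, 0, 3, 3, g)
  bm <- blur_metric_profile(ti_image(1 - 0.9 * ph$occupancy, g))
  expect_equal(stats::median(bm$fwhm[bm$ok]), 3, tolerance = 0.2)  # 2 px
  bm0 <- blur_metric_profile(ti_image(matrix(1, 64, 128), g))
  expect_false(any(bm0$ok))
})

test_that("the depth-map pipeline runs end to end on a small scene", {
  opt <- opt_tissue()
  g <- image_grid(96, 96, 0.1)
  ph <- make_cylinder_phantom(2, 7, 0, 3, 3, g)
  img <- blur_image(ph, opt, cap_radius = 4)
  dm <- estimate_depth_map(img, opt, depths = c(0.1, 1:8))
  expect_equal(dim(dm$depth), c(96L, 96L))
  expect_true(any(dm$valid))
  # fused image is a convex combination of the stack
  lo <- Reduce(pmin, dm$stack$images); hi <- Reduce(pmax, dm$stack$images)
  expect_true(all(dm$fused$values >= lo - 1e-9 & dm$fused$values <= hi + 1e-9))
  # reconstruct from it
  rec <- reconstruct_3d(dm, threshold = 0.9)
  expect_s3_class(rec, "reconstruction_3d")
  # empty segmentation warns and returns nothing
  expect_warning(r0 <- reconstruct_3d(dm, threshold = -1), "empty")
  expect_equal(nrow(r0$points), 0L)
})
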