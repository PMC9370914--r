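test_that("deconvolution config validates its parameters", {
  expect_error(deconv_config(nsr = 0), "nsr")
  expect_error(deconv_config("richardson_lucy", iterations = 0), "iterations")
  expect_equal(deconv_config()$method, "wiener")
})

test_that("a discrete delta kernel is the identity", {
  g <- image_grid(96, 96, 0.1)
  ph <- make_cylinder_phantom(2, 6, 0, 3, 3, g)
  img <- blur_image(ph, opt_tissue(), cap_radius = 3)
  dk <- rasterize_kernel(3, opt_tissue(), 0.1, support_radius = 1, tail_tol = Inf)
  dk$values <- matrix(0, nrow(dk$values), ncol(dk$values))
  dk$values[(nrow(dk$values) + 1) %/% 2, (ncol(dk$values) + 1) %/% 2] <- 1
  out <- deconvolve(img, dk)
  expect_equal(out$values, img$values, tolerance = 1e-9)
})

test_that("flat images stay flat under any kernel", {
  g <- image_grid(64, 64, 0.1)
  cst <- ti_image(matrix(0.7, 64, 64), g)
  k <- rasterize_kernel(3, opt_tissue(), 0.1, support_radius = 2.5, tail_tol = Inf)
  for (cfg in list(deconv_config(), deconv_config("richardson_lucy", iterations = 5))) {
    out <- deconvolve(cst, k, cfg)
    expect_lt(max(out$values) - min(out$values), 1e-6)
  }
})

test_that("oversized kernels and mismatched pitch are rejected", {
  g <- image_grid(48, 48, 0.1)
  img <- ti_image(matrix(1, 48, 48), g)
  k <- rasterize_kernel(3, opt_tissue(), 0.1, support_radius = 6, tail_tol = Inf)
  expect_error(deconvolve(img, k), "larger than the image")
  k2 <- rasterize_kernel(3, opt_tissue(), 0.2, support_radius = 2, tail_tol = Inf)
  expect_error(deconvolve(img, k2), "pitch")
})

test_that("deconvolution is deterministic", {
  g <- image_grid(96, 96, 0.1)
  ph <- make_cylinder_phantom(2, 6, 0, 3, 3, g)
  img <- blur_image(ph, opt_tissue(), cap_radius = 3)
  k <- rasterize_kernel(3, opt_tissue(), 0.1, support_radius = 3, tail_tol = Inf)
  expect_identical(deconvolve(img, k)$values, deconvolve(img, k)$values)
})

test_that("the depth sweep yields one layer per hypothesis depth", {
  g <- image_grid(96, 96, 0.1)
  ph <- make_cylinder_phantom(2, 6, 0, 3, 3, g)
  img <- blur_image(ph, opt_tissue(), cap_radius = 3)
  depths <- c(0.1, 1, 2, 3, 4)
  stk <- sweep_deconvolve(img, depths, opt_tissue())
  expect_length(stk$images, 5L)
  expect_equal(stk$depths, depths)
  # single-depth sweep equals a direct deconvolution with the same kernel
  stk1 <- sweep_deconvolve(img, 3, opt_tissue())
  k <- rasterize_kernel(3, opt_tissue(), 0.1,
                        support_radius = min(psf_support_radius(3, opt_tissue()),
                                             30, (48 - 1) * 0.1),
                        tail_tol = Inf)
  expect_equal(stk1$images[[1]], deconvolve(img, k)$values, tolerance = 1e-12)
  expect_error(sweep_deconvolve(img, c(3, 2), opt_tissue()), "increasing")
})

test_that("matched-depth deconvolution maximizes windowed focus", {
  opt <- opt_tissue()
  g <- image_grid(256, 256, 0.1)
  ph <- make_cylinder_phantom(3, 20, 0, 4, 4, g)
  img <- blur_image(ph, opt)
  # extend the scene with its background so kernel supports are not
  # truncated at the crop (as estimate_depth_map does internally)
  P <- 200L
  vp <- matrix(1, 256 + 2 * P, 256 + 2 * P)
  vp[P + 1:256, P + 1:256] <- img$values
  depths <- c(1:8, 10, 12)
  stk <- sweep_deconvolve(ti_image(vp, 0.1), depths, opt)
  fc <- vapply(stk$images, function(m) {
    fm <- focus_map(m[P + 1:256, P + 1:256], 9)
    mean(fm[seq(100, 156, by = 8), 114])   # bar-edge windows
  }, numeric(1))
  # the focus curve peaks within one grid step of the matched depth ...
  expect_lte(abs(depths[which.max(fc)] - 4), 1)
  # ... and clearly penalizes strongly mismatched kernels
  i4 <- which(depths == 4)
  far <- abs(depths - 4) >= 4
  expect_true(all(fc[far] < 0.8 * fc[i4]))
})
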