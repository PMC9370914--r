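test_that("effective attenuation follows the diffusion formula", {
  expect_equal(kappa_d(opt_tissue()), ORACLE_KAPPA_TISSUE, tolerance = 1e-9)
  expect_equal(kappa_d(optical_properties(1.0, 0)), 0)
  expect_equal(kappa_d(optical_properties(0.97, 0.03)), 0.3, tolerance = 1e-12)
  expect_error(optical_properties(-1, 0.01), "mu_s_prime")
  expect_error(optical_properties(1, -0.01), "mu_a")
})

test_that("PSF evaluation matches the hand-evaluated closed form", {
  opt <- opt_tissue()
  expect_equal(evaluate_psf(0, 5, opt), ORACLE_PSF_0_5, tolerance = 1e-9)
  expect_equal(evaluate_psf(0, 5, opt, parse = "r-squared"), ORACLE_PSF_0_5_R2,
               tolerance = 1e-9)
  # radial symmetry and monotone decay
  expect_equal(evaluate_psf(-3.2, 5, opt), evaluate_psf(3.2, 5, opt))
  v <- evaluate_psf(c(0, 2, 5), 5, opt)
  expect_true(v[1] > v[2] && v[2] > v[3])
  expect_true(all(is.finite(evaluate_psf(seq(0, 100, 5), 0.5, opt))))
  expect_error(evaluate_psf(1, 0, opt), "depth")
  expect_error(evaluate_psf(1, -2, opt), "depth")
})

test_that("rasterized kernels are normalized, symmetric and center-peaked", {
  opt <- opt_tissue()
  k <- rasterize_kernel(3, opt, 0.1, support_radius = 8, tail_tol = Inf)
  expect_equal(sum(k$values), 1, tolerance = 1e-9)
  expect_equal(nrow(k$values) %% 2L, 1L)
  expect_equal(k$values, k$values[nrow(k$values):1, ])      # mirror rows
  expect_equal(k$values, t(k$values))                       # transpose symmetry
  ctr <- (nrow(k$values) + 1L) %/% 2L
  expect_equal(which.max(k$values), (ctr - 1L) * nrow(k$values) + ctr)
  # shallow-depth supersampling path
  ks <- rasterize_kernel(0.15, opt, 0.1, support_radius = 3, tail_tol = Inf)
  expect_equal(sum(ks$values), 1, tolerance = 1e-9)
})

test_that("insufficient support radius fails with a suggested radius", {
  expect_error(rasterize_kernel(5, opt_tissue(), 0.1, support_radius = 5),
               "use at least")
})

test_that("kernel width grows strictly with depth and is stable in the optics", {
  opt <- opt_tissue()
  f <- vapply(c(0.5, 1, 2, 4, 8, 16, 30), psf_fwhm, numeric(1), optical = opt)
  expect_true(all(diff(f) > 0))
  expect_lt(kernel_fwhm(rasterize_kernel(2, opt, 0.1, support_radius = 12,
                                         tail_tol = Inf)),
            kernel_fwhm(rasterize_kernel(8, opt, 0.1, support_radius = 30,
                                         tail_tol = Inf)))
  # a +-20% change in either optical parameter moves the width much less
  f0 <- psf_fwhm(5, opt)
  for (fac in c(0.8, 1.2)) {
    expect_lt(abs(psf_fwhm(5, optical_properties(fac * 1.0, 0.01)) - f0) / f0, 0.2)
    expect_lt(abs(psf_fwhm(5, optical_properties(1.0, fac * 0.01)) - f0) / f0, 0.2)
  }
})

test_that("rasterization converges: halving the pitch moves FWHM < 1 coarse px", {
  opt <- opt_tissue()
  k1 <- rasterize_kernel(4, opt, 0.1, support_radius = 12, tail_tol = Inf)
  k2 <- rasterize_kernel(4, opt, 0.05, support_radius = 12, tail_tol = Inf)
  expect_lt(abs(kernel_fwhm(k1) - kernel_fwhm(k2)), 0.1)
})

test_that("kernels round-trip through TIFF + JSON sidecar", {
  k <- rasterize_kernel(3, opt_tissue(), 0.1, support_radius = 6, tail_tol = Inf)
  path <- file.path(tempdir(), "kern.tif")
  write_kernel(k, path)
  k2 <- read_kernel(path)
  expect_equal(k2$values, k$values, tolerance = 1e-6)
  expect_equal(k2$depth, k$depth)
  expect_equal(k2$optical$mu_a, k$optical$mu_a)
})
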