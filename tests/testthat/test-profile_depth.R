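test_that("Michelson contrast follows its defining ratio", {
  x <- seq(-8, 8, by = 0.1)
  p <- intensity_profile(3 - 2 * exp(-x^2 / 2), 0.1)   # Imax 3, Imin 1
  f <- profile_features(p, sigma = 0)
  expect_equal(f$cm, 0.5, tolerance = 1e-6)
  # flat profile: no dip to measure
  expect_error(profile_features(intensity_profile(rep(2, 64), 0.1)),
               class = "ti3d_feature_error")
})

test_that("FWHM of a Gaussian dip matches the closed form", {
  x <- seq(-8, 8, by = 0.1)
  p <- intensity_profile(1 - 0.5 * exp(-x^2 / 2), 0.1)  # sigma = 1 mm
  expect_equal(profile_features(p, sigma = 0)$fwhm, GAUSS_FWHM_FACTOR,
               tolerance = 1e-6)
  expect_equal(profile_features(p, sigma = 0, fwhm_method = "interp")$fwhm,
               GAUSS_FWHM_FACTOR, tolerance = 1e-3)
})

test_that("profiles extracted from images sample where they should", {
  g <- image_grid(64, 128, 0.1)
  img <- ti_image(matrix(0.8, 64, 128), g)
  prof <- extract_profile(img, c(32, 64), c(0, 1), 4)
  expect_true(all(prof$samples == 0.8))
  # blurred vertical bar: symmetric dip with minimum at the bar center
  ph <- make_cylinder_phantom(3, 5, 0, 3, 3, image_grid(64, 128, 0.1))
  bl <- blur_image(ph, opt_tissue(), cap_radius = 4)
  prof2 <- extract_profile(bl, c(32, 64.5), c(0, 1), 5)
  n <- length(prof2$samples)
  expect_lt(abs(which.min(prof2$samples) - (n + 1) / 2), 1.5)
  expect_error(extract_profile(img, c(32, 5), c(0, 1), 4), "outside")
})

test_that("lookup table is monotone and inverts its own nodes exactly", {
  lut <- small_lut()
  expect_true(all(apply(lut$cm, 2, function(cc) all(diff(cc) < 0))))
  expect_true(all(apply(lut$fwhm, 2, function(fw) all(diff(fw) > 0))))
  # node identity: features of every node map back to that node
  for (i in seq_along(lut$depths)) for (j in seq_along(lut$diameters)) {
    e <- estimate_depth_1d(c(lut$cm[i, j], lut$fwhm[i, j]), lut)
    expect_false(e$inestimable)
    expect_equal(e$depth, lut$depths[i], tolerance = 1e-6)
    expect_equal(e$diameter, lut$diameters[j], tolerance = 1e-6)
  }
})

test_that("off-grid absorbers are located between nodes", {
  lut <- small_lut()
  opt <- opt_tissue()
  # oracle: dense brute-force nearest-feature search on a 10x finer depth grid
  fine_d <- seq(4.0, 4.5, by = 0.005)
  fine_ft <- t(vapply(fine_d, function(d) {
    f <- profile_features(cylinder_profile(d, 3.0, opt))
    c(f$cm, f$fwhm)
  }, numeric(2)))
  q <- profile_features(cylinder_profile(4.25, 3.0, opt))
  s_cm <- diff(range(lut$cm)); s_fw <- diff(range(lut$fwhm))
  d2 <- ((fine_ft[, 1] - q$cm) / s_cm)^2 + ((fine_ft[, 2] - q$fwhm) / s_fw)^2
  oracle_depth <- fine_d[which.min(d2)]
  expect_equal(oracle_depth, 4.25, tolerance = 0.005)

  est <- estimate_depth_1d(q, lut)
  expect_false(est$inestimable)
  expect_equal(est$depth, 4.25, tolerance = 0.05)
  expect_equal(est$diameter, 3.0, tolerance = 0.05)
  # far outside the feature hull
  expect_true(estimate_depth_1d(c(0.99, 0.01), lut)$inestimable)
})

test_that("lookup tables round-trip through CSV bit-exactly", {
  lut <- small_lut()
  path <- file.path(tempdir(), "lut.csv")
  lut_save(lut, path)
  lut2 <- lut_load(path)
  expect_identical(lut2$cm, lut$cm)
  expect_identical(lut2$fwhm, lut$fwhm)
  expect_identical(lut2$depths, lut$depths)
  expect_equal(lut2$meta$half_length, lut$meta$half_length)
})

test_that("no cross-talk: feature pairs separate depth from diameter", {
  lut <- small_lut()
  # minimum pairwise feature-space distance across all nodes is positive
  f <- cbind(as.vector(lut$cm) / diff(range(lut$cm)),
             as.vector(lut$fwhm) / diff(range(lut$fwhm)))
  dmin <- min(stats::dist(f))
  expect_gt(dmin, 0)
})

test_that("an inclined bar is reconstructed slice by slice", {
  opt <- opt_tissue()
  g <- image_grid(370, 560, 0.1)
  ph <- make_cylinder_phantom(3, 30, 5, 3.2, 4.8, g)
  img <- blur_image(ph, opt)
  lut <- build_lookup_table(depth_range = c(2.5, 5.5), diameter_range = c(2, 4),
                            step = 0.25, optical = opt)
  rec <- reconstruct_cylinder_3d(img, lut, rows = seq(85, 285, by = 25))
  ok <- !rec$inestimable
  expect_gt(mean(ok), 0.8)
  truth <- ph$true_depth[cbind(rec$row, 280)]
  expect_lt(max(abs(rec$depth[ok & truth <= 4.2] - truth[ok & truth <= 4.2])),
            0.35)
  # estimated depth increases down the tilted bar
  expect_gt(stats::cor(rec$row[ok], rec$depth[ok]), 0.95)
  pts <- cylinder_points_3d(rec)
  expect_true(all(c("x", "y", "z") %in% names(pts)))
  expect_gt(nrow(pts), 0)
})
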