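test_that("cylinder phantom geometry follows the requested parameters", {
  g <- image_grid(360, 160, 0.1)
  ph <- make_cylinder_phantom(3.0, 30, 5, 2.2, 5.0, g)
  widths <- apply(ph$occupancy, 1, sum)
  expect_equal(max(widths), 30)                          # 3 mm at 0.1 mm/px
  expect_equal(range(ph$true_depth[ph$occupancy]), c(2.2, 5.0))
  # projected footprint = length * cos(tilt) / pitch
  expect_equal(sum(widths > 0), round(30 * cos(5 * pi / 180) / 0.1),
               tolerance = 1)
  # per-row depth rises linearly down the bar
  rows <- which(widths > 0)
  d <- ph$true_depth[cbind(rows, 80)]
  expect_true(all(diff(d) > 0))
  expect_equal(stats::cor(rows, d), 1, tolerance = 1e-12)

  ph0 <- make_cylinder_phantom(2, 10, 0, 4, 4, g)
  expect_equal(unique(ph0$true_depth[ph0$occupancy]), 4)
  expect_error(make_cylinder_phantom(3, 100, 0, 2, 2, g), "exceeds")
})

test_that("volumetric phantoms carry their depth assignment", {
  g <- image_grid(80, 80, 0.1)
  sil <- disk_silhouette(g, radius = 2)
  ph <- make_volumetric_phantom(sil, 5, g)
  expect_true(all(ph$true_depth[ph$occupancy] == 5))
  # two disjoint blobs at different depths -> bimodal depth map
  s2 <- disk_silhouette(g, 1, center = c(2, 2)) |
    disk_silhouette(g, 1, center = c(6, 6))
  dmap <- matrix(3, 80, 80); dmap[41:80, ] <- 9
  ph2 <- make_volumetric_phantom(s2, dmap, g)
  expect_setequal(unique(ph2$true_depth[ph2$occupancy]), c(3, 9))
  expect_error(make_volumetric_phantom(matrix(0, 80, 80), 5, g), "empty")
  # an arbitrary mask round-trips through save/load unchanged
  set.seed(3)
  mask <- matrix(runif(6400) < 0.2, 80, 80)
  mask[1] <- TRUE
  ph3 <- make_volumetric_phantom(mask, 4.5, g)
  p <- file.path(tempdir(), "ph.tif")
  phantom_save(ph3, p)
  back <- phantom_load(p)
  expect_identical(back$occupancy, ph3$occupancy)
  expect_equal(back$true_depth, ph3$true_depth, tolerance = 1e-6)
})

test_that("forward blur conserves intensity and reduces to plain convolution", {
  opt <- opt_tissue()
  g <- image_grid(128, 128, 0.1)
  # empty phantom -> uniform unit image
  ph0 <- make_volumetric_phantom(disk_silhouette(g, 1), 5, g)
  ph0$occupancy[] <- FALSE
  expect_equal(blur_image(ph0, opt)$values, matrix(1, 128, 128))
  # single dark pixel at depth d -> 1 - a * kernel(d)
  ph1 <- ph0; ph1$occupancy[64, 64] <- TRUE; ph1$true_depth[64, 64] <- 3
  b <- blur_image(ph1, opt, cap_radius = 5)$values
  k <- rasterize_kernel(3, opt, 0.1, support_radius = 5, tail_tol = Inf)$values
  r <- (nrow(k) - 1) / 2
  expect_equal(b[64 + (-r:r), 64 + (-r:r)], 1 - k, tolerance = 1e-9)
  # intensity conservation for a centered absorber
  ph <- make_cylinder_phantom(2, 6, 0, 4, 4, g)
  bl <- blur_image(ph, opt, cap_radius = 4)
  expect_equal(mean(bl$values), mean(1 - ph$occupancy), tolerance = 1e-3)
  # single-depth phantom == direct convolution of Io with its kernel
  io <- 1 - ph$occupancy
  kv <- rasterize_kernel(4, opt, 0.1, support_radius = 4, tail_tol = Inf)$values
  direct <- transillum3d:::conv2_reflect(io, kv)
  expect_equal(bl$values, direct, tolerance = 1e-12)
})

test_that("blurred contrast falls off with absorber depth", {
  opt <- opt_tissue()
  cms <- vapply(c(2, 4, 6, 8), function(d) {
    profile_features(cylinder_profile(d, 3, opt))$cm
  }, numeric(1))
  expect_true(all(diff(cms) < 0))
  fw <- vapply(c(2, 4, 6, 8), function(d) {
    profile_features(cylinder_profile(d, 3, opt))$fwhm
  }, numeric(1))
  expect_true(all(diff(fw) > 0))
})

test_that("the 1D cylinder profile agrees with the 2D forward model", {
  opt <- opt_tissue()
  g <- image_grid(360, 560, 0.1)
  ph <- make_cylinder_phantom(3, 30, 0, 4, 4, g)
  img <- blur_image(ph, opt)
  prof2d <- extract_profile(img, c(180, 280.5), c(0, 1), 14)
  f2 <- profile_features(prof2d)
  f1 <- profile_features(cylinder_profile(4, 3, opt, half_length = 14))
  expect_equal(f2$cm, f1$cm, tolerance = 0.03)
  expect_equal(f2$fwhm, f1$fwhm, tolerance = 0.03)
})

test_that("sensor noise is reproducible and hits the requested SNR", {
  g <- image_grid(120, 120, 0.1)
  ph <- make_cylinder_phantom(3, 10, 0, 3, 3, g)
  img <- blur_image(ph, opt_tissue(), cap_radius = 4)
  expect_identical(add_noise(img, Inf, 1), img)
  n1 <- add_noise(img, 21, seed = 7)
  n2 <- add_noise(img, 21, seed = 7)
  expect_identical(n1$values, n2$values)
  expect_false(identical(add_noise(img, 21, seed = 8)$values, n1$values))
  # recompute the SNR from the known injected field
  noise <- n1$values - img$values
  bg <- stats::median(img$values)
  snr <- 20 * log10(sqrt(mean((img$values - bg)^2)) / sqrt(mean(noise^2)))
  expect_equal(snr, 21, tolerance = 0.5)
})

test_that("background division removes a shared vignetting field", {
  g <- image_grid(64, 64, 0.1)
  flat <- matrix(1, 64, 64)
  x <- (col(flat) - 32.5) / 64; y <- (row(flat) - 32.5) / 64
  vign <- 0.6 + 0.4 * exp(-(x^2 + y^2) * 4)
  ph <- make_cylinder_phantom(2, 4, 0, 3, 3, g)
  scene <- blur_image(ph, opt_tissue(), cap_radius = 3)$values
  out <- remove_background(ti_image(scene * vign, g, "raw"),
                           ti_image(flat * vign, g, "raw"))
  expect_equal(out$values, scene, tolerance = 1e-9)
  expect_equal(out$provenance, "background_removed")
  # identical inputs -> unity; scaled inputs -> the scale
  expect_equal(remove_background(ti_image(vign, g, "raw"),
                                 ti_image(vign, g, "raw"))$values, flat)
  expect_equal(remove_background(ti_image(0.5 * vign, g, "raw"),
                                 ti_image(vign, g, "raw"))$values,
               0.5 * flat, tolerance = 1e-12)
  # floor masking
  low <- ti_image(matrix(1e-9, 64, 64), g, "raw")
  expect_warning(mres <- remove_background(ti_image(vign, g, "raw"), low),
                 "masked")
  expect_true(all(is.na(mres$values)))
})
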