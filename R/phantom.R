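#' Transillumination image container
#'
#' A 2D grid of relative transmitted intensity. After background removal the
#' background level is ~1 and absorbers appear as intensity below 1.
#'
#' @param values Numeric matrix, finite and non-negative (NA allowed for
#'   masked pixels).
#' @param grid An [image_grid()] matching `dim(values)`.
#' @param provenance One of `"raw"`, `"background_removed"`, `"synthetic"`.
#' @return A `ti_image` object.
#' @export
ti_image <- function(values, grid, provenance = "synthetic") {
  stopifnot(is.matrix(values))
  if (inherits(grid, "image_grid")) {
    if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
      stop("`values` dimensions do not match `grid`")
  } else {
    grid <- image_grid(nrow(values), ncol(values), as.numeric(grid))
  }
  if (any(values[!is.na(values)] < 0) || any(is.infinite(values)))
    stop("image values must be finite and non-negative")
  structure(list(values = values, grid = grid, provenance = provenance),
            class = "ti_image")
}

#' @export
print.ti_image <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("Transillumination image (%s): %d x %d px at %g mm/px, range [%.4g, %.4g]\n",
              x$provenance, x$grid$n_rows, x$grid$n_cols, x$grid$pitch,
              min(v), max(v)))
  invisible(x)
}

new_phantom <- function(occupancy, true_depth, geometry, grid) {
  occ <- occupancy != 0
  if (any(true_depth[occ] <= 0, na.rm = TRUE) || anyNA(true_depth[occ]))
    stop("true depth must be positive wherever the absorber is present")
  structure(list(occupancy = occ, true_depth = true_depth,
                 geometry = geometry, grid = grid),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- x$true_depth[x$occupancy]
  cat(sprintf("Phantom (%s): %d x %d px, %d absorber px, depth %s mm\n",
              x$geometry$type, x$grid$n_rows, x$grid$n_cols, sum(x$occupancy),
              if (length(d)) sprintf("[%.2f, %.2f]", min(d), max(d)) else "-"))
  invisible(x)
}

#' Save / load a phantom as a two-layer TIFF with a JSON sidecar
#'
#' Layer 1 is the occupancy mask, layer 2 the true depth map (mm; 0 where
#' unoccupied). Geometry metadata and the pixel pitch go to `<path>.json`.
#'
#' @param phantom A `phantom`.
#' @param path TIFF output path.
#' @return `path` (save) or a `phantom` (load).
#' @export
phantom_save <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  dep <- phantom$true_depth
  dep[is.na(dep)] <- 0
  dmax <- max(dep, 1)
  tiff::writeTIFF(list(phantom$occupancy * 1, dep / dmax), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(pitch = phantom$grid$pitch, depth_scale = dmax,
         geometry = phantom$geometry),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname phantom_save
#' @export
phantom_load <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  occ <- pages[[1L]] > 0.5
  dep <- pages[[2L]] * meta$depth_scale
  dep[!occ] <- NA_real_
  new_phantom(occ, dep, as.list(meta$geometry),
              image_grid(nrow(occ), ncol(occ), meta$pitch))
}

#' Cylindrical-bar phantom
#'
#' A straight cylindrical absorber viewed side-on: its shadow is a vertical
#' band of projected width equal to the diameter. The bar is inclined by
#' `tilt_deg` from the vertical *towards the observation surface*, so the
#' per-pixel true depth varies linearly along the axis from `depth_top` at
#' the top of the band to `depth_bottom` at the bottom, while the projected
#' axial footprint shortens to `length * cos(tilt)`.
#'
#' @param diameter Bar diameter, mm.
#' @param length Bar length, mm.
#' @param tilt_deg Inclination from the vertical, degrees (tilt in depth).
#' @param depth_top,depth_bottom Depths of the bar ends, mm (> 0).
#' @param grid An [image_grid()].
#' @return A `phantom`.
#' @examples
#' g <- image_grid(360, 160, 0.1)
#' ph <- make_cylinder_phantom(3.0, 30, 5, 2.2, 5.0, g)
#' @export
make_cylinder_phantom <- function(diameter, length, tilt_deg,
                                  depth_top, depth_bottom, grid) {
  stopifnot(inherits(grid, "image_grid"))
  if (diameter <= 0 || length <= 0) stop("diameter and length must be positive")
  if (depth_top <= 0 || depth_bottom <= 0) stop("depths must be positive (mm)")
  p <- grid$pitch
  footprint <- length * cos(tilt_deg * pi / 180)     # projected axial extent, mm
  n_ax <- round(footprint / p)
  n_w <- round(diameter / p)
  if (n_ax > grid$n_rows || n_w > grid$n_cols)
    stop(sprintf("bar footprint (%d x %d px) exceeds the %d x %d grid",
                 n_ax, n_w, grid$n_rows, grid$n_cols))
  r0 <- (grid$n_rows - n_ax) %/% 2L + 1L
  c0 <- (grid$n_cols - n_w) %/% 2L + 1L
  occ <- matrix(FALSE, grid$n_rows, grid$n_cols)
  occ[r0:(r0 + n_ax - 1L), c0:(c0 + n_w - 1L)] <- TRUE
  dep <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  ax_t <- if (n_ax > 1L) (seq_len(n_ax) - 1) / (n_ax - 1) else 0.5
  row_depth <- depth_top + ax_t * (depth_bottom - depth_top)
  dep[r0:(r0 + n_ax - 1L), c0:(c0 + n_w - 1L)] <- row_depth
  new_phantom(occ, dep,
              list(type = "cylinder", diameter = diameter, length = length,
                   tilt_deg = tilt_deg, depth_top = depth_top,
                   depth_bottom = depth_bottom,
                   rows = c(r0, r0 + n_ax - 1L), cols = c(c0, c0 + n_w - 1L)),
              grid)
}

#' Volumetric phantom from an arbitrary silhouette
#'
#' @param silhouette Logical/0-1 matrix matching `grid`: the absorber's
#'   projected outline.
#' @param depth Depth assignment: a positive scalar (constant depth), a
#'   matrix matching `grid`, or a `function(x_mm, y_mm)` of physical pixel
#'   center coordinates returning depths in mm.
#' @param grid An [image_grid()].
#' @return A `phantom`.
#' @export
make_volumetric_phantom <- function(silhouette, depth, grid) {
  stopifnot(inherits(grid, "image_grid"), is.matrix(silhouette))
  if (!any(silhouette != 0)) stop("silhouette is empty: no absorber pixels")
  if (nrow(silhouette) != grid$n_rows || ncol(silhouette) != grid$n_cols)
    stop("silhouette dimensions do not match grid")
  dep <- if (is.function(depth)) {
    x <- (col(silhouette) - 0.5) * grid$pitch
    y <- (row(silhouette) - 0.5) * grid$pitch
    matrix(depth(x, y), grid$n_rows, grid$n_cols)
  } else if (is.matrix(depth)) depth
  else matrix(as.numeric(depth), grid$n_rows, grid$n_cols)
  dep[silhouette == 0] <- NA_real_
  new_phantom(silhouette, dep, list(type = "volumetric"), grid)
}

#' Disk silhouette helper
#'
#' @param grid An [image_grid()].
#' @param center Physical center `c(x_mm, y_mm)`; default is the grid center.
#' @param radius Disk radius, mm.
#' @return Logical matrix.
#' @export
disk_silhouette <- function(grid, radius, center = NULL) {
  if (is.null(center))
    center <- c(grid$n_cols, grid$n_rows) * grid$pitch / 2
  x <- (col(matrix(0, grid$n_rows, grid$n_cols)) - 0.5) * grid$pitch
  y <- (row(matrix(0, grid$n_rows, grid$n_cols)) - 0.5) * grid$pitch
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

# --- convolution helpers -----------------------------------------------------

# Mirror-extend index into 1..n (tile-mirror, period 2n)
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j < n, j + 1L, 2L * n - j)
}

pad_reflect <- function(m, pr, pc) {
  m[reflect_index(seq(1L - pr, nrow(m) + pr), nrow(m)),
    reflect_index(seq(1L - pc, ncol(m) + pc), ncol(m)), drop = FALSE]
}

# FFT linear convolution, 'same' output size, input already padded as desired
fft_conv2 <- function(a, k) {
  nr <- stats::nextn(nrow(a) + nrow(k) - 1L, c(2, 3, 5))
  nc <- stats::nextn(ncol(a) + ncol(k) - 1L, c(2, 3, 5))
  A <- matrix(0, nr, nc); A[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  K <- matrix(0, nr, nc); K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (nr * nc)
  r0 <- (nrow(k) - 1L) %/% 2L; c0 <- (ncol(k) - 1L) %/% 2L
  full[r0 + seq_len(nrow(a)), c0 + seq_len(ncol(a)), drop = FALSE]
}

# Convolution with reflective boundary handling (pad, convolve, crop)
conv2_reflect <- function(img, kernel_values) {
  pr <- min((nrow(kernel_values) - 1L) %/% 2L, 4L * nrow(img))
  pc <- min((ncol(kernel_values) - 1L) %/% 2L, 4L * ncol(img))
  padded <- pad_reflect(img, pr, pc)
  out <- fft_conv2(padded, kernel_values)
  out[pr + seq_len(nrow(img)), pc + seq_len(ncol(img)), drop = FALSE]
}

# --- forward model -----------------------------------------------------------

#' Simulate the blurred transillumination image of a phantom
#'
#' Forward model: the unblurred shadow is `Io = 1 - absorptance * occupancy`
#' on a unit background; each pixel is blurred with the PSF kernel for its
#' own true depth. Depth-varying phantoms are composed by quantizing the
#' depth map into strata (default 0.1 mm), convolving each stratum's shadow
#' with its own kernel, and multiplying the resulting transmittances; a
#' single-depth phantom reduces exactly to one plain convolution.
#'
#' @param phantom A [make_cylinder_phantom()] / [make_volumetric_phantom()]
#'   phantom.
#' @param optical [optical_properties()].
#' @param absorptance Fraction of light removed along an occupied line of
#'   sight, in (0, 1]; default 1 (matte black).
#' @param depth_quantum Stratum width for depth quantization, mm.
#' @param composite How strata combine: `"additive"` (default) superposes
#'   the blurred absorption shadows linearly, `T = 1 - sum_s a * occ_s * K_s`
#'   clamped at 0; `"multiplicative"` multiplies per-stratum transmittances.
#'   Both reduce exactly to the plain convolution for a single-depth
#'   phantom. Additive is the default because a thin object does not shadow
#'   itself twice: the multiplicative cross-terms between neighbouring
#'   strata of the same absorber deflate the image contrast relative to the
#'   single-kernel model.
#' @param parse PSF parse variant, see [evaluate_psf()].
#' @param tail_tol,cap_radius Kernel truncation controls, see
#'   [rasterize_kernel()].
#' @return A `ti_image` with provenance `"synthetic"`.
#' @export
blur_image <- function(phantom, optical, absorptance = 1,
                       depth_quantum = 0.1,
                       composite = c("additive", "multiplicative"),
                       parse = "r", tail_tol = 1e-4, cap_radius = NULL) {
  composite <- match.arg(composite)
  stopifnot(inherits(phantom, "phantom"))
  optical <- as_optical(optical)
  if (absorptance <= 0 || absorptance > 1) stop("`absorptance` must be in (0, 1]")
  g <- phantom$grid
  if (!any(phantom$occupancy))
    return(ti_image(matrix(1, g$n_rows, g$n_cols), g))
  dq <- round(phantom$true_depth[phantom$occupancy] / depth_quantum) * depth_quantum
  strata <- sort(unique(dq))
  dmap <- round(phantom$true_depth / depth_quantum) * depth_quantum
  out <- matrix(1, g$n_rows, g$n_cols)
  absorbed <- matrix(0, g$n_rows, g$n_cols)
  for (d in strata) {
    occ_s <- phantom$occupancy & !is.na(dmap) & dmap == d
    kern <- rasterize_kernel(d, optical, g$pitch, tail_tol = tail_tol,
                             cap_radius = if (is.null(cap_radius)) 10 * d else cap_radius,
                             parse = parse)
    if (composite == "additive") {
      absorbed <- absorbed + conv2_reflect(absorptance * occ_s, kern$values)
    } else {
      out <- out * conv2_reflect(1 - absorptance * occ_s, kern$values)
    }
  }
  if (composite == "additive") out <- 1 - absorbed
  out[out < 0] <- 0
  ti_image(out, g)
}

#' Blurred cross-sectional profile of an infinite straight cylinder
#'
#' One-dimensional reduction of the forward model: for an absorber band that
#' is uniform along one axis, the 2D convolution with the PSF collapses to a
#' 1D convolution with the line spread function (the PSF integrated along
#' the band axis). With a box shadow of width `diameter` this is evaluated
#' exactly from the cumulative line spread \eqn{S}:
#' \deqn{I(x) = 1 - a\,[S(x + D/2) - S(x - D/2)]}
#' This is the generator used for lookup-table construction, where tens of
#' thousands of profiles are needed.
#'
#' @param depth Absorber depth, mm.
#' @param diameter Absorber (band) diameter, mm.
#' @param optical [optical_properties()].
#' @param pitch Sample spacing, mm.
#' @param half_length Profile half-length, mm (profile spans +- this).
#' @param absorptance Fraction absorbed, (0, 1].
#' @param lsf Optional precomputed [line_spread_cumulative()] for `depth`
#'   (cache for bulk generation).
#' @param parse PSF parse variant.
#' @return An [intensity_profile()].
#' @export
cylinder_profile <- function(depth, diameter, optical, pitch = 0.1,
                             half_length = 50, absorptance = 1,
                             lsf = NULL, parse = "r") {
  optical <- as_optical(optical)
  if (is.null(lsf))
    lsf <- line_spread_cumulative(depth, optical,
                                  x_max = half_length + diameter / 2 + 10,
                                  parse = parse)
  x <- seq(-half_length, half_length, by = pitch)
  Sfun <- stats::approxfun(lsf$x, lsf$S, rule = 2)
  samples <- 1 - absorptance * (Sfun(x + diameter / 2) - Sfun(x - diameter / 2))
  intensity_profile(samples, pitch, baseline = 1)
}

#' Add sensor noise at a prescribed SNR
#'
#' Adds zero-mean Gaussian noise scaled so that
#' `20 * log10(signal RMS contrast / noise RMS) = snr_db`, where the signal
#' RMS contrast is the root mean square of the deviation of the image from
#' its background level (the median intensity).
#'
#' @param image A `ti_image`.
#' @param snr_db Target signal-to-noise ratio in dB; `Inf` returns the image
#'   unchanged.
#' @param seed Integer seed; the same seed reproduces the same noise field.
#' @return A `ti_image`; the injected noise standard deviation is stored in
#'   attribute `"noise_sd"`.
#' @export
add_noise <- function(image, snr_db, seed) {
  stopifnot(inherits(image, "ti_image"), is.finite(snr_db) || is.infinite(snr_db))
  if (is.infinite(snr_db) && snr_db > 0) return(image)
  v <- image$values
  bg <- stats::median(v, na.rm = TRUE)
  signal_rms <- sqrt(mean((v - bg)^2, na.rm = TRUE))
  sd_n <- signal_rms * 10^(-snr_db / 20)
  noise <- with_seed(seed, matrix(stats::rnorm(length(v), sd = sd_n), nrow(v), ncol(v)))
  out <- v + noise
  out[out < 0] <- 0
  res <- ti_image(out, image$grid, image$provenance)
  attr(res, "noise_sd") <- sd_n
  res
}

# Run expr under a fixed RNG seed without disturbing the global RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Remove background non-uniformity by flat-field division
#'
#' Divides the image with the absorber by the image of the same scene
#' without the absorber, pixelwise; background regions become ~1.
#'
#' @param with_absorber,without_absorber `ti_image`s on the same grid.
#' @param floor Background pixels below this value are masked (NA) instead
#'   of divided; the number of masked pixels is reported in a warning.
#' @return A `ti_image` with provenance `"background_removed"`.
#' @export
remove_background <- function(with_absorber, without_absorber, floor = 1e-6) {
  stopifnot(inherits(with_absorber, "ti_image"),
            inherits(without_absorber, "ti_image"))
  if (!identical(dim(with_absorber$values), dim(without_absorber$values)))
    stop("images must share the same grid")
  bg <- without_absorber$values
  bad <- !is.na(bg) & bg < floor
  out <- with_absorber$values / bg
  out[bad] <- NA_real_
  if (any(bad))
    warning(sprintf("%d background pixels below floor %g were masked", sum(bad), floor))
  res <- ti_image(out, with_absorber$grid, "background_removed")
  attr(res, "n_masked") <- sum(bad)
  res
}
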