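#' 1D intensity profile across an absorber
#'
#' @param samples Numeric vector of intensities (>= 16 samples, finite).
#' @param pitch Sample spacing, mm.
#' @param baseline Optional background intensity estimate.
#' @return An `intensity_profile` object.
#' @export
intensity_profile <- function(samples, pitch, baseline = NULL) {
  if (length(samples) < 16L) stop("a profile needs at least 16 samples")
  if (any(!is.finite(samples))) stop("profile samples must be finite")
  if (!is.finite(pitch) || pitch <= 0) stop("`pitch` must be positive (mm)")
  structure(list(samples = as.numeric(samples), pitch = pitch,
                 baseline = baseline),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("Intensity profile: %d samples at %g mm (%.1f mm), range [%.4g, %.4g]\n",
              length(x$samples), x$pitch, length(x$samples) * x$pitch,
              min(x$samples), max(x$samples)))
  invisible(x)
}

# Discrete Gaussian smoothing, sigma in samples, reflective ends
gaussian_smooth <- function(x, sigma) {
  if (is.null(sigma) || sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- x[reflect_index(seq(1L - r, n + r), n)]
  as.numeric(stats::filter(xp, k, sides = 2))[r + seq_len(n)]
}

feature_error <- function(msg) {
  stop(errorCondition(msg, class = "ti3d_feature_error"))
}

#' Michelson contrast and FWHM of an absorption dip
#'
#' Extracts the two blur indices used for depth estimation from a 1D
#' intensity profile: the Michelson contrast
#' \eqn{C_M = (I_{max} - I_{min}) / (I_{max} + I_{min})} and the full width
#' at half maximum of the absorption dip.
#'
#' The profile is first low-pass filtered (Gaussian, `sigma` samples).
#' `Imax` is the local background plateau: the maximum of the smoothed
#' profile within a window of about six times an initial FWHM guess around
#' the dip (not a global image maximum, so the measure is invariant to
#' far-away structure). The dip is `Imax - profile`; its FWHM is measured
#' either from a Gaussian fit to the dip (`fwhm_method = "gauss"`,
#' iteratively reweighted log-quadratic regression, noise-robust) or by
#' direct linear interpolation of the half-amplitude crossings
#' (`fwhm_method = "interp"`).
#'
#' @param profile An [intensity_profile()].
#' @param sigma Low-pass Gaussian sigma in samples (0 disables smoothing).
#' @param fwhm_method `"gauss"` (default) or `"interp"`.
#' @param window_factor Analysis window half-width as a multiple of the
#'   initial FWHM guess (window length ~ 2x this factor x FWHM).
#' @return A `profile_features` object: list with `cm`, `fwhm` (mm),
#'   `imax`, `imin`, `center` (dip position, mm from first sample), `fit`
#'   (Gaussian fit parameters when used).
#' @examples
#' x <- seq(-8, 8, by = 0.1)
#' p <- intensity_profile(1 - 0.5 * exp(-x^2 / 2), 0.1)
#' f <- profile_features(p, sigma = 0)
#' f$fwhm  # ~ 2.3548 mm for unit-sigma dip
#' @export
profile_features <- function(profile, sigma = 2, fwhm_method = c("gauss", "interp"),
                             window_factor = 3) {
  stopifnot(inherits(profile, "intensity_profile"))
  fwhm_method <- match.arg(fwhm_method)
  p <- profile$pitch
  y <- gaussian_smooth(profile$samples, sigma)
  n <- length(y)
  i_min <- which.min(y)
  imax0 <- max(y); imin0 <- y[i_min]
  if (!(imin0 < imax0 - 1e-12 * max(abs(imax0), 1)))
    feature_error("no absorption dip detected (profile is flat)")

  # initial FWHM guess from half crossings w.r.t. the global max
  half0 <- imax0 - (imax0 - imin0) / 2
  w0 <- fwhm_crossings(y, i_min, half0, p)
  if (!is.finite(w0)) w0 <- n * p / 4
  r_win <- max(ceiling(window_factor * w0 / p), 8L)
  lo <- max(1L, i_min - r_win); hi <- min(n, i_min + r_win)
  yw <- y[lo:hi]
  imax <- max(yw); imin <- min(yw)
  if (!(imin < imax - 1e-12 * max(abs(imax), 1)))
    feature_error("no absorption dip detected within the analysis window")
  cm <- (imax - imin) / (imax + imin)

  iw_min <- which.min(yw)
  fit <- NULL
  if (fwhm_method == "gauss") {
    fit <- fit_dip_gaussian(yw, imax, p)
    fwhm <- fit$fwhm
    center <- (lo - 1 + fit$mu_idx - 1) * p
    if (!is.finite(fwhm) || fwhm <= 0) {
      # degenerate curvature: fall back to direct crossings
      fwhm <- fwhm_crossings(yw, iw_min, imax - (imax - imin) / 2, p)
      center <- (lo - 1 + iw_min - 1) * p
      fit$fallback <- TRUE
    }
  } else {
    fwhm <- fwhm_crossings(yw, iw_min, imax - (imax - imin) / 2, p)
    center <- (lo - 1 + iw_min - 1) * p
  }
  if (!is.finite(fwhm) || fwhm <= 0)
    feature_error("could not measure the dip width (no half-maximum crossings)")
  structure(list(cm = cm, fwhm = fwhm, imax = imax, imin = imin,
                 center = center, fit = fit, method = fwhm_method),
            class = "profile_features")
}

#' @export
print.profile_features <- function(x, ...) {
  cat(sprintf("Profile features: CM = %.5g, FWHM = %.5g mm (%s)\n",
              x$cm, x$fwhm, x$method))
  invisible(x)
}

# width (mm) at level `half` around the minimum at index i_min,
# linear interpolation of the crossings; NA when a side never crosses
fwhm_crossings <- function(y, i_min, half, pitch) {
  n <- length(y)
  right <- NA_real_
  if (i_min < n) {
    above <- which(y[(i_min + 1L):n] > half)
    if (length(above)) {
      j <- i_min + above[1L]
      right <- (j - 1L) + (half - y[j - 1L]) / (y[j] - y[j - 1L]) - i_min
    }
  }
  left <- NA_real_
  if (i_min > 1L) {
    above <- which(y[(i_min - 1L):1L] > half)
    if (length(above)) {
      j <- i_min - above[1L]
      left <- (i_min - 1L) - ((j - 1L) + (y[j] - half) / (y[j] - y[j + 1L]))
    }
  }
  (left + right) * pitch
}

# Gaussian fit to the inverted dip via iteratively reweighted log-quadratic
# regression (weights = fitted amplitude squared). Closed form per iteration:
# ln(dip) ~ a + b t + c t^2  =>  sigma^2 = -1/(2c), mu = -b/(2c).
fit_dip_gaussian <- function(y, imax, pitch, iterations = 3L) {
  dip <- imax - y
  keep <- dip > 0
  if (sum(keep) < 5L) return(list(fwhm = NA_real_, mu_idx = which.min(y)))
  t <- seq_along(y)[keep]
  z <- log(dip[keep])
  w <- dip[keep]^2
  for (it in seq_len(iterations)) {
    X <- cbind(1, t, t^2)
    XtW <- t(X * w)
    beta <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(beta) || !is.finite(beta[3L]) || beta[3L] >= 0)
      return(list(fwhm = NA_real_, mu_idx = which.min(y)))
    fitted <- exp(X %*% beta)
    w <- as.numeric(fitted)^2
  }
  sigma <- sqrt(-1 / (2 * beta[3L]))
  mu <- -beta[2L] / (2 * beta[3L])
  list(fwhm = 2 * sqrt(2 * log(2)) * sigma * pitch,
       sigma = sigma * pitch, mu_idx = mu,
       amplitude = exp(beta[1L] - beta[2L]^2 / (4 * beta[3L])),
       fallback = FALSE)
}

# Bilinear interpolation of matrix values at fractional (row, col) positions
bilinear_sample <- function(m, rows, cols) {
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  r0 <- pmin(pmax(r0, 1L), nrow(m) - 1L)
  c0 <- pmin(pmax(c0, 1L), ncol(m) - 1L)
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Extract an intensity profile along a line in the image
#'
#' Samples the image by bilinear interpolation along the line through
#' `center` in direction `direction` (typically the perpendicular to the
#' local absorber axis), at the pixel pitch.
#'
#' @param image A `ti_image`.
#' @param center Pixel position `c(row, col)` (may be fractional).
#' @param direction Direction vector `c(drow, dcol)`; normalized internally.
#' @param half_length Profile half-length, mm.
#' @return An [intensity_profile()].
#' @export
extract_profile <- function(image, center, direction, half_length) {
  stopifnot(inherits(image, "ti_image"), length(center) == 2L,
            length(direction) == 2L)
  p <- image$grid$pitch
  dir <- direction / sqrt(sum(direction^2))
  k <- seq(-round(half_length / p), round(half_length / p))
  rows <- center[1L] + k * dir[1L]
  cols <- center[2L] + k * dir[2L]
  if (any(rows < 1 | rows > image$grid$n_rows |
          cols < 1 | cols > image$grid$n_cols))
    stop("profile segment extends outside the image")
  v <- bilinear_sample(image$values, rows, cols)
  if (anyNA(v)) stop("profile crosses masked pixels")
  intensity_profile(v, p, baseline = stats::median(image$values, na.rm = TRUE))
}
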