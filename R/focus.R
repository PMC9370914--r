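#' Gray-level-variance focus function of a window
#'
#' The focus criterion: the sum (not mean) of squared deviations of the
#' window's pixels from the window mean. Larger values mean sharper content.
#'
#' @param window Numeric matrix or vector of window intensities.
#' @return Non-negative scalar.
#' @examples
#' focus_function(c(1, 3, 1, 3))  # mean 2, fc = 4
#' @export
focus_function <- function(window) {
  w <- as.numeric(window)
  sum((w - mean(w))^2)
}

#' Sliding-window focus map
#'
#' [focus_function()] evaluated for the `r` x `r` window centered on every
#' pixel (reflective padding at the borders), computed with box filters.
#'
#' @param img Numeric matrix.
#' @param r Window size, pixels.
#' @return Matrix of focus values, same size as `img`.
#' @export
focus_map <- function(img, r) {
  rl <- (r - 1L) %/% 2L; rr <- r - 1L - rl
  P <- pad_reflect2(img, c(rl, rr), c(rl, rr))
  s1 <- box_sum(P, r)
  s2 <- box_sum(P * P, r)
  fc <- s2 - s1 * s1 / (r * r)
  fc[fc < 0] <- 0
  fc
}

# sum over r x r windows; output dims = dim(P) - r + 1
box_sum <- function(P, r) {
  C <- apply(P, 2L, cumsum)
  n <- nrow(P)
  R <- C[r:n, , drop = FALSE] -
    rbind(0, C[seq_len(n - r), , drop = FALSE])
  C2 <- t(apply(R, 1L, cumsum))
  m <- ncol(P)
  C2[, r:m, drop = FALSE] -
    cbind(0, C2[, seq_len(m - r), drop = FALSE])
}

no_peak_error <- function(msg) {
  stop(errorCondition(msg, class = "ti3d_no_peak"))
}

#' Fit a Gaussian to a focus curve and locate the best-focus depth
#'
#' Least-squares fit of `a * exp(-(d - mu)^2 / (2 * sigma^2)) + c0` to the
#' focus-function samples over the hypothesis depths. The best-focus depth
#' `dmax` is the fitted peak location, clamped to the depth span extended by
#' one grid step. `method = "nls"` uses Levenberg-Marquardt least squares;
#' `method = "fast"` uses the closed-form iteratively reweighted
#' log-quadratic fit (the vectorizable path used for whole-image depth
#' maps). On non-convergence the discrete argmax is returned with
#' `fallback = TRUE`.
#'
#' @param depths Hypothesis depths, mm (>= 4 values).
#' @param fc Focus-function values, same length.
#' @param method `"nls"` or `"fast"`.
#' @return A `focus_curve` object: list with `depths`, `fc`, `amplitude`,
#'   `mu`, `sigma`, `offset`, `fitted`, `residual_rms`, `dmax`, `fallback`.
#' @export
fit_focus_gaussian <- function(depths, fc, method = c("nls", "fast")) {
  method <- match.arg(method)
  stopifnot(length(depths) == length(fc))
  if (length(depths) < 4L) stop("need at least 4 depth samples to fit")
  if (diff(range(fc)) <= 0)
    no_peak_error("focus function is flat: no best-focus peak exists")
  step <- stats::median(diff(depths))
  lo <- min(depths) - step; hi <- max(depths) + step
  fit <- if (method == "nls") fit_gauss_nls(depths, fc) else {
    f <- fit_gaussian_stack(depths, matrix(fc, nrow = 1L))
    list(a = f$amplitude[1L], mu = f$mu[1L], sigma = f$sigma[1L],
         c0 = f$offset[1L], ok = f$valid[1L])
  }
  if (is.null(fit) || !isTRUE(fit$ok) || !is.finite(fit$mu)) {
    dmax <- depths[which.max(fc)]
    return(structure(list(depths = depths, fc = fc, amplitude = NA_real_,
                          mu = NA_real_, sigma = NA_real_, offset = NA_real_,
                          fitted = rep(mean(fc), length(fc)),
                          residual_rms = stats::sd(fc), dmax = dmax,
                          fallback = TRUE),
                     class = "focus_curve"))
  }
  g <- fit$a * exp(-(depths - fit$mu)^2 / (2 * fit$sigma^2)) + fit$c0
  structure(list(depths = depths, fc = fc, amplitude = fit$a, mu = fit$mu,
                 sigma = fit$sigma, offset = fit$c0, fitted = g,
                 residual_rms = sqrt(mean((fc - g)^2)),
                 dmax = min(max(fit$mu, lo), hi), fallback = FALSE),
            class = "focus_curve")
}

fit_gauss_nls <- function(d, fc) {
  i0 <- which.max(fc)
  start <- list(a = max(fc) - min(fc), mu = d[i0],
                s = max(diff(range(d)) / 6, 1e-3), c0 = min(fc))
  fit <- tryCatch(
    minpack.lm::nlsLM(fc ~ a * exp(-(d - mu)^2 / (2 * s^2)) + c0,
                      start = start,
                      lower = c(a = 0, mu = min(d) - diff(range(d)),
                                s = 1e-6, c0 = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(a = cf[["a"]], mu = cf[["mu"]], sigma = cf[["s"]], c0 = cf[["c0"]],
       ok = TRUE)
}

#' @export
print.focus_curve <- function(x, ...) {
  cat(sprintf("Focus curve: %d depths, dmax = %.3g mm%s\n",
              length(x$depths), x$dmax,
              if (x$fallback) " (argmax fallback)" else ""))
  invisible(x)
}

# Vectorized Gaussian-with-offset fit to many focus curves at once.
# FC: n_curves x n_depths matrix. The fit is restricted to the contiguous
# run around each curve's argmax that stays above `peak_frac` of the peak
# amplitude, then solved by iteratively reweighted log-quadratic regression
# (weights = fitted^2), closed form via 3x3 normal equations. Focus curves
# are asymmetric away from the peak (slow far-depth plateaus); fitting the
# full curve would drag the peak estimate toward the plateau.
fit_gaussian_stack <- function(depths, FC, iterations = 3L, peak_frac = 0.35) {
  t1 <- depths
  np <- nrow(FC); n <- length(t1)
  imax <- max.col(FC, ties.method = "first")
  rows <- seq_len(np)
  offset <- apply(FC, 1L, min)
  Y <- FC - offset
  ymax <- Y[cbind(rows, imax)]
  # contiguous run around the argmax where the curve stays above
  # peak_frac of its amplitude
  jmat <- matrix(seq_len(n), np, n, byrow = TRUE)
  below <- Y < peak_frac * ymax
  cand_r <- jmat; cand_r[!(below & jmat > imax)] <- n + 1L
  rbound <- do.call(pmin, as.data.frame(cand_r)) - 1L
  cand_l <- jmat; cand_l[!(below & jmat < imax)] <- 0L
  lbound <- do.call(pmax, as.data.frame(cand_l)) + 1L
  mask <- jmat >= lbound & jmat <= rbound
  # log target; masked or zero entries get zero weight
  pos <- Y > 0 & mask
  Z <- matrix(0, np, n); Z[pos] <- log(Y[pos])
  W <- Y * Y * pos
  Tm <- cbind(1, t1, t1^2, t1^3, t1^4)
  Bm <- cbind(1, t1, t1^2)
  c0 <- c1 <- c2 <- rep(NA_real_, np)
  for (it in seq_len(iterations)) {
    M <- W %*% Tm                       # np x 5 moment sums
    B <- (W * Z) %*% Bm                 # np x 3 rhs
    # solve symmetric 3x3 [[m0,m1,m2],[m1,m2,m3],[m2,m3,m4]] beta = B
    m0 <- M[, 1L]; m1 <- M[, 2L]; m2 <- M[, 3L]; m3 <- M[, 4L]; m4 <- M[, 5L]
    det <- m0 * (m2 * m4 - m3 * m3) - m1 * (m1 * m4 - m3 * m2) +
      m2 * (m1 * m3 - m2 * m2)
    a11 <- m2 * m4 - m3 * m3; a12 <- m2 * m3 - m1 * m4; a13 <- m1 * m3 - m2 * m2
    a22 <- m0 * m4 - m2 * m2; a23 <- m1 * m2 - m0 * m3
    a33 <- m0 * m2 - m1 * m1
    b0 <- B[, 1L]; b1 <- B[, 2L]; b2 <- B[, 3L]
    c0 <- (a11 * b0 + a12 * b1 + a13 * b2) / det
    c1 <- (a12 * b0 + a22 * b1 + a23 * b2) / det
    c2 <- (a13 * b0 + a23 * b1 + a33 * b2) / det
    if (it < iterations) {
      G <- exp(pmin(outer(c0, rep(1, n)) + outer(c1, t1) + outer(c2, t1^2), 700))
      W <- G * G * pos
      W[!is.finite(W)] <- 0
    }
  }
  valid <- is.finite(c2) & c2 < 0 & ymax > 0
  sigma <- mu <- amp <- rep(NA_real_, np)
  sigma[valid] <- sqrt(-1 / (2 * c2[valid]))
  mu[valid] <- -c1[valid] / (2 * c2[valid])
  amp[valid] <- exp(c0[valid] - c1[valid]^2 / (4 * c2[valid]))
  list(mu = mu, sigma = sigma, amplitude = amp, offset = offset, valid = valid)
}

#' Selectivity of a focus curve
#'
#' Peak-to-residual ratio in dB:
#' `s = 20 * log10(max(fc) / RMS(fc - g))` where `g` is the Gaussian fit.
#' High selectivity marks windows whose focus curve is a clean peak (real
#' structure); low selectivity marks residual-dominated (noisy) windows.
#'
#' @param curve A `focus_curve` from [fit_focus_gaussian()].
#' @param cap Ceiling returned when the residual RMS underflows (perfect
#'   fits), dB.
#' @return Selectivity in dB.
#' @export
selectivity <- function(curve, cap = 120) {
  stopifnot(inherits(curve, "focus_curve"))
  peak <- max(curve$fc)
  rms <- curve$residual_rms
  if (!is.finite(rms) || rms <= peak * 10^(-cap / 20)) return(cap)
  min(20 * log10(peak / rms), cap)
}

#' Sharpening parameter of the fusion weights
#'
#' `phi(s) = (1 + tanh(alpha * (s - s_th))) / (2 * alpha)`: a soft gate that
#' rises from ~0 to `1/alpha` as the selectivity `s` crosses the threshold
#' `s_th`, so trustworthy focus peaks get sharp weights and noisy windows
#' get wide, smoothing weights.
#'
#' @param s Selectivity, dB (vectorized).
#' @param alpha Selectivity constant (> 0): strength of the gate.
#' @param s_th Selectivity threshold, dB.
#' @return `phi` values in (0, 1/alpha).
#' @export
sharpening_param <- function(s, alpha = 1, s_th = 22) {
  if (alpha <= 0) stop("`alpha` must be positive")
  (1 + tanh(alpha * (s - s_th))) / (2 * alpha)
}

#' Per-depth fusion weights from a focus curve
#'
#' `w(d_i) = (1 + tanh(phi * (fc_bar(d_i) - 1))) / 2` with `fc_bar` the
#' normalized focus function. With `normalization = "max"` (default) the
#' peak depth has `fc_bar = 1`, so its weight is 0.5 and rises towards 1 as
#' `phi` grows, while off-peak weights fall towards 0: sharp, selective
#' fusion. With `normalization = "sum"` (the literal normalization by the
#' sum over depths) `fc_bar` is of order `1/n` for every depth and the
#' argument `fc_bar - 1` is strongly negative throughout, which flattens the
#' weights into a near-uniform low-pass; it is provided for comparison.
#'
#' @param fc Non-negative focus-function values over the depth grid.
#' @param phi Sharpening parameter from [sharpening_param()].
#' @param normalization `"max"` or `"sum"`.
#' @return Weights in `[0, 1]`, same length as `fc`.
#' @export
fusion_weights <- function(fc, phi, normalization = c("max", "sum")) {
  normalization <- match.arg(normalization)
  if (any(fc < 0)) stop("focus values must be non-negative")
  tot <- if (normalization == "max") max(fc) else sum(fc)
  if (tot <= 0) {
    warning("all-zero focus function: uniform weights")
    return(rep(1, length(fc)))
  }
  (1 + tanh(phi * (fc / tot - 1))) / 2
}

#' Fuse a deconvolved stack into one all-in-focus image
#'
#' Per-pixel weighted mean of the stack layers normalized by the weight sum.
#' Weights may be one scalar per layer or a full per-pixel weight array.
#' Pixels whose weights sum to zero fall back to the unweighted mean and are
#' marked in the `"zero_weight"` attribute.
#'
#' @param stack A `focus_stack`.
#' @param weights Numeric vector (length = layers) or array
#'   `c(n_rows, n_cols, n_layers)` of weights in `[0, 1]`.
#' @return A `ti_image`.
#' @export
fuse <- function(stack, weights) {
  stopifnot(inherits(stack, "focus_stack"))
  n <- length(stack$images)
  nr <- stack$grid$n_rows; nc <- stack$grid$n_cols
  if (is.vector(weights) && length(weights) == n) {
    W <- lapply(weights, function(w) matrix(w, nr, nc))
  } else if (length(dim(weights)) == 3L && all(dim(weights) == c(nr, nc, n))) {
    W <- lapply(seq_len(n), function(i) weights[, , i])
  } else stop("`weights` must be one value per layer or an n_rows x n_cols x n_layers array")
  num <- den <- matrix(0, nr, nc)
  for (i in seq_len(n)) {
    num <- num + W[[i]] * stack$images[[i]]
    den <- den + W[[i]]
  }
  zero <- den <= 0
  if (any(zero)) {
    mean_img <- Reduce(`+`, stack$images) / n
    num[zero] <- mean_img[zero]
    den[zero] <- 1
  }
  out <- ti_image(num / den, stack$grid, "synthetic")
  attr(out, "zero_weight") <- zero
  out
}

#' Estimate a per-pixel depth map by focus stacking
#'
#' The full 2D pipeline: the (background-removed) image is deconvolved over
#' a grid of hypothesis depths; for every pixel, the gray-level variance of
#' the `window_r` x `window_r` window centered on it is computed in each
#' layer, the resulting focus curve is fitted with a Gaussian whose peak
#' gives the best-focus depth, and the fit quality (selectivity, dB) gates
#' per-pixel fusion weights that combine the stack into a noise-robust
#' all-in-focus image.
#'
#' @param image A `ti_image` (background ~ 1).
#' @param optical [optical_properties()].
#' @param depths Hypothesis depth grid, mm; default `c(0.1, 1:30)`.
#' @param window_r Focus window size in pixels (default 9).
#' @param alpha Selectivity constant (default 1).
#' @param s_th Selectivity threshold, dB (default 22; calibrated so that at
#'   least ~90% of pure-noise windows fall below it and get smoothing
#'   weights).
#' @param s_cap Selectivity ceiling, dB.
#' @param normalization Focus normalization in the weights, see
#'   [fusion_weights()].
#' @param config [deconv_config()].
#' @param stride Window stride in pixels; 1 (default) gives every pixel its
#'   own window, larger values subsample for speed.
#' @param pad_mm Scene-extension margin, mm: before the sweep the image is
#'   padded with its background level so that wide PSF supports are not
#'   truncated at the crop boundary (the physical scene continues beyond the
#'   recorded frame). 0 disables.
#' @param parse PSF parse variant.
#' @return A `depth_map` object: list with `depth` (matrix, mm),
#'   `selectivity` (matrix, dB), `valid` (logical matrix), `fused`
#'   (`ti_image`), `stack`, and the parameters.
#' @export
estimate_depth_map <- function(image, optical, depths = c(0.1, 1:30),
                               window_r = 9L, alpha = 1, s_th = 22,
                               s_cap = 120, normalization = "max",
                               config = deconv_config(), stride = 1L,
                               pad_mm = 20, parse = "r") {
  stopifnot(inherits(image, "ti_image"), window_r >= 3L)
  optical <- as_optical(optical)
  pad_px <- round(pad_mm / image$grid$pitch)
  if (pad_px > 0L) {
    bg <- stats::median(image$values, na.rm = TRUE)
    vp <- matrix(bg, image$grid$n_rows + 2L * pad_px,
                 image$grid$n_cols + 2L * pad_px)
    vp[pad_px + seq_len(image$grid$n_rows),
       pad_px + seq_len(image$grid$n_cols)] <- image$values
    padded <- ti_image(vp, image$grid$pitch, image$provenance)
    stack <- sweep_deconvolve(padded, depths, optical, config, parse = parse)
    stack$images <- lapply(stack$images, function(m)
      m[pad_px + seq_len(image$grid$n_rows),
        pad_px + seq_len(image$grid$n_cols), drop = FALSE])
    stack$grid <- image$grid
  } else {
    stack <- sweep_deconvolve(image, depths, optical, config, parse = parse)
  }
  n <- length(depths)
  nr <- image$grid$n_rows; nc <- image$grid$n_cols
  ri <- seq(1L, nr, by = stride); ci <- seq(1L, nc, by = stride)
  FC <- matrix(0, length(ri) * length(ci), n)
  for (i in seq_len(n)) {
    fm <- focus_map(stack$images[[i]], window_r)
    FC[, i] <- as.vector(fm[ri, ci])
  }
  fit <- fit_gaussian_stack(depths, FC)
  step <- stats::median(diff(depths))
  dmax <- pmin(pmax(fit$mu, min(depths) - step), max(depths) + step)
  # argmax fallback where the log-quadratic fit has no concave peak
  fallback <- !fit$valid
  if (any(fallback))
    dmax[fallback] <- depths[max.col(FC[fallback, , drop = FALSE],
                                     ties.method = "first")]
  # selectivity from the fit residuals
  G <- matrix(NA_real_, nrow(FC), n)
  v <- fit$valid
  if (any(v)) {
    E <- exp(-(outer(fit$mu[v], depths, `-`))^2 / (2 * fit$sigma[v]^2))
    G[v, ] <- fit$amplitude[v] * E + fit$offset[v]
  }
  peak <- apply(FC, 1L, max)
  rms <- sqrt(rowMeans((FC - G)^2))
  s <- rep(s_cap, nrow(FC))
  ok <- is.finite(rms) & rms > 0 & peak > 0
  s[ok] <- pmin(20 * log10(peak[ok] / rms[ok]), s_cap)
  s[!v] <- 0
  phi <- sharpening_param(s, alpha, s_th)
  # per-pixel fusion weights over the stack
  fcn <- FC / pmax(if (normalization == "max") peak else rowSums(FC), 1e-300)
  Wp <- (1 + tanh(phi * (fcn - 1))) / 2
  flat <- peak <= 0
  Wp[flat, ] <- 1
  Warr <- array(0, dim = c(length(ri), length(ci), n))
  for (i in seq_len(n)) Warr[, , i] <- matrix(Wp[, i], length(ri), length(ci))
  if (stride == 1L) {
    fused <- fuse(stack, Warr)
  } else {
    sub_stack <- stack
    sub_stack$images <- lapply(stack$images, function(m) m[ri, ci, drop = FALSE])
    sub_stack$grid <- image_grid(length(ri), length(ci), image$grid$pitch * stride)
    fused <- fuse(sub_stack, Warr)
  }
  structure(list(
    depth = matrix(dmax, length(ri), length(ci)),
    selectivity = matrix(s, length(ri), length(ci)),
    valid = matrix(v & peak > 0, length(ri), length(ci)),
    fused = fused, stack = stack,
    rows = ri, cols = ci,
    params = list(depths = depths, window_r = window_r, alpha = alpha,
                  s_th = s_th, s_cap = s_cap, normalization = normalization,
                  stride = stride, config = config)),
    class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  d <- x$depth[x$valid]
  cat(sprintf("Depth map: %d x %d px, %.1f%% valid, depth range [%.2f, %.2f] mm\n",
              nrow(x$depth), ncol(x$depth), 100 * mean(x$valid),
              if (length(d)) min(d) else NA, if (length(d)) max(d) else NA))
  invisible(x)
}

#' Linear calibration of estimated against given depths
#'
#' Ordinary least squares of the estimated depth on the given depth;
#' corrected estimates are `(estimated - intercept) / slope`.
#'
#' @param given,estimated Paired depths, mm (>= 2 distinct given values).
#' @return List with `slope`, `intercept`, `r_squared`, `corrected`.
#' @export
calibrate_depths <- function(given, estimated) {
  stopifnot(length(given) == length(estimated))
  keep <- is.finite(given) & is.finite(estimated)
  given <- given[keep]; estimated <- estimated[keep]
  if (length(unique(given)) < 2L)
    stop("calibration needs at least 2 distinct given depths")
  fit <- stats::lm(estimated ~ given)
  cf <- stats::coef(fit)
  if (abs(cf[[2L]]) < 1e-12) stop("degenerate calibration: zero slope")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((estimated - mean(estimated))^2)
  list(slope = cf[[2L]], intercept = cf[[1L]],
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       corrected = (estimated - cf[[1L]]) / cf[[2L]])
}

#' Per-row blur metric: FWHM of each horizontal profile
#'
#' Measures the absorber image blur row by row as the FWHM of the
#' horizontal intensity profile, for before/after comparisons of the
#' focus-stacking result. Rows without a detectable dip are masked.
#'
#' @param image A `ti_image` containing a near-vertical curvilinear
#'   absorber.
#' @param sigma Smoothing for the per-row profile, samples.
#' @param min_dip Minimum relative dip for a row to be measured.
#' @return data.frame with `row`, `fwhm` (mm), `ok`.
#' @export
blur_metric_profile <- function(image, sigma = 2, min_dip = 0.02) {
  stopifnot(inherits(image, "ti_image"))
  v <- image$values
  p <- image$grid$pitch
  out <- data.frame(row = seq_len(nrow(v)), fwhm = NA_real_, ok = FALSE)
  for (r in seq_len(nrow(v))) {
    y <- gaussian_smooth(v[r, ], sigma)
    bg <- stats::median(y); dip <- bg - min(y)
    if (!is.finite(dip) || dip < min_dip * bg) next
    i_min <- which.min(y)
    w <- fwhm_crossings(y, i_min, max(y) - (max(y) - min(y)) / 2, p)
    if (is.finite(w)) { out$fwhm[r] <- w; out$ok[r] <- TRUE }
  }
  out
}

#' Reconstruct the absorber in 3D from a depth map and fused image
#'
#' Absorber pixels (fused intensity below `threshold`) are placed at their
#' estimated depths, yielding a 3D point cloud (x, y in image mm, z =
#' depth mm) with per-point intensity.
#'
#' @param depth_map A `depth_map` from [estimate_depth_map()].
#' @param threshold Segmentation threshold on the fused intensity.
#' @return A `reconstruction_3d`: list with `points` (data.frame `x`, `y`,
#'   `z`, `intensity`) and `mask` (logical matrix).
#' @export
reconstruct_3d <- function(depth_map, threshold = 0.9) {
  stopifnot(inherits(depth_map, "depth_map"))
  fused <- depth_map$fused$values
  mask <- fused < threshold & depth_map$valid
  if (!any(mask)) {
    warning("empty segmentation: no pixel below the threshold")
    return(structure(list(points = data.frame(x = numeric(0), y = numeric(0),
                                              z = numeric(0), intensity = numeric(0)),
                          mask = mask, threshold = threshold),
                     class = "reconstruction_3d"))
  }
  p <- depth_map$fused$grid$pitch
  idx <- which(mask, arr.ind = TRUE)
  structure(list(points = data.frame(
    x = (idx[, 2L] - 0.5) * p,
    y = (idx[, 1L] - 0.5) * p,
    z = depth_map$depth[mask],
    intensity = fused[mask]),
    mask = mask, threshold = threshold),
    class = "reconstruction_3d")
}

#' @export
print.reconstruction_3d <- function(x, ...) {
  cat(sprintf("3D reconstruction: %d points, z range [%.2f, %.2f] mm\n",
              nrow(x$points),
              if (nrow(x$points)) min(x$points$z) else NA,
              if (nrow(x$points)) max(x$points$z) else NA))
  invisible(x)
}
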