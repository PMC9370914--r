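#' Build the (depth x diameter) lookup table of profile features
#'
#' For every node of a regular (depth, diameter) grid, generates the
#' noise-free blurred profile of an infinite straight cylindrical absorber
#' (via [cylinder_profile()]) and stores its Michelson contrast and FWHM.
#' Along each diameter column the contrast must decrease and the FWHM
#' increase with depth (the one-to-one correspondence that makes the table
#' invertible); violations are counted and reported.
#'
#' @param depth_range,diameter_range Length-2 ranges in mm.
#' @param step Grid step, mm (same for both axes).
#' @param optical [optical_properties()].
#' @param pitch Profile sample spacing, mm/px.
#' @param half_length Profile half-length, mm.
#' @param absorptance Absorber absorptance in (0, 1].
#' @param sigma,fwhm_method,window_factor Feature extraction settings, see
#'   [profile_features()].
#' @param parse PSF parse variant.
#' @param verbose Print progress.
#' @return A `lookup_table`: list with `depths`, `diameters`, `cm`, `fwhm`
#'   (matrices indexed depth x diameter) and `meta`.
#' @export
build_lookup_table <- function(depth_range = c(1, 10), diameter_range = c(1, 10),
                               step = 0.1, optical = optical_properties(1.0, 0.01),
                               pitch = 0.1, half_length = 50, absorptance = 1,
                               sigma = 2, fwhm_method = "gauss",
                               window_factor = 3, parse = "r", verbose = FALSE) {
  stopifnot(step > 0, depth_range[1] > 0, diameter_range[1] > 0)
  optical <- as_optical(optical)
  depths <- seq(depth_range[1], depth_range[2], by = step)
  diameters <- seq(diameter_range[1], diameter_range[2], by = step)
  cm <- fwhm <- matrix(NA_real_, length(depths), length(diameters))
  x_max <- half_length + max(diameters) / 2 + 10
  for (i in seq_along(depths)) {
    lsf <- line_spread_cumulative(depths[i], optical, x_max = x_max, parse = parse)
    for (j in seq_along(diameters)) {
      prof <- cylinder_profile(depths[i], diameters[j], optical, pitch = pitch,
                               half_length = half_length,
                               absorptance = absorptance, lsf = lsf, parse = parse)
      ft <- tryCatch(profile_features(prof, sigma = sigma,
                                      fwhm_method = fwhm_method,
                                      window_factor = window_factor),
                     ti3d_feature_error = function(e) {
                       stop(sprintf("feature extraction failed at node depth=%.3g, diameter=%.3g: %s",
                                    depths[i], diameters[j], conditionMessage(e)))
                     })
      cm[i, j] <- ft$cm; fwhm[i, j] <- ft$fwhm
    }
    if (verbose && i %% 10L == 0L)
      message(sprintf("lookup table: depth %d/%d", i, length(depths)))
  }
  viol_cm <- sum(apply(cm, 2L, function(col) sum(diff(col) >= 0)))
  viol_fw <- sum(apply(fwhm, 2L, function(col) sum(diff(col) <= 0)))
  if (viol_cm + viol_fw > 0L)
    warning(sprintf("lookup table monotonicity violations: %d (contrast), %d (FWHM)",
                    viol_cm, viol_fw))
  structure(list(depths = depths, diameters = diameters, cm = cm, fwhm = fwhm,
                 meta = list(optical = optical, pitch = pitch,
                             half_length = half_length, absorptance = absorptance,
                             sigma = sigma, fwhm_method = fwhm_method,
                             window_factor = window_factor, parse = parse,
                             monotonicity_violations = c(cm = viol_cm, fwhm = viol_fw))),
            class = "lookup_table")
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("Lookup table: %d depths [%g, %g] x %d diameters [%g, %g] mm\n",
              length(x$depths), min(x$depths), max(x$depths),
              length(x$diameters), min(x$diameters), max(x$diameters)))
  cat(sprintf("  CM range [%.4g, %.4g], FWHM range [%.4g, %.4g] mm\n",
              min(x$cm), max(x$cm), min(x$fwhm), max(x$fwhm)))
  invisible(x)
}

#' Save / load a lookup table as CSV (long format) plus JSON metadata
#'
#' Values are written with full double precision so that a save/load round
#' trip is bit-exact.
#'
#' @param lut A `lookup_table`.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return `path` (save) or a `lookup_table` (load).
#' @export
lut_save <- function(lut, path) {
  stopifnot(inherits(lut, "lookup_table"))
  grid <- expand.grid(depth = lut$depths, diameter = lut$diameters,
                      KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(depth = sprintf("%.17g", grid$depth),
                   diameter = sprintf("%.17g", grid$diameter),
                   cm = sprintf("%.17g", as.vector(lut$cm)),
                   fwhm = sprintf("%.17g", as.vector(lut$fwhm)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- lut$meta
  meta$optical <- list(mu_s_prime = meta$optical$mu_s_prime, mu_a = meta$optical$mu_a)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname lut_save
#' @export
lut_load <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$optical <- optical_properties(meta$optical$mu_s_prime, meta$optical$mu_a)
  depths <- sort(unique(df$depth)); diameters <- sort(unique(df$diameter))
  o <- order(df$diameter, df$depth)
  structure(list(depths = depths, diameters = diameters,
                 cm = matrix(df$cm[o], length(depths), length(diameters)),
                 fwhm = matrix(df$fwhm[o], length(depths), length(diameters)),
                 meta = meta),
            class = "lookup_table")
}

# Inverse bilinear mapping: solve q = bilinear(u, v; corners) by Newton.
# corners: 2x4 matrix, columns F00 F10 F01 F11 (u along depth, v along diam).
# Returns c(u, v) or NULL when the iteration leaves the cell.
invert_bilinear <- function(q, f00, f10, f01, f11, tol = 1e-12) {
  uv <- c(0.5, 0.5)
  for (it in 1:25) {
    u <- uv[1L]; v <- uv[2L]
    Fv <- (1 - u) * (1 - v) * f00 + u * (1 - v) * f10 + (1 - u) * v * f01 + u * v * f11 - q
    if (sum(Fv^2) < tol^2) break
    J <- cbind((1 - v) * (f10 - f00) + v * (f11 - f01),
               (1 - u) * (f01 - f00) + u * (f11 - f10))
    det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    if (!is.finite(det) || abs(det) < 1e-300) return(NULL)
    duv <- c(J[2, 2] * Fv[1L] - J[1, 2] * Fv[2L],
             -J[2, 1] * Fv[1L] + J[1, 1] * Fv[2L]) / det
    uv <- uv - duv
    if (any(!is.finite(uv)) || any(uv < -1) || any(uv > 2)) return(NULL)
  }
  uv
}

#' Estimate depth and diameter from profile features via the lookup table
#'
#' Locates the grid cell of the lookup table whose image in (contrast, FWHM)
#' feature space encloses the query, and linearly interpolates the depths
#' and diameters of the cell's four nodes (inverse bilinear interpolation).
#' When no enclosing cell exists near the query but the query is inside the
#' table's feature range, a local linear model through the four nearest
#' nodes is used and flagged. Queries outside the feature-space hull are
#' returned as inestimable; this is a value, not an error.
#'
#' @param features A [profile_features()] object, or `c(cm, fwhm)`.
#' @param lut A `lookup_table`.
#' @return A `depth_estimate_1d`: list with `depth`, `diameter` (mm; NA when
#'   inestimable), `inestimable` flag, `residual` (feature-space distance of
#'   the reconstruction) and `method` (`"cell"`, `"nearest4"` or `"none"`).
#' @export
estimate_depth_1d <- function(features, lut) {
  if (inherits(features, "profile_features"))
    features <- c(features$cm, features$fwhm)
  res <- estimate_depth_1d_batch(features[1L], features[2L], lut)
  structure(list(depth = res$depth[1L], diameter = res$diameter[1L],
                 inestimable = res$inestimable[1L], residual = res$residual[1L],
                 method = res$method[1L]),
            class = "depth_estimate_1d")
}

#' @export
print.depth_estimate_1d <- function(x, ...) {
  if (x$inestimable) cat("Depth estimate: inestimable\n")
  else cat(sprintf("Depth estimate: depth %.4g mm, diameter %.4g mm (%s)\n",
                   x$depth, x$diameter, x$method))
  invisible(x)
}

#' Vectorized lookup-table inversion
#'
#' @param cm,fwhm Feature vectors (same length).
#' @param lut A `lookup_table`.
#' @return A data.frame with columns `depth`, `diameter`, `inestimable`,
#'   `residual`, `method`.
#' @export
estimate_depth_1d_batch <- function(cm, fwhm, lut) {
  stopifnot(inherits(lut, "lookup_table"), length(cm) == length(fwhm))
  nd <- length(lut$depths); nD <- length(lut$diameters)
  s_cm <- max(diff(range(lut$cm)), 1e-12)
  s_fw <- max(diff(range(lut$fwhm)), 1e-12)
  node_cm <- as.vector(lut$cm) / s_cm
  node_fw <- as.vector(lut$fwhm) / s_fw
  nq <- length(cm)
  nearest <- integer(nq)
  # chunked nearest-node search in scaled feature space
  chunk <- 512L
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    d2 <- outer(cm[s:e] / s_cm, node_cm, `-`)^2 + outer(fwhm[s:e] / s_fw, node_fw, `-`)^2
    nearest[s:e] <- max.col(-d2, ties.method = "first")
  }
  dstep <- if (nd > 1L) lut$depths[2L] - lut$depths[1L] else 1
  Dstep <- if (nD > 1L) lut$diameters[2L] - lut$diameters[1L] else 1
  depth_out <- diam_out <- resid_out <- rep(NA_real_, nq)
  inest <- rep(TRUE, nq)
  method <- rep("none", nq)
  cmm <- lut$cm; fwm <- lut$fwhm
  for (q in seq_len(nq)) {
    ni <- (nearest[q] - 1L) %% nd + 1L
    nj <- (nearest[q] - 1L) %/% nd + 1L
    qv <- c(cm[q], fwhm[q])
    found <- FALSE
    for (ring in 1:2) {
      is <- max(1L, ni - ring):min(nd - 1L, ni + ring - 1L)
      js <- max(1L, nj - ring):min(nD - 1L, nj + ring - 1L)
      for (i in is) for (j in js) {
        uv <- invert_bilinear(qv,
                              c(cmm[i, j], fwm[i, j]),
                              c(cmm[i + 1L, j], fwm[i + 1L, j]),
                              c(cmm[i, j + 1L], fwm[i, j + 1L]),
                              c(cmm[i + 1L, j + 1L], fwm[i + 1L, j + 1L]))
        if (!is.null(uv) && all(uv > -1e-6) && all(uv < 1 + 1e-6)) {
          u <- min(max(uv[1L], 0), 1); v <- min(max(uv[2L], 0), 1)
          depth_out[q] <- lut$depths[i] + u * dstep
          diam_out[q] <- lut$diameters[j] + v * Dstep
          resid_out[q] <- 0
          inest[q] <- FALSE; method[q] <- "cell"
          found <- TRUE; break
        }
      }
      if (found) break
    }
    if (!found) {
      # local linear model through the four nearest nodes (non-convex cells)
      d2 <- (node_cm - qv[1L] / s_cm)^2 + (node_fw - qv[2L] / s_fw)^2
      idx <- order(d2)[1:4]
      ii <- (idx - 1L) %% nd + 1L; jj <- (idx - 1L) %/% nd + 1L
      X <- cbind(1, as.vector(cmm)[idx] / s_cm, as.vector(fwm)[idx] / s_fw)
      fit_d <- tryCatch(qr.solve(X, lut$depths[ii]), error = function(e) NULL)
      fit_D <- tryCatch(qr.solve(X, lut$diameters[jj]), error = function(e) NULL)
      if (!is.null(fit_d) && !is.null(fit_D)) {
        dd <- sum(c(1, qv[1L] / s_cm, qv[2L] / s_fw) * fit_d)
        DD <- sum(c(1, qv[1L] / s_cm, qv[2L] / s_fw) * fit_D)
        margin <- 0.5
        if (dd >= min(lut$depths) - margin * dstep && dd <= max(lut$depths) + margin * dstep &&
            DD >= min(lut$diameters) - margin * Dstep && DD <= max(lut$diameters) + margin * Dstep) {
          depth_out[q] <- dd; diam_out[q] <- DD
          resid_out[q] <- sqrt(min(d2))
          inest[q] <- FALSE; method[q] <- "nearest4"
        }
      }
    }
  }
  data.frame(depth = depth_out, diameter = diam_out, inestimable = inest,
             residual = resid_out, method = method, stringsAsFactors = FALSE)
}

#' Reconstruct a curvilinear absorber in 3D from a single blurred image
#'
#' Slices the image row by row across a (near-vertical) curvilinear
#' absorber: each row's intensity profile perpendicular to the absorber axis
#' is reduced to (contrast, FWHM) and inverted through the lookup table to a
#' depth and diameter, giving a circular cross-section per slice. Slices
#' whose features cannot be extracted or fall outside the table are emitted
#' as gaps (`inestimable = TRUE`).
#'
#' @param image A `ti_image` (background-removed or synthetic).
#' @param lut A `lookup_table`.
#' @param rows Row indices to slice; default all rows with a detectable dip.
#' @param half_length Profile half-length, mm; default reaches as far as the
#'   image allows around the absorber.
#' @param sigma,fwhm_method,window_factor Feature settings, see
#'   [profile_features()].
#' @param min_dip Minimum dip amplitude (relative to background) for a row
#'   to count as containing the absorber.
#' @return A `cylinder_reconstruction`: data.frame with one row per slice
#'   (`row`, `y_mm`, `center_col`, `center_x_mm`, `cm`, `fwhm`, `depth`,
#'   `diameter`, `inestimable`, `method`).
#' @export
reconstruct_cylinder_3d <- function(image, lut, rows = NULL, half_length = NULL,
                                    sigma = 2, fwhm_method = "gauss",
                                    window_factor = 3, min_dip = 0.05) {
  stopifnot(inherits(image, "ti_image"), inherits(lut, "lookup_table"))
  v <- image$values
  p <- image$grid$pitch
  if (is.null(half_length))
    half_length <- (floor((ncol(v) - 1) / 2) - 1) * p
  # locate the absorber column band from the column-mean dip
  colprof <- colMeans(v, na.rm = TRUE)
  c_global <- which.min(gaussian_smooth(colprof, 2))
  if (is.null(rows)) {
    row_min <- apply(v, 1L, min, na.rm = TRUE)
    row_bg <- apply(v, 1L, stats::median, na.rm = TRUE)
    rows <- which(row_bg - row_min > min_dip * row_bg)
    if (!length(rows)) stop("no absorber detected: no row has a sufficient dip")
  }
  out <- data.frame(row = rows, y_mm = (rows - 0.5) * p,
                    center_col = NA_real_, center_x_mm = NA_real_,
                    cm = NA_real_, fwhm = NA_real_,
                    depth = NA_real_, diameter = NA_real_,
                    inestimable = TRUE, method = "none",
                    stringsAsFactors = FALSE)
  for (k in seq_along(rows)) {
    r <- rows[k]
    prof_try <- tryCatch({
      sm <- gaussian_smooth(v[r, ], sigma)
      # track the dip near the global band center
      search <- max(1L, c_global - 50L):min(ncol(v), c_global + 50L)
      cc <- search[which.min(sm[search])]
      hl <- min(half_length, (cc - 1 - 1) * p, (ncol(v) - cc - 1) * p)
      if (hl < 16 * p) stop("absorber too close to the image edge")
      profile <- extract_profile(image, c(r, cc), c(0, 1), hl)
      ft <- profile_features(profile, sigma = sigma, fwhm_method = fwhm_method,
                             window_factor = window_factor)
      list(cc = cc, ft = ft)
    }, error = function(e) NULL)
    if (is.null(prof_try)) next
    out$center_col[k] <- prof_try$cc
    out$center_x_mm[k] <- (prof_try$cc - 0.5) * p
    out$cm[k] <- prof_try$ft$cm
    out$fwhm[k] <- prof_try$ft$fwhm
    est <- estimate_depth_1d(prof_try$ft, lut)
    out$depth[k] <- est$depth
    out$diameter[k] <- est$diameter
    out$inestimable[k] <- est$inestimable
    out$method[k] <- est$method
  }
  class(out) <- c("cylinder_reconstruction", class(out))
  out
}

#' Turn per-slice circular cross-sections into a 3D point cloud
#'
#' @param rec A `cylinder_reconstruction`.
#' @param n_theta Points per circle.
#' @return data.frame with columns `x`, `y`, `z` (mm); `z` is depth.
#' @export
cylinder_points_3d <- function(rec, n_theta = 24L) {
  rec <- rec[!rec$inestimable, , drop = FALSE]
  if (!nrow(rec)) return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-1L]
  do.call(rbind, lapply(seq_len(nrow(rec)), function(k) {
    rad <- rec$diameter[k] / 2
    data.frame(x = rec$center_x_mm[k] + rad * cos(th),
               y = rec$y_mm[k],
               z = rec$depth[k] + rad * (1 + sin(th)))
  }))
}

#' Simulation study of lookup-table depth estimation accuracy
#'
#' Builds a lookup table, generates a noise-free (or noisy) blurred profile
#' for every combination of a test diameter and depth grid, estimates each
#' profile through the table, and summarizes the error statistics. The
#' default test grid (diameters 1.0--10 mm in 0.5 mm steps, depths
#' 0.1--10 mm in 0.01 mm steps) contains 19 x 991 = 18,829 combinations;
#' combinations coinciding with table nodes are counted separately and the
#' summary reports statistics both over the full grid and with those
#' excluded.
#'
#' @param lut A prebuilt `lookup_table`, or `NULL` to build from `lut_spec`.
#' @param lut_spec List of [build_lookup_table()] arguments. The default
#'   extends the table down to 0.1 mm depth so the whole test depth range is
#'   interpolable.
#' @param test_diameters,test_depths Test grids, mm.
#' @param snr_db Per-profile sensor noise level; `Inf` (default) means
#'   noise-free.
#' @param seed Base RNG seed for the noise fields.
#' @param verbose Print progress.
#' @return A `simulation_study` object: list with `results` (per-profile
#'   data.frame) and `summary` (named list of statistics).
#' @export
simulation_study <- function(lut = NULL,
                             lut_spec = list(depth_range = c(0.1, 10),
                                             diameter_range = c(1, 10),
                                             step = 0.1),
                             test_diameters = seq(1, 10, by = 0.5),
                             test_depths = seq(0.1, 10, by = 0.01),
                             snr_db = Inf, seed = 1, verbose = FALSE) {
  if (is.null(lut)) {
    if (verbose) message("building lookup table ...")
    lut <- do.call(build_lookup_table, lut_spec)
  }
  m <- lut$meta
  optical <- m$optical
  n_dia <- length(test_diameters); n_dep <- length(test_depths)
  res <- data.frame(depth_true = rep(test_depths, each = n_dia),
                    diameter_true = rep(test_diameters, times = n_dep),
                    cm = NA_real_, fwhm = NA_real_, feature_ok = TRUE)
  x_max <- m$half_length + max(test_diameters) / 2 + 10
  row0 <- 0L
  for (i in seq_along(test_depths)) {
    lsf <- line_spread_cumulative(test_depths[i], optical, x_max = x_max,
                                  parse = m$parse)
    for (j in seq_along(test_diameters)) {
      prof <- cylinder_profile(test_depths[i], test_diameters[j], optical,
                               pitch = m$pitch, half_length = m$half_length,
                               absorptance = m$absorptance, lsf = lsf,
                               parse = m$parse)
      if (is.finite(snr_db)) {
        s <- prof$samples
        sd_n <- sqrt(mean((s - stats::median(s))^2)) * 10^(-snr_db / 20)
        s <- s + with_seed(seed + row0 + j,
                           stats::rnorm(length(s), sd = sd_n))
        prof$samples <- pmax(s, 0)
      }
      ft <- tryCatch(profile_features(prof, sigma = m$sigma,
                                      fwhm_method = m$fwhm_method,
                                      window_factor = m$window_factor),
                     error = function(e) NULL)
      if (is.null(ft)) res$feature_ok[row0 + j] <- FALSE
      else { res$cm[row0 + j] <- ft$cm; res$fwhm[row0 + j] <- ft$fwhm }
    }
    row0 <- row0 + n_dia
    if (verbose && i %% 100L == 0L)
      message(sprintf("test profiles: depth %d/%d", i, n_dep))
  }
  est <- data.frame(depth = NA_real_, diameter = NA_real_,
                    inestimable = TRUE, residual = NA_real_, method = "none",
                    stringsAsFactors = FALSE)[rep(1L, nrow(res)), ]
  ok <- res$feature_ok
  est[ok, ] <- estimate_depth_1d_batch(res$cm[ok], res$fwhm[ok], lut)
  res$depth_est <- est$depth
  res$diameter_est <- est$diameter
  res$inestimable <- est$inestimable
  res$method <- est$method
  res$depth_err <- res$depth_est - res$depth_true
  res$diameter_err <- res$diameter_est - res$diameter_true

  tolg <- 1e-9
  on_lut <- vapply(res$depth_true, function(d) any(abs(lut$depths - d) < tolg), logical(1)) &
    vapply(res$diameter_true, function(D) any(abs(lut$diameters - D) < tolg), logical(1))
  ea <- abs(res$depth_err)
  estimable <- !res$inestimable
  smry <- list(
    n_total = nrow(res),
    n_lut_coincident = sum(on_lut),
    n_inestimable = sum(res$inestimable),
    inestimable_pct = 100 * mean(res$inestimable),
    mean_abs_depth_error_mm = mean(ea[estimable]),
    mean_abs_depth_error_um = 1000 * mean(ea[estimable]),
    median_abs_depth_error_um = 1000 * stats::median(ea[estimable]),
    max_abs_depth_error_mm = max(ea[estimable]),
    mean_abs_depth_error_um_excl_nodes = 1000 * mean(ea[estimable & !on_lut]),
    mean_abs_diameter_error_mm = mean(abs(res$diameter_err[estimable])),
    cor_depth_diameter_error = stats::cor(res$depth_err[estimable],
                                          res$diameter_err[estimable]),
    error_hist = graphics::hist(ea[estimable], breaks = 50, plot = FALSE)[c("breaks", "counts")]
  )
  structure(list(results = res, summary = smry, lut = lut, snr_db = snr_db),
            class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Simulation study: %d profiles (%d coincide with table nodes)\n",
              s$n_total, s$n_lut_coincident))
  cat(sprintf("  inestimable: %d (%.4g%%)\n", s$n_inestimable, s$inestimable_pct))
  cat(sprintf("  mean |depth error|: %.3g um (excl. nodes: %.3g um); max %.3g mm\n",
              s$mean_abs_depth_error_um, s$mean_abs_depth_error_um_excl_nodes,
              s$max_abs_depth_error_mm))
  cat(sprintf("  mean |diameter error|: %.3g mm; depth/diameter error corr: %.3f\n",
              s$mean_abs_diameter_error_mm, s$cor_depth_diameter_error))
  invisible(x)
}
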