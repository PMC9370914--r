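#' Optical properties of a turbid medium
#'
#' Bundles the reduced scattering coefficient and the absorption coefficient
#' of the medium, the two parameters that determine the depth-dependent blur
#' of a transillumination image. The effective attenuation coefficient
#' \eqn{\kappa_d = \sqrt{3\mu_a(\mu_s' + \mu_a)}} is derived from them.
#'
#' @param mu_s_prime Reduced scattering coefficient, 1/mm. Tissue-like value
#'   is 1.0/mm. Must be positive.
#' @param mu_a Absorption coefficient, 1/mm. Tissue-like value is 0.01/mm.
#'   Must be non-negative.
#' @return An object of class `optical_properties`: a list with elements
#'   `mu_s_prime`, `mu_a` and the derived `kappa_d` (1/mm).
#' @examples
#' opt <- optical_properties(1.0, 0.01)
#' opt$kappa_d  # 0.1741/mm
#' @export
optical_properties <- function(mu_s_prime, mu_a) {
  stopifnot(is.numeric(mu_s_prime), length(mu_s_prime) == 1L,
            is.numeric(mu_a), length(mu_a) == 1L)
  if (!is.finite(mu_s_prime) || mu_s_prime <= 0)
    stop("`mu_s_prime` must be a positive finite number (1/mm)")
  if (!is.finite(mu_a) || mu_a < 0)
    stop("`mu_a` must be a non-negative finite number (1/mm)")
  structure(
    list(mu_s_prime = mu_s_prime, mu_a = mu_a,
         kappa_d = sqrt(3 * mu_a * (mu_s_prime + mu_a))),
    class = "optical_properties")
}

#' Effective attenuation coefficient
#'
#' Computes \eqn{\kappa_d = \sqrt{3\mu_a(\mu_s' + \mu_a)}}, the diffusive
#' decay rate that appears in the exponential of the point spread function.
#'
#' @param optical An [optical_properties()] object, or a positive scalar
#'   `mu_s_prime` when `mu_a` is also given.
#' @param mu_a Absorption coefficient, 1/mm; only used when `optical` is a
#'   bare scalar.
#' @return Effective attenuation, 1/mm.
#' @export
kappa_d <- function(optical, mu_a = NULL) {
  if (!inherits(optical, "optical_properties"))
    optical <- optical_properties(optical, mu_a)
  optical$kappa_d
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("Turbid medium: mu_s' = %g /mm, mu_a = %g /mm (kappa_d = %.6g /mm)\n",
              x$mu_s_prime, x$mu_a, x$kappa_d))
  invisible(x)
}

as_optical <- function(x) {
  if (inherits(x, "optical_properties")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(optical_properties(x[1L], x[2L]))
  stop("expected an `optical_properties` object or a numeric (mu_s_prime, mu_a) pair")
}

#' Pixel raster of an image
#'
#' Describes the sampling of a transillumination image: pixel counts and the
#' physical pixel pitch. Image coordinates are row-major with y pointing down;
#' physical positions are measured in mm.
#'
#' @param n_rows,n_cols Pixel counts, at least 1.
#' @param pitch Pixel pitch, mm per pixel. The default 0.1 mm/px resolves
#'   1--10 mm absorbers and submillimeter depth steps.
#' @return An `image_grid` object.
#' @export
image_grid <- function(n_rows, n_cols, pitch = 0.1) {
  stopifnot(is.numeric(n_rows), is.numeric(n_cols), is.numeric(pitch))
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid must have at least one pixel per axis")
  if (!is.finite(pitch) || pitch <= 0) stop("`pitch` must be positive (mm/px)")
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch = pitch),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("Image grid: %d x %d px at %g mm/px (%.1f x %.1f mm)\n",
              x$n_rows, x$n_cols, x$pitch,
              x$n_rows * x$pitch, x$n_cols * x$pitch))
  invisible(x)
}
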