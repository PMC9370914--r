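#' Read a transillumination image from TIFF or PNG
#'
#' Float TIFF is the canonical interchange format and round-trips exactly.
#' Integer TIFF/PNG values are returned on their native relative scale in
#' `[0, 1]` (8/16-bit files are rescaled by their bit depth; the ordering of
#' values is preserved).
#'
#' @param path File path (`.tif`, `.tiff` or `.png`).
#' @param pitch Pixel pitch to attach, mm/px.
#' @param provenance Provenance tag for the resulting image.
#' @return A `ti_image`.
#' @export
read_image <- function(path, pitch = 0.1, provenance = "raw") {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
                 tif = , tiff = tiff::readTIFF(path),
                 png = png::readPNG(path),
                 stop(sprintf("unsupported image format '.%s' (use TIFF or PNG)", ext)))
  if (length(dim(vals)) == 3L) vals <- vals[, , 1L]   # first channel of RGB(A)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$scale)) vals <- vals * meta$scale
  }
  ti_image(vals, pitch, provenance)
}

#' Write a transillumination image
#'
#' TIFF output is 32-bit float (lossless for this package's pipelines);
#' PNG output is 16-bit, rescaled to the image maximum, intended for
#' viewing only.
#'
#' @param image A `ti_image` (NAs are written as 0).
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "ti_image"))
  v <- image$values
  v[is.na(v)] <- 0
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff_scaled(v, path)
  } else if (ext == "png") {
    m <- max(v)
    png::writePNG(if (m > 0) v / m else v, path)
  } else stop(sprintf("unsupported image format '.%s'", ext))
  invisible(path)
}

# float TIFF stores [0, 1]; larger dynamic ranges (depth maps, deconvolved
# overshoot) are divided by their maximum, recorded in a JSON sidecar that
# read_image() applies on the way back in
write_tiff_scaled <- function(v, path) {
  m <- max(v, 1)
  if (m > 1) {
    v <- v / m
    jsonlite::write_json(list(scale = m), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  tiff::writeTIFF(v, path, bits.per.sample = 32L)
  path
}

#' Write / read a focus stack as a multi-page TIFF with a depth sidecar
#'
#' @param stack A `focus_stack`.
#' @param path Multi-page TIFF path; per-page depths go to `<path>.json`.
#' @return `path` (write) or a `focus_stack` (read).
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "focus_stack"))
  m <- max(1, vapply(stack$images, max, numeric(1)))
  tiff::writeTIFF(lapply(stack$images, function(x) x / m), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(list(depths = stack$depths, pitch = stack$grid$pitch,
                            scale = m),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!is.null(meta$scale) && meta$scale != 1)
    pages <- lapply(pages, function(x) x * meta$scale)
  g <- image_grid(nrow(pages[[1L]]), ncol(pages[[1L]]), meta$pitch)
  structure(list(depths = meta$depths, images = pages, grid = g,
                 config = NULL),
            class = "focus_stack")
}

#' Write a 3D point cloud as ASCII PLY (with optional grid surface) or XYZ
#'
#' @param points data.frame with `x`, `y`, `z` (mm) and optionally
#'   `intensity`.
#' @param path Output `.ply` or `.xyz` path.
#' @param mask Optional logical matrix (the segmentation the points came
#'   from); when given, adjacent masked pixels are triangulated into a
#'   surface.
#' @return `path`, invisibly.
#' @export
write_points_3d <- function(points, path, mask = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") {
    utils::write.table(points[, c("x", "y", "z")], path,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  if (ext != "ply") stop("unsupported 3D format (use .ply or .xyz)")
  faces <- NULL
  if (!is.null(mask)) {
    idx <- matrix(NA_integer_, nrow(mask), ncol(mask))
    idx[mask] <- seq_len(sum(mask)) - 1L        # ply is 0-based
    f <- list()
    for (r in seq_len(nrow(mask) - 1L)) for (c in seq_len(ncol(mask) - 1L)) {
      a <- idx[r, c]; b <- idx[r, c + 1L]; d <- idx[r + 1L, c]; e <- idx[r + 1L, c + 1L]
      if (!anyNA(c(a, b, d))) f[[length(f) + 1L]] <- c(a, b, d)
      if (!anyNA(c(b, e, d))) f[[length(f) + 1L]] <- c(b, e, d)
    }
    faces <- f
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(points)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", length(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%g %g %g", points$x, points$y, points$z), con)
  if (length(faces))
    writeLines(vapply(faces, function(v) sprintf("3 %d %d %d", v[1], v[2], v[3]),
                      character(1)), con)
  invisible(path)
}

#' Run configuration: defaults, file override, save/load
#'
#' A flat key-value configuration controlling optics, grid, deconvolution
#' and fusion parameters. `run_config()` returns the defaults merged with
#' any overrides; configurations round-trip through JSON save/load.
#'
#' @param ... Named overrides of the default keys.
#' @param file Optional JSON config file whose entries are applied before
#'   `...`.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list(
    mu_s_prime = 1.0, mu_a = 0.01, pitch = 0.1,
    absorptance = 1.0, depth_quantum = 0.1, parse = "r",
    deconv_method = "wiener", nsr = 1e-2, rl_iterations = 25L,
    window_r = 9L, alpha = 1.0, s_th = 22.0, s_cap = 120.0,
    normalization = "max", stride = 1L,
    profile_sigma = 2.0, fwhm_method = "gauss", window_factor = 3.0,
    seed = 1L)
  if (!is.null(file)) {
    ov <- jsonlite::read_json(file, simplifyVector = TRUE)
    cfg[names(ov)] <- ov
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON output path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a deterministic result bundle
#'
#' Writes the elements of `results` with formats chosen by type: `ti_image`
#' as float TIFF, matrices as float TIFF, data.frames as CSV, `focus_stack`
#' as multi-page TIFF, plus a JSON summary with the configuration hash,
#' seed and package version. The same inputs and configuration produce
#' byte-identical CSV/JSON outputs.
#'
#' @param results Named list of result objects.
#' @param prefix Output path prefix (directories are created).
#' @param config A [run_config()] recorded in the summary.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(results, prefix, config = run_config()) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    f <- if (inherits(x, "ti_image")) {
      write_image(x, paste0(prefix, "_", nm, ".tif"))
    } else if (inherits(x, "focus_stack")) {
      write_stack(x, paste0(prefix, "_", nm, ".tif"))
    } else if (is.matrix(x)) {
      write_tiff_scaled(x, paste0(prefix, "_", nm, ".tif"))
    } else if (is.data.frame(x)) {
      utils::write.csv(x, paste0(prefix, "_", nm, ".csv"), row.names = FALSE)
      paste0(prefix, "_", nm, ".csv")
    } else next
    files <- c(files, f)
  }
  summary_path <- paste0(prefix, "_summary.json")
  jsonlite::write_json(
    list(files = basename(files),
         config = unclass(config),
         config_hash = config_hash(config),
         seed = config$seed,
         package_version = as.character(utils::packageVersion("transillum3d"))),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, summary_path))
}

# one structured log line per pipeline stage
log_stage <- function(stage, ..., verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  kv <- list(...)
  msg <- if (length(kv))
    paste(names(kv), vapply(kv, function(x) paste(format(x), collapse = ","),
                            character(1)), sep = "=", collapse = " ")
  else ""
  message(sprintf("[transillum3d] %s %s", stage, msg))
  invisible(NULL)
}
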