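#' @importFrom stats runif rnorm fft dist t.test pt var setNames
#' @importFrom utils write.csv read.csv
NULL

CHANNEL_ROLES <- c("nuclei", "neuron", "astrocyte", "phase")

#' Single-channel micrograph
#'
#' Light-weight container for one fluorescence or phase-contrast channel as
#' read from disk: a non-negative intensity raster plus its native bit depth
#' and biological role (`nuclei` = DAPI/Hoechst, `neuron` = beta-III
#' tubulin/green, `astrocyte` = GFAP/red, `phase` = phase contrast).
#'
#' @param pixels Numeric matrix of intensities (rows x columns); must be
#'   finite and non-negative.
#' @param bit_depth Native bit depth, 8 or 16.
#' @param role One of `"nuclei"`, `"neuron"`, `"astrocyte"`, `"phase"`.
#' @return An object of class `channel_image` with fields `pixels`,
#'   `bit_depth`, `role`.
#' @export
channel_image <- function(pixels, bit_depth = 16L, role = "nuclei") {
  role <- match.arg(role, CHANNEL_ROLES)
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1, ncol(pixels) >= 1)
  px <- pixels * 1.0
  if (any(!is.finite(px))) {
    stop("channel intensities must all be finite")
  }
  if (any(px < 0)) {
    stop("channel intensities must be non-negative")
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop("bit_depth must be 8 or 16, got ", bit_depth)
  }
  structure(
    list(pixels = px, bit_depth = as.integer(bit_depth), role = role),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf(
    "<channel_image> role=%s  %d x %d px  %d-bit  intensity range [%g, %g]\n",
    x$role, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Read a grayscale channel image from disk
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG into a [channel_image()].
#' Intensities are kept on the native integer scale (0..2^bit_depth - 1) and
#' converted to double. RGB or multi-page files are ambiguous for a
#' single-channel pipeline and raise an error unless `channel` selects a
#' plane of an RGB file.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param role Channel role, see [channel_image()].
#' @param channel Optional integer (1..3) selecting a plane from an RGB file.
#' @return A `channel_image`.
#' @export
load_channel <- function(path, role = "nuclei", channel = NULL) {
  if (!file.exists(path)) {
    stop("image file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (length(pages) > 1L) {
      stop(
        "multi-page TIFF '", path,
        "' is ambiguous: split the pages into one file per channel"
      )
    }
    img <- pages[[1L]]
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bits <- if (!is.null(info) && !is.null(info$bit.depth)) info$bit.depth else 8L
    img <- img * (2^bits - 1) # readPNG rescales to [0,1]; undo to native scale
  } else {
    stop("unsupported image format '.", ext, "': use grayscale TIFF or PNG")
  }
  if (length(dim(img)) == 3L) {
    if (is.null(channel)) {
      stop(
        "'", path, "' has ", dim(img)[3],
        " samples per pixel (RGB/RGBA): pass `channel` to select one plane"
      )
    }
    img <- img[, , channel]
  }
  channel_image(img, bit_depth = as.integer(bits), role = role)
}

#' Standardize a channel to the canonical 600 x 600 geometry
#'
#' Images acquired with different objectives and camera resolutions are made
#' comparable by (1) bilinear resampling to 800 x 600 px at a fixed physical
#' scale of 1.6 px/um and (2) cropping to the centred 600-column window
#' (columns 101..700 of the 800-wide intermediate, rows untouched), yielding a
#' square 600 x 600 raster suitable for Fourier analysis.
#'
#' Images already at a canonical geometry skip the resampling step: an
#' 800 x 600 (w x h) input is only cropped, and a 600 x 600 input passes
#' through unchanged, making `standardize` idempotent.
#'
#' @param image A `channel_image` or numeric matrix, at least 2 x 2.
#' @return A 600 x 600 numeric matrix.
#' @seealso [standardize_image()] for whole multi-channel acquisitions.
#' @export
standardize <- function(image) {
  px <- as_raster(image)
  stopifnot(nrow(px) >= 2, ncol(px) >= 2)
  if (all(dim(px) == c(600L, 600L))) {
    return(px)
  }
  if (!all(dim(px) == c(600L, 800L))) {
    px <- EBImage::resize(px, w = 600L, h = 800L, filter = "bilinear")
    px <- matrix(as.numeric(px), 600L, 800L)
  }
  px[, 101:700, drop = FALSE]
}

#' Multi-channel standardized image
#'
#' Bundle of co-registered 600 x 600 channels at the canonical pixel scale.
#' `std_image()` validates already-standardized rasters;
#' `standardize_image()` runs [standardize()] on each channel first.
#'
#' @param channels Named list of 600 x 600 matrices (or `channel_image`s for
#'   `standardize_image`), names drawn from the channel roles.
#' @param pixel_scale Pixels per micrometre; fixed at 1.6 by the
#'   standardization recipe.
#' @return An object of class `std_image` with fields `channels` and
#'   `pixel_scale`.
#' @export
std_image <- function(channels, pixel_scale = 1.6) {
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("channels must be a named list (e.g. nuclei, neuron, astrocyte)")
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !all(dim(ch) == c(600L, 600L))) {
      stop("channel '", nm, "' is not a 600 x 600 matrix; run standardize()")
    }
  }
  structure(
    list(channels = channels, pixel_scale = pixel_scale),
    class = "std_image"
  )
}

#' @rdname std_image
#' @export
standardize_image <- function(channels, pixel_scale = 1.6) {
  std_image(lapply(channels, standardize), pixel_scale = pixel_scale)
}

#' @export
print.std_image <- function(x, ...) {
  cat(sprintf(
    "<std_image> 600 x 600 px at %.1f px/um; channels: %s\n",
    x$pixel_scale, paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Min-max normalize a raster to [0, 1]
#'
#' Linear rescale `(x - min) / (max - min)` so the darkest pixel maps to 0 and
#' the brightest to 1. A constant raster has no dynamic range; it is returned
#' as all zeros with a warning so downstream fixed thresholds (which assume
#' the \[0, 1\] scale) behave deterministically.
#'
#' @param x A `channel_image` or numeric matrix.
#' @return A numeric matrix with values in \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  px <- as_raster(x)
  rng <- range(px)
  if (rng[1] == rng[2]) {
    warning("constant raster: no dynamic range, returning all zeros")
    return(matrix(0, nrow(px), ncol(px)))
  }
  (px - rng[1]) / (rng[2] - rng[1])
}
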