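#' Calibrated raster containers
#'
#' `rgb_raster()` wraps a 3-channel brightfield image (values 0-255) together
#' with its isotropic pixel size in micrometres.  `raster_layer()` holds a
#' single scalar channel on the same grid (e.g. the texture layer), and
#' `tissue_mask()` a boolean tissue/background partition.  All grids are
#' ordinary R matrices/arrays indexed `[row, col]`, 0-based pixel-centre
#' coordinates are used in exported tables.
#'
#' @param pixels numeric array `nrow x ncol x 3`, values in `[0, 255]`.
#' @param pixel_size_um micrometres per pixel (isotropic), `> 0`.
#' @return An object of class `rgb_raster`.
#' @export
rgb_raster <- function(pixels, pixel_size_um) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "rgb_raster")
}

#' @param values numeric matrix of finite values.
#' @rdname rgb_raster
#' @export
raster_layer <- function(values, pixel_size_um) {
  stopifnot(is.matrix(values))
  if (!all(is.finite(values))) stop("raster_layer values must be finite")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be positive")
  }
  structure(list(values = values, pixel_size_um = pixel_size_um),
            class = "raster_layer")
}

#' @param mask logical matrix; `TRUE` marks tissue.
#' @rdname rgb_raster
#' @export
tissue_mask <- function(mask, pixel_size_um) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(list(mask = mask, pixel_size_um = pixel_size_um),
            class = "tissue_mask")
}

#' @export
print.rgb_raster <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_raster> %d x %d px, %.3g um/px\n", d[1], d[2],
              x$pixel_size_um))
  invisible(x)
}

#' @export
print.raster_layer <- function(x, ...) {
  cat(sprintf("<raster_layer> %d x %d px, %.3g um/px, range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), x$pixel_size_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d x %d px, %.3g um/px, %d tissue px\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size_um, sum(x$mask)))
  invisible(x)
}

#' Extract one channel of an RGB raster as a raster layer
#'
#' @param image an [rgb_raster].
#' @param channel 1 = red, 2 = green, 3 = blue.
#' @return A [raster_layer].
#' @export
channel_layer <- function(image, channel) {
  stopifnot(inherits(image, "rgb_raster"), channel %in% 1:3)
  raster_layer(image$pixels[, , channel, drop = TRUE], image$pixel_size_um)
}

#' Nearest-neighbour downsampling
#'
#' Reduces an image to `scale_fraction` of its linear resolution by copying,
#' for every output pixel, the nearest input pixel (no interpolation); output
#' dimensions are `floor(dims * scale_fraction)` and the pixel size grows by
#' `1 / scale_fraction`.  The default working scale of 10% turns a
#' 0.56 um/px slide into a 5.6 um/px working image.
#'
#' @param image an [rgb_raster] (or [raster_layer] / [tissue_mask]).
#' @param scale_fraction ratio in (0, 1].
#' @return Object of the same class at the new resolution.
#' @export
downsample <- function(image, scale_fraction) {
  if (!is.numeric(scale_fraction) || length(scale_fraction) != 1L ||
      scale_fraction <= 0 || scale_fraction > 1) {
    stop("scale_fraction must lie in (0, 1]")
  }
  UseMethod("downsample")
}

nn_index <- function(n, scale_fraction) {
  n_out <- floor(n * scale_fraction)
  if (n_out < 1) stop("downsampling would produce a zero-sized image")
  # output pixel centre i (0-based) maps to input coordinate (i + 0.5)/scale
  idx <- floor(((seq_len(n_out) - 0.5) / scale_fraction)) + 1L
  pmin(pmax(idx, 1L), n)
}

#' @export
downsample.rgb_raster <- function(image, scale_fraction) {
  ri <- nn_index(dim(image$pixels)[1], scale_fraction)
  ci <- nn_index(dim(image$pixels)[2], scale_fraction)
  rgb_raster(image$pixels[ri, ci, , drop = FALSE],
             image$pixel_size_um / scale_fraction)
}

#' @export
downsample.raster_layer <- function(image, scale_fraction) {
  ri <- nn_index(nrow(image$values), scale_fraction)
  ci <- nn_index(ncol(image$values), scale_fraction)
  raster_layer(image$values[ri, ci, drop = FALSE],
               image$pixel_size_um / scale_fraction)
}

#' @export
downsample.tissue_mask <- function(image, scale_fraction) {
  ri <- nn_index(nrow(image$mask), scale_fraction)
  ci <- nn_index(ncol(image$mask), scale_fraction)
  tissue_mask(image$mask[ri, ci, drop = FALSE],
              image$pixel_size_um / scale_fraction)
}

#' Convert a pixel area to square millimetres
#'
#' `area_mm2 = area_px * (pixel_size_um / 1000)^2`.  At the 5.6 um working
#' pixel size the lobule area filter 2000-14000 px^2 corresponds to
#' 0.0627-0.439 mm^2.
#'
#' @param area_px pixel count (>= 0).
#' @param pixel_size_um micrometres per pixel.
#' @return Area in mm^2.
#' @export
area_px_to_mm2 <- function(area_px, pixel_size_um) {
  stopifnot(all(area_px >= 0), pixel_size_um > 0)
  area_px * (pixel_size_um / 1000)^2
}
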