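#' Standard deviation of each pixel to its neighbours
#'
#' The key texture statistic of the workflow: for every pixel, the
#' root-mean-square difference between the pixel value and its 8-connected
#' neighbours.  Edge pixels use the neighbours that exist.  Mammary lobules --
#' regular rings of epithelial nuclei around tubule lumens -- light up as
#' bright blobs in this channel at the working resolution, against darker,
#' smoother stroma.
#'
#' @param layer a [raster_layer] (or bare numeric matrix), at least 3x3.
#' @return A [raster_layer] (or matrix) of non-negative deviations.
#' @export
stddev_to_neighbors <- function(layer) {
  m <- if (inherits(layer, "raster_layer")) layer$values else layer
  stopifnot(is.matrix(m), nrow(m) >= 3, ncol(m) >= 3)
  acc <- matrix(0, nrow(m), ncol(m))
  cnt <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- shift_mat(m, dr, dc, fill = NA_real_)
    ok <- !is.na(nb)
    d2 <- (nb - m)^2
    d2[!ok] <- 0
    acc <- acc + d2
    cnt <- cnt + ok
  }
  out <- sqrt(acc / cnt)
  if (inherits(layer, "raster_layer")) {
    raster_layer(out, layer$pixel_size_um)
  } else {
    out
  }
}

#' Build the texture layer of a working-resolution image
#'
#' Composition used throughout detection: stddev-to-neighbours of the blue
#' channel, median filtered with a 3x3 window, then smoothed with an 11x11
#' Gaussian kernel.  The blue channel is used because both hematoxylin and
#' DAB absorb there, so nuclear texture is visible irrespective of stain
#' class; changes confined to red/green leave the layer untouched.
#'
#' @param image an [rgb_raster] at working resolution.
#' @return A [raster_layer] of non-negative texture values.
#' @export
build_texture_layer <- function(image) {
  stopifnot(inherits(image, "rgb_raster"))
  blue <- image$pixels[, , 3, drop = TRUE]
  tex <- stddev_to_neighbors(blue)
  tex <- median3(tex)
  tex <- gaussian_smooth(tex, 11L)
  tex[tex < 0] <- 0
  raster_layer(tex, image$pixel_size_um)
}

#' Separate tissue from background
#'
#' Mean-RGB brightness is smoothed with a 15x15 Gaussian kernel; an Otsu
#' threshold is computed on the smoothed image and brighter pixels become
#' background (slides are bright-field: glass is near-white).  Small enclosed
#' background islands are reclassified as tissue and vice versa, so pen
#' marks, lumens and dust do not fragment the partition.
#'
#' @param image an [rgb_raster] at working resolution.
#' @param small_area_px components smaller than this are reclassified when
#'   fully enclosed by the opposite class.  Default 2500 working px
#'   (~0.078 mm^2 at 5.6 um/px), below the minimum lobule area so no lobule
#'   can be destroyed.
#' @return A [tissue_mask].
#' @export
tissue_mask_from_image <- function(image, small_area_px = 2500L) {
  stopifnot(inherits(image, "rgb_raster"))
  brightness <- (image$pixels[, , 1] + image$pixels[, , 2] +
                 image$pixels[, , 3]) / 3
  sm <- gaussian_smooth(brightness, 15L)
  # threshold value computed from the raw histogram (the smoothing spreads a
  # wide ramp tail under the glass mode that misleads the mode analysis),
  # then applied to the smoothed image
  thr <- tryCatch(otsu_background_threshold(brightness),
                  error = function(e) NULL)
  if (is.null(thr)) {
    warning("near-constant image: classifying everything as background")
    return(tissue_mask(matrix(FALSE, nrow(sm), ncol(sm)),
                       image$pixel_size_um))
  }
  tissue <- sm <= thr
  tissue <- reclassify_small(tissue, small_area_px)
  tissue_mask(tissue, image$pixel_size_um)
}

# Enclosed components of either class smaller than the limit flip class.
reclassify_small <- function(tissue, small_area_px) {
  flip_small <- function(mask_from) {
    lab <- cpp_cc_label(mask_from, 4L)
    if (max(lab) == 0L) return(mask_from)
    nr <- nrow(lab); nc <- ncol(lab)
    border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    small_enclosed <- which(sizes > 0 & sizes < small_area_px &
                            !(seq_along(sizes) %in% border_labels))
    if (length(small_enclosed)) {
      mask_from[lab %in% small_enclosed] <- FALSE
    }
    mask_from
  }
  bg <- !tissue
  bg <- flip_small(bg)            # small enclosed background -> tissue
  tissue <- !bg
  flip_small(tissue)              # small enclosed tissue -> background
}
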