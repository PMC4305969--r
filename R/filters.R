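# Low-level raster filtering primitives shared by the pipeline stages.
# All operate on plain numeric/logical matrices [row, col].

shift_mat <- function(m, dr, dc, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  if (max(1, 1 - dr) > min(nr, nr - dr) ||
      max(1, 1 - dc) > min(nc, nc - dc)) {
    return(out)
  }
  r_src <- max(1, 1 - dr):min(nr, nr - dr)
  c_src <- max(1, 1 - dc):min(nc, nc - dc)
  out[r_src + dr, c_src + dc] <- m[r_src, c_src]
  out
}

#' Gaussian kernel parameterised by window size
#'
#' 1-D kernel of odd length `size`, sigma = `(size - 1) / 6`, truncated to the
#' window and normalised to sum 1.  The sigma rule puts +-3 sigma at the
#' window edge, the usual convention when a method states only a window size.
#'
#' @param size odd window size (>= 1).
#' @return Numeric vector of length `size` summing to 1.
#' @export
gaussian_kernel <- function(size) {
  stopifnot(size >= 1, size %% 2 == 1)
  if (size == 1) return(1)
  sigma <- (size - 1) / 6
  x <- seq(-(size - 1) / 2, (size - 1) / 2)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with a symmetric 1-D kernel applied to rows then
# columns.  Near edges the kernel is renormalised over the in-image support
# (normalised convolution), so constants are preserved everywhere.
conv_sep <- function(m, kernel) {
  k <- length(kernel)
  if (k == 1) return(m * kernel)
  half <- (k - 1) / 2
  ones <- matrix(1, nrow(m), ncol(m))
  pass <- function(v, w, along) {
    acc <- matrix(0, nrow(m), ncol(m))
    wacc <- matrix(0, nrow(m), ncol(m))
    for (j in seq_len(k)) {
      d <- j - 1 - half
      if (along == "row") {
        acc <- acc + kernel[j] * shift_mat(v, d, 0, fill = 0)
        wacc <- wacc + kernel[j] * shift_mat(w, d, 0, fill = 0)
      } else {
        acc <- acc + kernel[j] * shift_mat(v, 0, d, fill = 0)
        wacc <- wacc + kernel[j] * shift_mat(w, 0, d, fill = 0)
      }
    }
    list(v = acc, w = wacc)
  }
  p1 <- pass(m, ones, "row")
  p2v <- pass(p1$v, p1$w, "col")
  p2v$v / p2v$w
}

#' Gaussian smoothing with an `size x size` window
#'
#' @param m numeric matrix.
#' @param size odd window size.
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(m, size) {
  conv_sep(m, gaussian_kernel(size))
}

#' 3x3 median filter (edge pixels use available neighbours only)
#'
#' @param m numeric matrix.
#' @return Filtered matrix.
#' @export
median3 <- function(m) {
  cpp_median3(m)
}

#' Otsu's automatic threshold
#'
#' Maximises between-class variance of a 256-bin histogram.  Returns the
#' threshold value; pixels strictly above it form the bright class.
#'
#' @param values numeric vector or matrix.
#' @param n_bins number of histogram bins.
#' @return Threshold on the scale of `values`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    stop("degenerate histogram: all values (nearly) equal")
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  # plateau-safe argmax: delta-spike histograms maximise sigma_b over a
  # whole plateau of splits; take its midpoint (deterministic)
  top <- which(sigma_b >= max(sigma_b) - 1e-12 * max(sigma_b, 1))
  k <- top[ceiling(length(top) / 2)]
  thr <- breaks[k + 1L]
  # effectiveness of the split: between-class / total variance
  tot <- sum(p * (mids - mu_t)^2)
  attr(thr, "eta") <- if (tot > 0) sigma_b[k] / tot else 0
  thr
}

# Recursive Otsu for multi-modal histograms: re-split the bright class
# while the split is still effective (eta > 0.8).  Reduces to plain Otsu
# for a bimodal tissue/glass histogram; on tumor-dominant slides it steps
# over the dark tumor mode to the stroma/glass boundary.
otsu_background_threshold <- function(values, eta_min = 0.8,
                                      max_depth = 4L) {
  thr <- otsu_threshold(values)
  for (i in seq_len(max_depth)) {
    bright <- values[values > thr]
    if (length(bright) < 100) break
    t2 <- tryCatch(otsu_threshold(bright), error = function(e) NULL)
    if (is.null(t2) || attr(t2, "eta") <= eta_min) break
    thr <- t2
  }
  as.numeric(thr)
}

# --- binary morphology (3x3 square structuring element) ---------------------

dilate3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_mat_l(mask, dr, dc)
  }
  out
}

erode3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & shift_mat_l(mask, dr, dc)
  }
  out
}

shift_mat_l <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  if (max(1, 1 - dr) > min(nr, nr - dr) ||
      max(1, 1 - dc) > min(nc, nc - dc)) {
    return(out)
  }
  r_src <- max(1, 1 - dr):min(nr, nr - dr)
  c_src <- max(1, 1 - dc):min(nc, nc - dc)
  out[r_src + dr, c_src + dc] <- m[r_src, c_src]
  out
}

morph_open3 <- function(mask) dilate3(erode3(mask))
morph_close3 <- function(mask) erode3(dilate3(mask))

#' Fill enclosed holes in a binary mask
#'
#' Background components (4-connected) that do not touch the image border are
#' reclassified as foreground.
#'
#' @param mask logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  lab <- cpp_cc_label(!mask, 4L)
  if (max(lab) == 0L) return(mask)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0L]
  hole <- lab > 0L & !(lab %in% border_labels)
  mask | hole
}

#' Connected-component labelling
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer label matrix (0 = background), labels in raster-scan order.
#' @export
label_components <- function(mask, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  cpp_cc_label(mask, as.integer(connectivity))
}

#' Euclidean distance transform
#'
#' Distance of each `TRUE` pixel to the nearest `FALSE` pixel, in pixels.
#'
#' @param mask logical matrix.
#' @return Numeric matrix of distances (0 on `FALSE` pixels).
#' @export
distance_transform <- function(mask) {
  sqrt(cpp_edt_sq(mask))
}

# Separable running maximum over a (2*radius+1)^2 window.
max_filter <- function(m, radius) {
  pass <- function(v, along) {
    out <- v
    for (d in seq_len(radius)) {
      if (along == "row") {
        out <- pmax(out, shift_mat(v, d, 0, fill = -Inf),
                    shift_mat(v, -d, 0, fill = -Inf))
      } else {
        out <- pmax(out, shift_mat(v, 0, d, fill = -Inf),
                    shift_mat(v, 0, -d, fill = -Inf))
      }
    }
    out
  }
  pass(pass(m, "row"), "col")
}
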