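#' Stain reference for hue-saturation-density deconvolution
#'
#' Background (glass) intensity per RGB channel plus the optical-density
#' spectra of hematoxylin (blue counterstain) and DAB (brown chromogen).
#' Defaults are the standard literature vectors; slides with a calibrated
#' stain profile can override them.  Internally the spectra are normalised to
#' mean 1 so that each stain's density equals its contribution to the total
#' optical density, which places each stain at a fixed point in the
#' chromatic (hue-saturation) plane of the HSD model.
#'
#' @param i0 background intensity per channel, in (0, 255].
#' @param hema,dab optical-density RGB direction of each stain.
#' @return A `stain_reference`.
#' @export
stain_reference <- function(i0 = c(245, 245, 245),
                            hema = c(0.650, 0.704, 0.286),
                            dab = c(0.268, 0.570, 0.776)) {
  stopifnot(length(i0) == 3L, all(i0 > 0), length(hema) == 3L,
            length(dab) == 3L, all(hema >= 0), all(dab >= 0))
  h <- hema / mean(hema)
  d <- dab / mean(dab)
  ch_h <- od_chroma(h)
  ch_d <- od_chroma(d)
  if (sum((ch_h - ch_d)^2) < 1e-12) {
    stop("stain directions are collinear in the chromatic plane")
  }
  structure(list(i0 = i0, hema = h, dab = d,
                 chroma_hema = ch_h, chroma_dab = ch_d),
            class = "stain_reference")
}

# chromatic coordinates of a mean-normalised OD triple (van der Laak's HSD)
od_chroma <- function(v) {
  c(x = v[1] - 1, y = (v[2] - v[3]) / sqrt(3))
}

#' Hue-saturation-density stain separation
#'
#' Per pixel, channel optical densities `D_c = -ln(I_c / I0_c)` are reduced
#' to a total density `D` and a chromatic point in the HSD plane; the point
#' is projected onto the line between the two stain chromas, which splits `D`
#' into a hematoxylin and a DAB density (negative parts clamped to zero).
#' For pixels generated by Beer-Lambert mixing of the two reference stains
#' this inverts the forward model exactly.
#'
#' @param tile an [rgb_raster] at full resolution.
#' @param ref a [stain_reference()].
#' @return A `density_layers` list with `dab` and `hema` [raster_layer]s and
#'   a `clamped` counter of zero-intensity pixels clamped before the log.
#' @export
hsd_deconvolve <- function(tile, ref = stain_reference()) {
  stopifnot(inherits(tile, "rgb_raster"), inherits(ref, "stain_reference"))
  px <- tile$pixels
  clamped <- sum(px <= 0)
  if (clamped > 0) {
    warning(sprintf("%d zero-intensity samples clamped to 1 before log",
                    clamped))
    px[px <= 0] <- 1
  }
  od <- array(0, dim(px))
  for (k in 1:3) od[, , k] <- -log(pmin(px[, , k], ref$i0[k]) / ref$i0[k])
  d_tot <- (od[, , 1] + od[, , 2] + od[, , 3]) / 3
  eps <- 1e-8
  cx <- ifelse(d_tot > eps, od[, , 1] / pmax(d_tot, eps) - 1, 0)
  cy <- ifelse(d_tot > eps, (od[, , 2] - od[, , 3]) /
                 (sqrt(3) * pmax(d_tot, eps)), 0)
  axis <- ref$chroma_hema - ref$chroma_dab
  alpha <- ((cx - ref$chroma_dab[1]) * axis[1] +
            (cy - ref$chroma_dab[2]) * axis[2]) / sum(axis^2)
  hema <- pmax(alpha * d_tot, 0)
  dab <- pmax((1 - alpha) * d_tot, 0)
  hema[d_tot <= eps] <- 0
  dab[d_tot <= eps] <- 0
  structure(list(dab = raster_layer(dab, tile$pixel_size_um),
                 hema = raster_layer(hema, tile$pixel_size_um),
                 clamped = clamped),
            class = "density_layers")
}

#' Preliminary nuclear regions per stain
#'
#' A pixel belongs to the DAB nuclear region iff its DAB density exceeds the
#' threshold AND exceeds the hematoxylin density (and symmetrically for
#' hematoxylin), so the two masks are disjoint by construction.
#'
#' @param layers a `density_layers` from [hsd_deconvolve()].
#' @param threshold density threshold (default 0.2).
#' @return List of logical matrices `mask_dab`, `mask_hema`.
#' @export
nuclear_regions <- function(layers, threshold = 0.2) {
  dab <- layers$dab$values
  hema <- layers$hema$values
  list(mask_dab = dab > threshold & dab > hema,
       mask_hema = hema > threshold & hema > dab)
}

#' Watershed splitting of a nuclear region into nuclei
#'
#' The stain density is smoothed with a 5x5 Gaussian; local maxima with a
#' minimum separation of `peak_separation_px` seed a priority-flood
#' watershed restricted to the region mask.  Objects get their holes filled;
#' objects smaller than the minimum nuclear area are dropped.
#'
#' @param mask logical nuclear-region mask.
#' @param density the matching stain density matrix.
#' @param min_area_px minimum nuclear area in full-resolution pixels
#'   (default 30 px^2, about 9.4 um^2 at 0.56 um/px -- well below a real
#'   nucleus, so only debris is removed).
#' @param peak_separation_px minimum seed separation (default 8 px, 4.5 um).
#' @return Integer label matrix of nuclei (0 = background).
#' @export
split_nuclei <- function(mask, density, min_area_px = 30L,
                         peak_separation_px = 8L) {
  stopifnot(is.matrix(mask), all(dim(mask) == dim(density)))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  sm <- gaussian_smooth(density, 5L)
  radius <- max(1L, floor(peak_separation_px / 2))
  mx <- max_filter(sm, radius)
  peaks <- mask & (sm >= mx - 1e-12)
  seed_lab <- label_components(peaks, 8L)
  if (max(seed_lab) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- cpp_watershed(sm, seed_lab, mask)
  lab <- fill_label_holes(lab)
  filter_small_labels(lab, min_area_px)
}

# fill enclosed background holes of each labelled object
fill_label_holes <- function(lab) {
  bg <- lab == 0L
  holes <- bg & fill_holes(!bg)      # background pixels enclosed by objects
  if (!any(holes)) return(lab)
  # assign each hole to the label surrounding it (take any 4-neighbour label)
  idx <- which(holes)
  repeat {
    remaining <- which(lab == 0L & holes)
    if (!length(remaining)) break
    filled_any <- FALSE
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- shift_mat(lab, d[1], d[2], fill = 0)
      sel <- remaining[lab[remaining] == 0L & nb[remaining] > 0L]
      if (length(sel)) {
        lab[sel] <- nb[sel]
        filled_any <- TRUE
      }
    }
    if (!filled_any) break
  }
  lab
}

filter_small_labels <- function(lab, min_area_px) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  drop <- which(sizes < min_area_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab
}

#' Cut a nucleus at significant concave dents
#'
#' The object contour is simplified to a polygon (Douglas-Peucker, 1 px
#' tolerance); vertices whose inward turning angle exceeds
#' `max_tangent_angle_deg` are significant dents.  When at least two dents
#' exist the object is cut along the shortest chord joining two dents that
#' lies inside the object, and the fragments are processed recursively.
#' Convex objects come back uncut; fragments below the minimum area are
#' discarded.
#'
#' @param mask logical matrix holding one connected object.
#' @param max_tangent_angle_deg dent significance threshold (default 30).
#' @param min_area_px minimum fragment area.
#' @return List of logical masks, one per resulting object.
#' @export
dent_cut <- function(mask, max_tangent_angle_deg = 30, min_area_px = 30L) {
  if (sum(mask) < min_area_px) return(list())
  poly <- tryCatch(trace_boundary(mask), error = function(e) NULL)
  if (is.null(poly) || nrow(poly) < 8L) return(list(mask))
  simp <- dp_simplify_closed(poly, tol = 1)
  if (nrow(simp) < 4L) return(list(mask))
  dents <- concave_vertices(simp, max_tangent_angle_deg)
  if (length(dents) < 2L) return(list(mask))
  # shortest interior chord between two dents
  best <- NULL; best_d <- Inf
  for (i in seq_along(dents)[-length(dents)]) {
    for (j in (i + 1L):length(dents)) {
      p <- simp[dents[i], ]; q <- simp[dents[j], ]
      d2 <- sum((p - q)^2)
      if (d2 >= best_d || d2 < 4) next
      line <- bresenham(p, q)
      if (all(mask[line])) {
        best <- line; best_d <- d2
      }
    }
  }
  if (is.null(best)) return(list(mask))
  cutm <- mask
  cutm[best] <- FALSE
  lab <- label_components(cutm, 4L)
  if (max(lab) < 2L) return(list(mask))   # cut did not separate anything
  out <- list()
  for (k in seq_len(max(lab))) {
    frag <- lab == k
    if (sum(frag) < min_area_px) next
    out <- c(out, dent_cut(frag, max_tangent_angle_deg, min_area_px))
  }
  if (!length(out)) list(mask) else out
}

# Moore-neighbour boundary trace of the largest object in `mask`;
# returns an n x 2 matrix of (row, col) boundary pixel coordinates.
trace_boundary <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  start <- idx[order(idx[, 2], idx[, 1])[1], ]      # leftmost, then topmost
  nbs <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                ncol = 2, byrow = TRUE)             # clockwise from N
  inside <- function(p) {
    p[1] >= 1 && p[1] <= nrow(mask) && p[2] >= 1 && p[2] <= ncol(mask) &&
      mask[p[1], p[2]]
  }
  path <- list(start)
  cur <- start
  dir <- 7L                                          # came from the west
  repeat {
    found <- FALSE
    for (s in 0:7) {
      k <- (dir + s) %% 8 + 1L
      p <- cur + nbs[k, ]
      if (inside(p)) {
        path[[length(path) + 1L]] <- p
        dir <- (k - 1L + 5L) %% 8L                   # backtrack direction
        cur <- p
        found <- TRUE
        break
      }
    }
    if (!found) break                                # isolated pixel
    if (all(cur == start) && length(path) > 2L) break
    if (length(path) > 4L * sum(mask) + 8L) break    # safety
  }
  do.call(rbind, path[-length(path)])
}

# Douglas-Peucker simplification of a closed contour: split at the two most
# distant points, simplify both halves.
dp_simplify_closed <- function(pts, tol = 1) {
  n <- nrow(pts)
  if (n <= 4L) return(pts)
  i0 <- 1L
  d <- rowSums((pts - matrix(pts[i0, ], n, 2, byrow = TRUE))^2)
  i1 <- which.max(d)
  half1 <- dp_simplify(pts[i0:i1, , drop = FALSE], tol)
  half2 <- dp_simplify(pts[c(i1:n, i0), , drop = FALSE], tol)
  rbind(half1[-nrow(half1), , drop = FALSE], half2[-nrow(half2), , drop = FALSE])
}

dp_simplify <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  a <- pts[1, ]; b <- pts[n, ]
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d <- sqrt(rowSums((pts - matrix(a, n, 2, byrow = TRUE))^2))
  } else {
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2])
    d <- sqrt(rowSums((pts - proj)^2))
  }
  k <- which.max(d)
  if (d[k] <= tol) return(pts[c(1L, n), , drop = FALSE])
  left <- dp_simplify(pts[1:k, , drop = FALSE], tol)
  right <- dp_simplify(pts[k:n, , drop = FALSE], tol)
  rbind(left[-nrow(left), , drop = FALSE], right)
}

# indices (into the polygon) of concave vertices with turning angle beyond
# the threshold; the polygon is taken in its traced orientation
concave_vertices <- function(poly, angle_deg) {
  n <- nrow(poly)
  if (n < 4L) return(integer(0))
  # polygon orientation via the shoelace sum (row = y downwards)
  x <- poly[, 2]; y <- poly[, 1]
  shoelace <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  ccw <- shoelace > 0
  out <- integer(0)
  for (i in seq_len(n)) {
    p0 <- poly[if (i == 1L) n else i - 1L, ]
    p1 <- poly[i, ]
    p2 <- poly[if (i == n) 1L else i + 1L, ]
    v1 <- p1 - p0
    v2 <- p2 - p1
    cross <- v1[2] * v2[1] - v1[1] * v2[2]   # z of (x1,y1,0)x(x2,y2,0)
    dot <- sum(v1 * v2)
    ang <- atan2(abs(cross), dot) * 180 / pi # exterior turning angle
    concave <- if (ccw) cross < 0 else cross > 0
    if (concave && ang > angle_deg) out <- c(out, i)
  }
  out
}

bresenham <- function(p, q) {
  n <- max(abs(q - p)) + 1L
  r <- round(seq(p[1], q[1], length.out = n))
  c_ <- round(seq(p[2], q[2], length.out = n))
  cbind(r, c_)
}

#' Smooth nucleus borders and re-apply the area filter
#'
#' Morphological opening then closing with a 3x3 structuring element applied
#' per object; pixels already claimed by another nucleus are never taken, so
#' masks stay disjoint.  Objects falling below the minimum area are removed.
#'
#' @param lab integer nucleus label matrix.
#' @param min_area_px minimum nuclear area.
#' @return Smoothed label matrix.
#' @export
postprocess_nuclei <- function(lab, min_area_px = 30L) {
  ids <- sort(setdiff(unique(as.integer(lab)), 0L))
  if (!length(ids)) return(lab)
  out <- matrix(0L, nrow(lab), ncol(lab))
  boxes <- label_bboxes(lab, ids)
  for (i in seq_along(ids)) {
    b <- expand_bbox(boxes[i, ], 2L, dim(lab))
    sub <- lab[b[1]:b[2], b[3]:b[4], drop = FALSE]
    m <- sub == ids[i]
    sm <- morph_close3(morph_open3(m))
    sm <- sm & (sub == ids[i] | sub == 0L)   # never take another nucleus
    if (sum(sm) >= min_area_px) {
      osub <- out[b[1]:b[2], b[3]:b[4], drop = FALSE]
      sm <- sm & osub == 0L
      osub[sm] <- ids[i]
      out[b[1]:b[2], b[3]:b[4]] <- osub
    }
  }
  out
}

# row/col bounding boxes of positive labels: matrix [id, r0, r1, c0, c1]
label_bboxes <- function(lab, ids) {
  px <- which(lab > 0L)
  v <- lab[px]
  nr <- nrow(lab)
  r <- (px - 1L) %% nr + 1L
  c_ <- (px - 1L) %/% nr + 1L
  g <- match(v, ids)
  cbind(r0 = tapply(r, g, min), r1 = tapply(r, g, max),
        c0 = tapply(c_, g, min), c1 = tapply(c_, g, max))
}

expand_bbox <- function(b, pad, dims) {
  c(max(1L, b[1] - pad), min(dims[1], b[2] + pad),
    max(1L, b[3] - pad), min(dims[2], b[4] + pad))
}

#' Detect and classify nuclei in a full-resolution tile
#'
#' Runs the complete per-tile chain: HSD stain separation, thresholded
#' nuclear regions, watershed splitting per stain channel, concavity cuts of
#' merged nuclei, border smoothing, and the minimum-area filter.
#'
#' @param tile an [rgb_raster] full-resolution tile.
#' @param ref a [stain_reference()].
#' @param roi optional logical mask restricting detection (e.g. the
#'   upsampled lobule outline).
#' @param stain_threshold nuclear-region density threshold.
#' @param min_area_px minimum nuclear area.
#' @param dent_angle_deg dent significance threshold in degrees.
#' @return List with the nucleus table (`nucleus_id`, `stain_class`,
#'   `area_px`, `centroid_row`, `centroid_col`) and the two label matrices.
#' @export
detect_nuclei <- function(tile, ref = stain_reference(), roi = NULL,
                          stain_threshold = 0.2, min_area_px = 30L,
                          dent_angle_deg = 30) {
  layers <- hsd_deconvolve(tile, ref)
  regions <- nuclear_regions(layers, stain_threshold)
  if (!is.null(roi)) {
    regions$mask_dab <- regions$mask_dab & roi
    regions$mask_hema <- regions$mask_hema & roi
  }
  per_channel <- function(mask, density) {
    lab <- split_nuclei(mask, density, min_area_px)
    lab <- apply_dent_cuts(lab, dent_angle_deg, min_area_px)
    postprocess_nuclei(lab, min_area_px)
  }
  lab_dab <- per_channel(regions$mask_dab, layers$dab$values)
  lab_hema <- per_channel(regions$mask_hema, layers$hema$values)
  tab <- rbind(nucleus_table(lab_dab, "positive"),
               nucleus_table(lab_hema, "negative"))
  if (nrow(tab)) tab$nucleus_id <- seq_len(nrow(tab))
  list(nuclei = tab, lab_dab = lab_dab, lab_hema = lab_hema,
       clamped = layers$clamped)
}

apply_dent_cuts <- function(lab, dent_angle_deg, min_area_px) {
  ids <- sort(setdiff(unique(as.integer(lab)), 0L))
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (!length(ids)) return(out)
  next_id <- 0L
  boxes <- label_bboxes(lab, ids)
  for (i in seq_along(ids)) {
    b <- expand_bbox(boxes[i, ], 2L, dim(lab))
    sub <- lab[b[1]:b[2], b[3]:b[4], drop = FALSE] == ids[i]
    frags <- dent_cut(sub, dent_angle_deg, min_area_px)
    osub <- out[b[1]:b[2], b[3]:b[4], drop = FALSE]
    for (fr in frags) {
      next_id <- next_id + 1L
      osub[fr] <- next_id
    }
    out[b[1]:b[2], b[3]:b[4]] <- osub
  }
  out
}

nucleus_table <- function(lab, stain_class) {
  ids <- sort(setdiff(unique(as.integer(lab)), 0L))
  if (!length(ids)) {
    return(data.frame(nucleus_id = integer(0), stain_class = character(0),
                      area_px = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), stringsAsFactors = FALSE))
  }
  idx <- which(lab > 0L, arr.ind = TRUE)
  g <- match(lab[lab > 0L], ids)
  area <- tabulate(g, nbins = length(ids))
  data.frame(nucleus_id = ids, stain_class = stain_class,
             area_px = area,
             centroid_row = as.numeric(rowsum(idx[, 1], g)) / area - 1,
             centroid_col = as.numeric(rowsum(idx[, 2], g)) / area - 1,
             stringsAsFactors = FALSE)
}

#' Nuclear positivity of one lobule at full resolution
#'
#' Counts DAB-positive and hematoxylin-negative nuclei inside the lobule's
#' upsampled region of interest and returns the positive fraction
#' `n_pos / (n_pos + n_neg)`; with zero nuclei the ratio is `NA`.
#'
#' @param tile full-resolution [rgb_raster] covering the lobule.
#' @param roi logical matrix on the tile grid marking the lobule region.
#' @param ref a [stain_reference()].
#' @param ... further arguments passed to [detect_nuclei()].
#' @return List `n_pos`, `n_neg`, `ratio`.
#' @export
lobule_positivity <- function(tile, roi, ref = stain_reference(), ...) {
  det <- detect_nuclei(tile, ref, roi = roi, ...)
  n_pos <- sum(det$nuclei$stain_class == "positive")
  n_neg <- sum(det$nuclei$stain_class == "negative")
  ratio <- if (n_pos + n_neg == 0) NA_real_ else n_pos / (n_pos + n_neg)
  list(n_pos = n_pos, n_neg = n_neg, ratio = ratio, detection = det)
}
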