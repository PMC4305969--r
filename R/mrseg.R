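#' Texture-weighted multiresolution segmentation hierarchy
#'
#' Bottom-up region merging over the tissue mask: every tissue pixel starts
#' as a segment and the globally cheapest adjacent pair is merged repeatedly,
#' where the cost of a merge is the weighted sum over channels (R, G, B,
#' texture) of the increase in `area x within-segment standard deviation`.
#' The full merge tree is then cut at cost threshold `scale^2` for each scale,
#' giving strictly nested levels: a segment at a finer level is a sub-segment
#' of exactly one segment at every coarser level.  The texture channel is
#' weighted twice as much as the colour channels by default, which makes the
#' bright lobule blobs in the stddev-n channel coalesce into their own
#' segments.
#'
#' @param image an [rgb_raster] at working resolution.
#' @param texture the texture [raster_layer] from [build_texture_layer()].
#' @param mask a [tissue_mask]; pixels outside it belong to no segment.
#' @param scales strictly descending scale parameters, coarsest first.
#' @param weights non-negative channel weights (R, G, B, texture).
#' @param shape_weight weight of the shape-heterogeneity term (compactness /
#'   smoothness, the reference algorithm's convention) relative to one
#'   spectral channel.  A positive weight suppresses the thin irregular
#'   "halo" segments that pure spectral merging produces along smoothed
#'   texture edges; 0 gives spectral-only merging.
#' @param compactness mix between the compactness (`perimeter * sqrt(n)`)
#'   and smoothness (`n * perimeter / bbox perimeter`) shape terms.
#' @return A `seg_hierarchy`: list of `seg_level`s coarse to fine, each with a
#'   label image, per-segment features, adjacency (shared border lengths in
#'   pixel edges) and parent links into the level above.
#' @export
multires_hierarchy <- function(image, texture, mask,
                               scales = c(100, 80, 60, 40, 20),
                               weights = c(1, 1, 1, 2),
                               shape_weight = 1, compactness = 0.5) {
  stopifnot(inherits(image, "rgb_raster"), inherits(texture, "raster_layer"),
            inherits(mask, "tissue_mask"))
  if (any(diff(scales) >= 0)) stop("scales must be strictly descending")
  if (length(weights) != 4L || any(weights < 0) || all(weights == 0)) {
    stop("weights must be 4 non-negative values, not all zero")
  }
  if (!any(mask$mask)) stop("empty tissue mask: nothing to segment")
  d <- dim(image$pixels)
  stopifnot(all(dim(texture$values) == d[1:2]), all(dim(mask$mask) == d[1:2]))

  channels <- array(0, dim = c(d[1], d[2], 4L))
  channels[, , 1:3] <- image$pixels
  channels[, , 4] <- texture$values
  # raw (unsmoothed) stddev-n: the feature channel for classification; the
  # median+Gaussian smoothed layer above is the segmentation channel
  stddevn_raw <- stddev_to_neighbors(image$pixels[, , 3, drop = TRUE])
  merges <- cpp_mrseg_merges(channels, as.numeric(weights), mask$mask,
                             shape_weight, compactness)
  a <- as.integer(merges$a); b <- as.integer(merges$b)
  cost <- as.numeric(merges$cost)

  # prefix cut: level for scale s applies merges up to the first one whose
  # cost exceeds s^2; prefix cuts of one sequence are nested by construction
  cut_k <- function(s) {
    over <- which(cost > s^2)
    if (length(over)) over[1] - 1L else length(cost)
  }
  levels <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    k <- cut_k(scales[i])
    lab <- cpp_cut_labels(mask$mask, a, b, k)
    levels[[i]] <- build_level(lab, channels, stddevn_raw, scales[i], i - 1L,
                               image$pixel_size_um,
                               with_roundness = TRUE)
  }
  # parent links: the coarse label at any member pixel of a fine segment
  for (i in seq_along(levels)[-1]) {
    fine <- levels[[i]]
    coarse_lab <- levels[[i - 1]]$labels
    rep_px <- fine$features$id      # id is the segment's smallest pixel index
    fine$features$parent <- coarse_lab[rep_px]
    levels[[i]] <- fine
  }
  levels[[1]]$features$parent <- NA_integer_
  structure(list(levels = levels,
                 merges = list(a = a, b = b, cost = cost),
                 channels = channels,
                 stddevn = stddevn_raw,
                 mask = mask$mask,
                 pixel_size_um = image$pixel_size_um),
            class = "seg_hierarchy")
}

#' @export
print.seg_hierarchy <- function(x, ...) {
  cat("<seg_hierarchy>\n")
  for (lv in x$levels) {
    cat(sprintf("  level %d (scale %g): %d segments\n",
                lv$level_index, lv$scale, nrow(lv$features)))
  }
  invisible(x)
}

build_level <- function(lab, channels, stddevn_raw, scale, level_index,
                        pixel_size_um, with_roundness = TRUE) {
  inside <- lab > 0L
  labv <- lab[inside]
  ids <- sort(unique(labv))
  grp <- match(labv, ids)
  area <- tabulate(grp, nbins = length(ids))
  ch_means <- vapply(1:4, function(k) {
    v <- channels[, , k][inside]
    as.numeric(rowsum(v, grp)) / area
  }, numeric(length(ids)))
  if (is.null(dim(ch_means))) ch_means <- matrix(ch_means, nrow = 1L)
  sdn_mean <- as.numeric(rowsum(stddevn_raw[inside], grp)) / area
  feats <- data.frame(
    id = ids,
    area_px = area,
    mean_r = ch_means[, 1],
    mean_g = ch_means[, 2],
    mean_b = ch_means[, 3],
    mean_texture = ch_means[, 4],
    mean_stddevn = sdn_mean,
    roundness = NA_real_,
    parent = NA_integer_
  )
  if (with_roundness) {
    feats$roundness <- segment_roundness_all(lab, ids)
  }
  adjacency <- cpp_label_adjacency(lab)
  perimeter <- cpp_label_perimeter(lab)
  structure(list(level_index = level_index, scale = scale, labels = lab,
                 features = feats, adjacency = adjacency,
                 perimeter = perimeter, pixel_size_um = pixel_size_um),
            class = "seg_level")
}

#' @export
print.seg_level <- function(x, ...) {
  cat(sprintf("<seg_level> index %d, scale %g, %d segments\n",
              x$level_index, x$scale, nrow(x$features)))
  invisible(x)
}

# --- roundness ---------------------------------------------------------------

#' Roundness from analytic radii
#'
#' The roundness feature is the radius of the smallest enclosing circle minus
#' the radius of the largest inscribed circle, normalised by the radius of
#' the circle of equal area: `(r_enclosing - r_inscribed) / sqrt(area / pi)`.
#' Smaller is rounder; a perfect disk scores 0 because all three radii
#' coincide.  Lobule candidates are accepted in the range 0-1.3.
#'
#' @param r_enclosing radius of the smallest enclosing circle.
#' @param r_inscribed radius of the largest inscribed circle.
#' @param area object area (same length unit, squared).
#' @return Dimensionless roundness, >= 0 for any real shape.
#' @export
roundness_from_radii <- function(r_enclosing, r_inscribed, area) {
  stopifnot(area > 0, r_enclosing >= 0, r_inscribed >= 0)
  (r_enclosing - r_inscribed) / sqrt(area / pi)
}

#' Roundness of a rasterised object
#'
#' `r_inscribed` comes from the Euclidean distance transform of the mask,
#' `r_enclosing` from the minimal enclosing circle of the boundary pixel
#' centres (plus half a pixel to reach the pixel boundary).
#'
#' @param mask logical matrix containing a single object.
#' @return Dimensionless roundness.
#' @export
mask_roundness <- function(mask) {
  stopifnot(any(mask))
  area <- sum(mask)
  # pad so objects touching the frame still have an outside
  pad <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  dt <- distance_transform(pad)
  r_in <- max(dt[pad]) - 0.5          # centre-to-centre minus half pixel
  if (r_in < 0) r_in <- 0
  idx <- which(mask, arr.ind = TRUE)
  mec <- min_enclosing_circle(idx)
  r_out <- mec$r + 0.5                # pixel centres to pixel extent
  roundness_from_radii(r_out, r_in, area)
}

segment_roundness_all <- function(lab, ids) {
  px <- which(lab > 0L)
  grp <- match(lab[px], ids)
  nr <- nrow(lab)
  by_seg <- split(px, grp)
  vapply(seq_along(ids), function(i) {
    p <- by_seg[[i]]
    r <- (p - 1L) %% nr + 1L
    c_ <- (p - 1L) %/% nr + 1L
    rr <- range(r); cc <- range(c_)
    sub <- matrix(FALSE, rr[2] - rr[1] + 1L, cc[2] - cc[1] + 1L)
    sub[cbind(r - rr[1] + 1L, c_ - cc[1] + 1L)] <- TRUE
    mask_roundness(sub)
  }, numeric(1))
}

# Minimal enclosing circle (Welzl, deterministic order).
min_enclosing_circle <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) > 3L) {
    hull <- grDevices::chull(pts[, 2], pts[, 1])
    pts <- pts[hull, , drop = FALSE]
  }
  n <- nrow(pts)
  if (n == 1L) return(list(center = pts[1, ], r = 0))
  # deterministic pseudo-shuffle to keep Welzl near linear on adversarial input
  ord <- order((seq_len(n) * 2654435761) %% 4294967296)
  pts <- pts[ord, , drop = FALSE]
  circ2 <- function(p, q) {
    ctr <- (p + q) / 2
    list(center = ctr, r = sqrt(sum((p - ctr)^2)))
  }
  circ3 <- function(p, q, r) {
    ax <- p[2]; ay <- p[1]; bx <- q[2]; by <- q[1]; cx <- r[2]; cy <- r[1]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    ctr <- c(uy, ux)
    list(center = ctr, r = sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  inside <- function(circ, p, eps = 1e-9) {
    sqrt(sum((p - circ$center)^2)) <= circ$r + eps
  }
  trivial <- function(boundary) {
    nb <- nrow(boundary)
    if (nb == 0L) return(list(center = c(0, 0), r = -1))
    if (nb == 1L) return(list(center = boundary[1, ], r = 0))
    if (nb == 2L) return(circ2(boundary[1, ], boundary[2, ]))
    for (i in 1:2) for (j in (i + 1):3) {
      cc <- circ2(boundary[i, ], boundary[j, ])
      k <- setdiff(1:3, c(i, j))
      if (inside(cc, boundary[k, ])) return(cc)
    }
    c3 <- circ3(boundary[1, ], boundary[2, ], boundary[3, ])
    if (is.null(c3)) {
      # collinear: widest pair
      dists <- c(sum((boundary[1, ] - boundary[2, ])^2),
                 sum((boundary[1, ] - boundary[3, ])^2),
                 sum((boundary[2, ] - boundary[3, ])^2))
      pick <- list(c(1, 2), c(1, 3), c(2, 3))[[which.max(dists)]]
      return(circ2(boundary[pick[1], ], boundary[pick[2], ]))
    }
    c3
  }
  circ <- trivial(pts[0, , drop = FALSE])
  bnd <- pts[0, , drop = FALSE]
  welzl <- function(i, bnd) {
    circ <- trivial(bnd)
    if (nrow(bnd) == 3L) return(circ)
    for (j in seq_len(i)) {
      p <- pts[j, ]
      if (circ$r < 0 || !inside(circ, p)) {
        circ <- welzl(j - 1L, rbind(bnd, p))
      }
    }
    circ
  }
  welzl(n, bnd)
}

# --- relational features -----------------------------------------------------

#' Border contrast between two adjacent segments
#'
#' Michelson contrast `(m_a - m_b) / (m_a + m_b)` of the mean layer values
#' over the 1-pixel-deep strips of each segment along the shared border.
#' Positive when `a` is brighter; 0 when both strips have mean 0.
#'
#' @param level a `seg_level`.
#' @param id_a,id_b adjacent segment ids.
#' @param layer numeric matrix (typically the texture layer values).
#' @return Contrast in `[-1, 1]`.
#' @export
border_contrast <- function(level, id_a, id_b, layer) {
  lab <- level$labels
  strip_a <- strip_b <- matrix(FALSE, nrow(lab), ncol(lab))
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- shift_mat(lab, d[1], d[2], fill = 0)
    strip_a <- strip_a | (lab == id_a & nb == id_b)
    strip_b <- strip_b | (lab == id_b & nb == id_a)
  }
  if (!any(strip_a) || !any(strip_b)) stop("segments are not adjacent")
  m_a <- mean(layer[strip_a])
  m_b <- mean(layer[strip_b])
  if (m_a + m_b == 0) return(0)
  (m_a - m_b) / (m_a + m_b)
}

#' Difference of means to neighbouring segments
#'
#' Segment mean minus the shared-border-length-weighted mean of its
#' neighbours' means, in layer units.  Used on the stddev-n channel: lobules
#' must exceed their surroundings by at least 5.
#'
#' @param level a `seg_level`.
#' @param id segment id.
#' @param means named vector of per-segment layer means (names = ids);
#'   defaults to the level's `mean_stddevn`.
#' @return Difference in layer units; 0 if the segment has no neighbours.
#' @export
diff_of_means <- function(level, id, means = NULL) {
  if (is.null(means)) {
    means <- stats::setNames(level$features$mean_stddevn, level$features$id)
  }
  adj <- level$adjacency
  sel <- adj$a == id | adj$b == id
  if (!any(sel)) return(0)
  nb <- ifelse(adj$a[sel] == id, adj$b[sel], adj$a[sel])
  w <- adj$border[sel]
  own <- means[[as.character(id)]]
  own - sum(w * means[as.character(nb)]) / sum(w)
}

# All border strips at once: for every ordered adjacent pair (a, b) the mean
# of `layer` over the 1-pixel strip of segment a along its border with b.
# Returns a data.frame (a, b, strip_mean, n_px).
strip_pair_means <- function(lab, layer) {
  acc_px <- integer(0); acc_a <- integer(0); acc_b <- integer(0)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- shift_mat(lab, d[1], d[2], fill = 0)
    sel <- which(lab > 0L & nb > 0L & lab != nb)
    acc_px <- c(acc_px, sel)
    acc_a <- c(acc_a, lab[sel])
    acc_b <- c(acc_b, nb[sel])
  }
  if (!length(acc_px)) {
    return(data.frame(a = integer(0), b = integer(0),
                      strip_mean = numeric(0), n_px = integer(0)))
  }
  dup <- duplicated(cbind(acc_px, acc_a, acc_b))
  acc_px <- acc_px[!dup]; acc_a <- acc_a[!dup]; acc_b <- acc_b[!dup]
  key <- interaction(acc_a, acc_b, drop = TRUE)
  v <- layer[acc_px]
  s <- rowsum(v, key)
  n <- tabulate(key, nbins = nlevels(key))
  parts <- strsplit(rownames(s), ".", fixed = TRUE)
  data.frame(a = as.integer(vapply(parts, `[`, "", 1L)),
             b = as.integer(vapply(parts, `[`, "", 2L)),
             strip_mean = as.numeric(s) / n,
             n_px = n)
}

# Border-length-weighted mean Michelson contrast for every segment of a
# level against its neighbours, computed from the segment means of the raw
# stddev-n channel.  (The 1-px strip variant of border_contrast() is not
# usable as a classification feature: the strips on both sides of an edge
# lie inside the 3x3 edge-response band of the deviation statistic, which
# caps strip contrast around 0.2 however strong the true edge is.)
all_border_contrasts <- function(level, layer = NULL) {
  adj <- level$adjacency
  if (!nrow(adj)) {
    return(stats::setNames(rep(0, nrow(level$features)), level$features$id))
  }
  means <- stats::setNames(level$features$mean_stddevn, level$features$id)
  m_ab <- means[as.character(adj$a)]
  m_ba <- means[as.character(adj$b)]
  tot <- m_ab + m_ba
  ct <- ifelse(tot == 0, 0, (m_ab - m_ba) / tot)  # contrast of a vs b
  ids <- level$features$id
  num <- stats::setNames(rep(0, length(ids)), ids)
  den <- num
  acc <- function(seg, val) {
    ws <- rowsum(cbind(adj$border * val, adj$border), seg)
    num[rownames(ws)] <<- num[rownames(ws)] + ws[, 1]
    den[rownames(ws)] <<- den[rownames(ws)] + ws[, 2]
  }
  acc(adj$a, ct)
  acc(adj$b, -ct)
  ifelse(den > 0, num / den, 0)
}

# Difference of means for every segment of a level in one pass.
all_diff_of_means <- function(level) {
  ids <- level$features$id
  means <- stats::setNames(level$features$mean_stddevn, ids)
  adj <- level$adjacency
  num <- stats::setNames(rep(0, length(ids)), ids)
  den <- num
  if (nrow(adj)) {
    acc <- function(seg, other) {
      ws <- rowsum(cbind(adj$border * means[as.character(other)], adj$border),
                   seg)
      num[rownames(ws)] <<- num[rownames(ws)] + ws[, 1]
      den[rownames(ws)] <<- den[rownames(ws)] + ws[, 2]
    }
    acc(adj$a, adj$b)
    acc(adj$b, adj$a)
  }
  ifelse(den > 0, means - num / den, 0)
}

# Border-length-weighted mean Michelson contrast of a segment to all its
# neighbours (single-segment variant of all_border_contrasts()).
segment_border_contrast <- function(level, id, layer) {
  adj <- level$adjacency
  sel <- adj$a == id | adj$b == id
  if (!any(sel)) return(0)
  nb <- ifelse(adj$a[sel] == id, adj$b[sel], adj$a[sel])
  w <- adj$border[sel]
  ct <- vapply(nb, function(j) border_contrast(level, id, j, layer),
               numeric(1))
  sum(w * ct) / sum(w)
}
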