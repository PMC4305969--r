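#' Seed segments for tumor growth
#'
#' Over all tissue segments of the final-lobule level that are not lobules,
#' the median of the mean stddev-n values is taken; segments within +-0.1 of
#' that median become seeds.  In slides with a coherent tumor mass the
#' median-texture segments lie inside the tumor: stroma is smoother and
#' lobules rougher than the dense but lumen-free tumor sheet.
#'
#' @param hier a `seg_hierarchy`.
#' @param lobule_ids level-3 segment ids already classified as lobule.
#' @param tolerance half-width of the acceptance band around the median.
#' @param level_index level on which growth operates (default 3, the level
#'   holding the final lobule classification).
#' @param min_area_px minimum segment area entering the median and the seed
#'   set; few-pixel fragments of the deepest cuts are not "tissue segments"
#'   in the sense of the seeding rule and their means form a continuum that
#'   would swamp the median.
#' @return Integer vector of seed segment ids.
#' @export
select_seeds <- function(hier, lobule_ids = integer(0), tolerance = 0.1,
                         level_index = 3L, min_area_px = 50L) {
  stopifnot(inherits(hier, "seg_hierarchy"))
  f <- hier$levels[[level_index + 1L]]$features
  f <- f[!(f$id %in% lobule_ids) & f$area_px >= min_area_px, , drop = FALSE]
  if (!nrow(f)) stop("no non-lobule segment to seed from")
  # segment means of the smoothed texture field: stable regional estimates,
  # which the tight +-0.1 band presupposes
  med <- stats::median(f$mean_texture)
  seeds <- f$id[abs(f$mean_texture - med) <= tolerance]
  if (!length(seeds)) {
    stop(sprintf(paste0("no segment within +-%g of the median stddev-n ",
                        "(%.3f); increase the seed tolerance"),
                 tolerance, med))
  }
  seeds
}

#' Grow the tumor region from seed segments
#'
#' Iterative accretion on the segment adjacency graph: a neighbouring
#' non-lobule segment joins the region iff its mean stddev-n differs from the
#' current region mean by at most `max_delta` AND its shared border with the
#' region is at least `min_border_fraction` of its total border.  The region
#' mean is the area-weighted running mean, updated after every addition.
#' Candidates are processed from a queue ordered by |segment mean - region
#' mean| ascending (ties by id) so the growth order is deterministic.
#'
#' @param hier a `seg_hierarchy`.
#' @param seeds seed segment ids from [select_seeds()].
#' @param lobule_ids segment ids excluded from growth (final lobules).
#' @param max_delta maximum stddev-n deviation from the region mean.
#' @param min_border_fraction minimum shared-border fraction of the
#'   candidate's total border.
#' @param level_index growth level (default 3).
#' @return A `tumor_region`: working-grid mask plus the member segment ids.
#' @export
grow_tumor <- function(hier, seeds, lobule_ids = integer(0), max_delta = 2,
                       min_border_fraction = 0.2, level_index = 3L) {
  stopifnot(inherits(hier, "seg_hierarchy"), length(seeds) >= 1L)
  level <- hier$levels[[level_index + 1L]]
  f <- level$features
  means <- stats::setNames(f$mean_texture, f$id)
  areas <- stats::setNames(f$area_px, f$id)
  per <- stats::setNames(level$perimeter$perimeter, level$perimeter$id)
  adj <- level$adjacency

  member <- stats::setNames(rep(FALSE, nrow(f)), f$id)
  member[as.character(seeds)] <- TRUE
  region_area <- sum(areas[as.character(seeds)])
  region_sum <- sum(means[as.character(seeds)] * areas[as.character(seeds)])

  neighbour_ids <- function() {
    ids <- names(member)[member]
    sel <- (adj$a %in% ids) != (adj$b %in% ids)
    nb <- ifelse(adj$a[sel] %in% ids, adj$b[sel], adj$a[sel])
    setdiff(unique(nb), c(as.integer(ids), lobule_ids))
  }
  shared_border <- function(id) {
    ids <- as.integer(names(member)[member])
    sel <- (adj$a == id & adj$b %in% ids) | (adj$b == id & adj$a %in% ids)
    sum(adj$border[sel])
  }
  repeat {
    region_mean <- region_sum / region_area
    cand <- neighbour_ids()
    if (!length(cand)) break
    dev <- abs(means[as.character(cand)] - region_mean)
    ord <- order(dev, cand)
    added <- FALSE
    for (i in ord) {
      id <- cand[i]
      if (dev[i] > max_delta) break   # sorted: nothing further qualifies
      if (shared_border(id) < min_border_fraction * per[[as.character(id)]]) {
        next
      }
      member[as.character(id)] <- TRUE
      region_area <- region_area + areas[[as.character(id)]]
      region_sum <- region_sum + means[[as.character(id)]] *
        areas[[as.character(id)]]
      added <- TRUE
      break                            # re-rank against the updated mean
    }
    if (!added) break
  }
  ids <- as.integer(names(member)[member])
  mask <- level$labels %in% ids
  dim(mask) <- dim(level$labels)
  structure(list(mask = mask, segment_ids = ids,
                 pixel_size_um = hier$pixel_size_um),
            class = "tumor_region")
}

#' @export
print.tumor_region <- function(x, ...) {
  lab <- label_components(x$mask, 4L)
  cat(sprintf("<tumor_region> %d px, %d component(s), %.3g um/px\n",
              sum(x$mask), max(lab), x$pixel_size_um))
  invisible(x)
}

#' Post-process a grown tumor region
#'
#' Enclosed holes are filled and isolated components smaller than one third
#' of the largest component are eliminated (such fragments are usually false
#' detections at folded tissue borders).
#'
#' @param region a `tumor_region`.
#' @return A cleaned `tumor_region`.
#' @export
postprocess_tumor <- function(region) {
  stopifnot(inherits(region, "tumor_region"), any(region$mask))
  mask <- fill_holes(region$mask)
  lab <- label_components(mask, 4L)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= max(sizes) / 3)
  mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  structure(list(mask = mask, segment_ids = region$segment_ids,
                 pixel_size_um = region$pixel_size_um),
            class = "tumor_region")
}

#' Detect the coherent tumor mass
#'
#' The full tumor stage: seed segments are selected at the final
#' classification level (whose rich segment population carries the median
#' statistic), mapped to their coarsest-level ancestors through the strict
#' nesting, and the delta/shared-border growth runs on the coarsest segment
#' graph -- the scale at which a coherent mass is one or few segments with
#' stable, spatially averaged texture means.  The grown region is
#' post-processed (holes closed, 1/3-largest rule).
#'
#' @param hier a `seg_hierarchy`.
#' @param lobule_labels integer working-grid label image of accepted
#'   lobules (0 = none), as in a `lobule_set`.
#' @param seed_tolerance,seed_min_area_px see [select_seeds()].
#' @param max_delta,min_border_fraction see [grow_tumor()].
#' @return A `tumor_region`.
#' @export
detect_tumor <- function(hier, lobule_labels, seed_tolerance = 0.1,
                         seed_min_area_px = 50L, max_delta = 2,
                         min_border_fraction = 0.2) {
  l3 <- hier$levels[[4L]]$labels
  l0 <- hier$levels[[1L]]$labels
  in_lobule <- lobule_labels > 0L
  lob_ids3 <- setdiff(unique(l3[in_lobule]), 0L)
  seeds3 <- select_seeds(hier, lob_ids3, tolerance = seed_tolerance,
                         min_area_px = seed_min_area_px)
  # coarsest-level ancestors of the seeds; level-0 segments lying mostly
  # inside accepted lobules are excluded from seeding and growth
  f0 <- hier$levels[[1L]]$features
  ov <- table(l0[in_lobule])
  frac <- as.numeric(ov[as.character(f0$id)]) / f0$area_px
  lob0 <- f0$id[!is.na(frac) & frac > 0.3]
  seeds0 <- setdiff(unique(l0[l3 %in% seeds3]), c(0L, lob0))
  if (!length(seeds0)) stop("tumor seeds fall inside excluded segments")
  grown <- grow_tumor(hier, seeds0, lob0, max_delta = max_delta,
                      min_border_fraction = min_border_fraction,
                      level_index = 0L)
  postprocess_tumor(grown)
}

#' Border pixels of a tumor region
#'
#' Tumor pixels with at least one 4-neighbour outside the region (image
#' border counts as outside).
#'
#' @param region a `tumor_region`.
#' @return Logical matrix marking border pixels.
#' @export
tumor_border <- function(region) {
  m <- region$mask
  interior <- erode3_plus(m)
  m & !interior
}

# 4-connected erosion (cross structuring element), outside treated as FALSE
erode3_plus <- function(mask) {
  mask &
    shift_mat_l(mask, 1, 0) & shift_mat_l(mask, -1, 0) &
    shift_mat_l(mask, 0, 1) & shift_mat_l(mask, 0, -1)
}
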