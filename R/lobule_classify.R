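#' Lobule acceptance criteria
#'
#' The printed rule set for a mammary lobule segment at the 5.6 um working
#' resolution: mean stddev-n within 15-36 (regular tubular texture), area
#' 2000-14000 px^2 (0.0627-0.439 mm^2), roundness 0-1.3, difference of
#' stddev-n means to neighbours >= 5 and border contrast >= 0.4 (lobules are
#' brighter than their surroundings in the texture channel).  All conditions
#' must be met.
#'
#' @param stddevn_range accepted range of mean stddev-n.
#' @param area_range_px accepted segment area in working pixels.
#' @param roundness_range accepted roundness range.
#' @param min_diff_of_means minimum difference of stddev-n means.
#' @param min_border_contrast minimum border contrast in the texture channel.
#' @param subdivergence_limit maximum spread (max pairwise difference) of
#'   sub-segment mean stddev-n before a candidate is considered inhomogeneous
#'   and dropped.  The original rule ("too different from each other") names
#'   no value; the default 21 is the width of the accepted lobule texture
#'   class (36 - 15): sub-segments spreading beyond one class width signal a
#'   chimeric candidate, spread within it is within-class variation.
#' @param surround_px width (working px) of the surrounding band against
#'   which the relational features of a candidate are measured; 5 px
#'   (~28 um) reaches through the thin edge-ramp artefacts of the smoothed
#'   texture channel to the actual surroundings.
#' @return A `lobule_criteria` list.
#' @export
lobule_criteria <- function(stddevn_range = c(15, 36),
                            area_range_px = c(2000, 14000),
                            roundness_range = c(0, 1.3),
                            min_diff_of_means = 5,
                            min_border_contrast = 0.4,
                            subdivergence_limit = 21,
                            surround_px = 5) {
  stopifnot(diff(stddevn_range) > 0, diff(area_range_px) > 0,
            diff(roundness_range) > 0, min_diff_of_means >= 0,
            min_border_contrast >= 0, subdivergence_limit >= 0)
  structure(list(stddevn_range = stddevn_range,
                 area_range_px = area_range_px,
                 roundness_range = roundness_range,
                 min_diff_of_means = min_diff_of_means,
                 min_border_contrast = min_border_contrast,
                 subdivergence_limit = subdivergence_limit,
                 surround_px = surround_px),
            class = "lobule_criteria")
}

passes_full_criteria <- function(f, criteria) {
  f$mean_stddevn >= criteria$stddevn_range[1] &
    f$mean_stddevn <= criteria$stddevn_range[2] &
    f$area_px >= criteria$area_range_px[1] &
    f$area_px <= criteria$area_range_px[2] &
    f$roundness >= criteria$roundness_range[1] &
    f$roundness <= criteria$roundness_range[2] &
    f$diff_of_means >= criteria$min_diff_of_means &
    f$border_contrast >= criteria$min_border_contrast
}

# reduced set: full minus minimum area and border contrast
passes_reduced_criteria <- function(f, criteria) {
  f$mean_stddevn >= criteria$stddevn_range[1] &
    f$mean_stddevn <= criteria$stddevn_range[2] &
    f$area_px <= criteria$area_range_px[2] &
    f$roundness >= criteria$roundness_range[1] &
    f$roundness <= criteria$roundness_range[2] &
    f$diff_of_means >= criteria$min_diff_of_means
}

#' Initial per-level lobule candidate classification
#'
#' Applies the full criteria independently to every segment of one of the
#' four coarsest segmentation levels.  Border contrast and difference of
#' means are evaluated against all neighbours, weighted by shared border
#' length; segments without neighbours cannot stand out from surroundings
#' and are never candidates.
#'
#' @param hier a `seg_hierarchy` from [multires_hierarchy()].
#' @param level_index level index 0 (coarsest) to 3.
#' @param criteria a [lobule_criteria()].
#' @return Integer vector of candidate segment ids.
#' @export
initial_classify <- function(hier, level_index, criteria = lobule_criteria()) {
  stopifnot(inherits(hier, "seg_hierarchy"), level_index %in% 0:3)
  level <- hier$levels[[level_index + 1L]]
  f <- level$features
  # cheap texture/geometry gates first; relational features only for the
  # survivors
  pre <- f$mean_stddevn >= criteria$stddevn_range[1] &
    f$mean_stddevn <= criteria$stddevn_range[2] &
    f$area_px >= criteria$area_range_px[1] &
    f$area_px <= criteria$area_range_px[2] &
    f$roundness >= criteria$roundness_range[1] &
    f$roundness <= criteria$roundness_range[2]
  out <- integer(0)
  for (id in f$id[pre]) {
    mask <- level$labels == id
    rel <- band_relational(hier, mask, criteria$surround_px)
    if (rel$diff_of_means >= criteria$min_diff_of_means &&
        rel$border_contrast >= criteria$min_border_contrast) {
      out <- c(out, id)
    }
  }
  out
}

# Relational features of a region against its surrounding band: mean raw
# stddev-n inside the mask versus the mean over the tissue pixels within
# `surround_px` of the mask.  diff_of_means is the absolute difference,
# border_contrast the Michelson contrast.
band_relational <- function(hier, mask, surround_px = 5) {
  raw <- hier$stddevn
  idx <- which(mask, arr.ind = TRUE)
  pad <- surround_px + 1L
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(mask), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(mask), max(idx[, 2]) + pad)
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  dt <- distance_transform(!sub)
  band <- !sub & dt <= surround_px & hier$mask[r0:r1, c0:c1]
  m_in <- mean(raw[mask])
  if (!any(band)) {
    return(list(diff_of_means = 0, border_contrast = 0))
  }
  m_b <- mean(raw[r0:r1, c0:c1][band])
  list(diff_of_means = m_in - m_b,
       border_contrast = if (m_in + m_b == 0) 0 else
         (m_in - m_b) / (m_in + m_b))
}

# Features of a region formed by a set of same-level segments.  Relational
# features come from the surrounding band (band_relational), so they are
# independent of how the surroundings happen to be partitioned at any level.
region_full_features <- function(hier, level_index, ids,
                                 criteria = lobule_criteria()) {
  lab <- hier$levels[[level_index + 1L]]$labels
  inside <- lab %in% ids
  dim(inside) <- dim(lab)
  mask_full_features(hier, inside, criteria)
}

#' Hierarchical refinement of lobule candidates
#'
#' Every candidate from [initial_classify()] is checked once against its
#' sub-segments on the next finer level: (a) if the sub-segments' mean
#' stddev-n values spread more than the sub-divergence limit, the candidate
#' is dropped; (b) if all sub-segments satisfy the reduced criteria (full
#' set minus minimum area and border contrast) the candidate is accepted
#' whole; (c) otherwise failing peripheral sub-segments (at least half of
#' their border on the candidate outline) are removed iteratively and the
#' merged remainder is accepted iff it passes the full criteria.  Accepted
#' candidates are carried unchanged to the final classification (the fourth
#' level); candidates covered by an already-accepted coarser lobule are
#' skipped.  A last pass merges adjacent reduced-criteria segments at each
#' level and reclassifies groups that pass the full criteria.
#'
#' @param hier a `seg_hierarchy`.
#' @param initial list of candidate id vectors for levels 0-3, as returned
#'   by [initial_classify()] per level.
#' @param criteria a [lobule_criteria()].
#' @return A `lobule_set`: label image of accepted lobules plus a feature
#'   table (id, centroid, area, stddev-n, roundness, review label).
#' @export
refine_lobules <- function(hier, initial, criteria = lobule_criteria()) {
  stopifnot(inherits(hier, "seg_hierarchy"), length(initial) >= 4L)
  # reduced-criteria tables for the four sub-segment levels (1..4)
  red_pass <- vector("list", 5L)
  for (li in 1:4) {
    level <- hier$levels[[li + 1L]]
    f <- level$features
    f$diff_of_means <- as.numeric(all_diff_of_means(level))
    red_pass[[li + 1L]] <- stats::setNames(
      passes_reduced_criteria(f, criteria), f$id)
  }

  dims <- dim(hier$levels[[1L]]$labels)
  covered <- matrix(FALSE, dims[1], dims[2])
  masks <- list()
  for (li in 0:3) {
    lab <- hier$levels[[li + 1L]]$labels
    child_lab <- hier$levels[[li + 2L]]$labels
    for (id in initial[[li + 1L]]) {
      seg <- lab == id
      if (sum(seg & covered) / sum(seg) >= 0.3) next
      C <- refine_one(hier, li, id, criteria, red_pass[[li + 2L]])
      if (!length(C)) next
      m <- child_lab %in% C
      dim(m) <- dims
      masks[[length(masks) + 1L]] <- m
      covered <- covered | m
    }
  }

  # last pass: merge adjacent reduced-criteria segments, pairwise until
  # fixpoint, and reclassify groups that pass the full criteria.  Spares
  # are gated with the surrounding-band diff of means (a fragmented
  # lobule's sibling pieces would poison the neighbour-weighted one).
  for (li in 0:3) {
    level <- hier$levels[[li + 1L]]
    f <- level$features
    pre <- f$mean_stddevn >= criteria$stddevn_range[1] &
      f$mean_stddevn <= criteria$stddevn_range[2] &
      f$area_px <= criteria$area_range_px[2] &
      f$roundness >= criteria$roundness_range[1] &
      f$roundness <= criteria$roundness_range[2]
    ov <- table(level$labels[covered])
    touched <- as.integer(names(ov))
    cand_ids <- f$id[pre & !(f$id %in% touched)]
    spare <- integer(0)
    for (id in cand_ids) {
      m <- level$labels == id
      rel <- band_relational(hier, m, criteria$surround_px)
      if (rel$diff_of_means >= criteria$min_diff_of_means) {
        spare <- c(spare, id)
      }
    }
    groups <- merge_adjacent_pass(hier, spare, criteria, level_index = li)
    for (g in groups) {
      m <- level$labels %in% g
      dim(m) <- dims
      masks[[length(masks) + 1L]] <- m
      covered <- covered | m
    }
  }
  build_lobule_set(hier, masks, criteria)
}

refine_one <- function(hier, level_index, S, criteria, red_pass_child,
                       origin = level_index) {
  target <- level_index + 1L
  child_feats <- hier$levels[[target + 1L]]$features
  C <- child_feats$id[child_feats$parent %in% S]
  if (!length(C)) return(integer(0))
  if (length(C) == 1L) return(C)   # same pixels, evaluated directly
  # rule (a): sub-segments too different from each other.  Judged on the
  # max pairwise difference of mean stddev-n among sub-segments holding a
  # meaningful share (>= 10%) of the candidate's area: a chimeric candidate
  # (half stroma, half lobule) always has large divergent halves, whereas
  # fine-scale micro-fragments of a genuinely spiky lobule interior would
  # produce extreme means that are not evidence of inhomogeneity.
  sd_means <- child_feats$mean_stddevn[match(C, child_feats$id)]
  areas <- child_feats$area_px[match(C, child_feats$id)]
  big <- areas >= 0.1 * sum(areas)
  if (sum(big) >= 2L &&
      max(sd_means[big]) - min(sd_means[big]) > criteria$subdivergence_limit) {
    return(integer(0))
  }
  ok <- red_pass_child[as.character(C)]
  if (all(ok)) return(C)           # rule (b): accept whole
  # rule (c): iteratively remove failing peripheral sub-segments
  level <- hier$levels[[target + 1L]]
  adj <- level$adjacency
  per <- stats::setNames(level$perimeter$perimeter, level$perimeter$id)
  repeat {
    failing <- C[!red_pass_child[as.character(C)]]
    if (!length(failing)) break
    removed_any <- FALSE
    for (id in sort(failing)) {
      sel <- (adj$a == id & adj$b %in% C) | (adj$b == id & adj$a %in% C)
      internal <- sum(adj$border[sel])
      outline_frac <- 1 - internal / per[[as.character(id)]]
      if (outline_frac >= 0.5) {
        C <- setdiff(C, id)
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  if (!length(C)) return(integer(0))
  f <- region_full_features(hier, target, C, criteria)
  if (passes_full_criteria(f, criteria)) C else integer(0)
}

merge_adjacent_pass <- function(hier, spare_ids, criteria,
                                level_index = 3L) {
  if (length(spare_ids) < 2L) return(list())
  adj <- hier$levels[[level_index + 1L]]$adjacency
  # first merge each connected component of adjacent reduced-criteria
  # segments whole and test it against the full criteria; a fragmented
  # lobule only passes the contrast gate once ALL of its pieces are united
  # (any partial union keeps the remaining pieces in its surround).
  # Components that fail as a whole fall back to pairwise merging.
  comp <- spare_components(spare_ids, adj)
  out <- list()
  leftovers <- list()
  for (members in comp) {
    if (length(members) >= 2L) {
      f <- region_full_features(hier, level_index, members, criteria)
      if (passes_full_criteria(f, criteria)) {
        out[[length(out) + 1L]] <- members
        next
      }
    }
    leftovers[[length(leftovers) + 1L]] <- members
  }
  for (members in leftovers) {
    if (length(members) < 2L) next
    out <- c(out, merge_pairwise(hier, members, criteria, level_index, adj))
  }
  out
}

spare_components <- function(ids, adj) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  sel <- adj$a %in% ids & adj$b %in% ids
  for (k in which(sel)) {
    ra <- find(adj$a[k]); rb <- find(adj$b[k])
    if (ra != rb) parent[[as.character(max(ra, rb))]] <- min(ra, rb)
  }
  roots <- vapply(ids, find, numeric(1))
  unname(split(ids, roots))
}

merge_pairwise <- function(hier, spare_ids, criteria, level_index, adj) {
  groups <- as.list(sort(spare_ids))
  accepted <- logical(length(groups))
  repeat {
    merged_any <- FALSE
    n <- length(groups)
    for (i in seq_len(n - 1L)) {
      if (is.null(groups[[i]])) next
      for (j in (i + 1L):n) {
        if (is.null(groups[[j]])) next
        touch <- any((adj$a %in% groups[[i]] & adj$b %in% groups[[j]]) |
                     (adj$b %in% groups[[i]] & adj$a %in% groups[[j]]))
        if (!touch) next
        u <- c(groups[[i]], groups[[j]])
        f <- region_full_features(hier, level_index, u, criteria)
        if (passes_full_criteria(f, criteria)) {
          groups[[i]] <- u
          groups[[j]] <- NULL
          accepted[i] <- TRUE
          accepted <- accepted[-j]
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  groups[accepted & lengths(groups) > 1L]
}

build_lobule_set <- function(hier, lob_masks,
                             criteria = lobule_criteria()) {
  dims <- dim(hier$levels[[1L]]$labels)
  out_lab <- matrix(0L, dims[1], dims[2])
  rows <- list()
  k <- 0L
  for (m in lob_masks) {
    k <- k + 1L
    out_lab[m] <- k
    idx <- which(m, arr.ind = TRUE)
    f <- mask_full_features(hier, m, criteria)
    rows[[k]] <- data.frame(
      lobule_id = k,
      centroid_row = mean(idx[, 1]) - 1,   # 0-based pixel-centre coords
      centroid_col = mean(idx[, 2]) - 1,
      area_px = f$area_px,
      area_mm2 = area_px_to_mm2(f$area_px, hier$pixel_size_um),
      mean_stddevn = f$mean_stddevn,
      roundness = f$roundness,
      diff_of_means = f$diff_of_means,
      border_contrast = f$border_contrast,
      review_label = "unreviewed",
      stringsAsFactors = FALSE
    )
  }
  feats <- if (k) do.call(rbind, rows) else data.frame(
    lobule_id = integer(0), centroid_row = numeric(0),
    centroid_col = numeric(0), area_px = integer(0), area_mm2 = numeric(0),
    mean_stddevn = numeric(0), roundness = numeric(0),
    diff_of_means = numeric(0), border_contrast = numeric(0),
    review_label = character(0), stringsAsFactors = FALSE)
  structure(list(labels = out_lab, features = feats, masks = lob_masks,
                 pixel_size_um = hier$pixel_size_um),
            class = "lobule_set")
}

# full feature set of an arbitrary pixel mask
mask_full_features <- function(hier, mask, criteria = lobule_criteria()) {
  area <- sum(mask)
  mean_sd <- mean(hier$stddevn[mask])
  idx <- which(mask, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  sub <- matrix(FALSE, rr[2] - rr[1] + 1L, cc[2] - cc[1] + 1L)
  sub[cbind(idx[, 1] - rr[1] + 1L, idx[, 2] - cc[1] + 1L)] <- TRUE
  rnd <- mask_roundness(sub)
  rel <- band_relational(hier, mask, criteria$surround_px)
  list(area_px = area, mean_stddevn = mean_sd, roundness = rnd,
       diff_of_means = rel$diff_of_means,
       border_contrast = rel$border_contrast)
}

#' @export
print.lobule_set <- function(x, ...) {
  cat(sprintf("<lobule_set> %d lobules, %.3g um/px\n", nrow(x$features),
              x$pixel_size_um))
  invisible(x)
}

#' Apply pathologist review labels
#'
#' Detected lobules labelled `FP` are excluded from downstream evaluation;
#' missed lobules supplied as `FN` outlines are added.  With an empty label
#' table all detections are retained as `unreviewed`.  Downstream positivity
#' evaluation thus covers only correctly detected or missed-and-added
#' lobules once a review is applied.
#'
#' @param lobules a `lobule_set`.
#' @param labels data.frame with columns `lobule_id` and `label`
#'   (`"TP"`/`"FP"`); may be empty.
#' @param fn_masks optional list of logical working-grid masks for
#'   false-negative lobules to add.
#' @return A `lobule_set` with review labels applied, FPs removed and FNs
#'   appended (labelled `"FN-added"`).
#' @export
apply_review <- function(lobules, labels = NULL, fn_masks = NULL) {
  stopifnot(inherits(lobules, "lobule_set"))
  feats <- lobules$features
  masks <- lobules$masks
  if (!is.null(labels) && nrow(labels)) {
    bad <- setdiff(labels$lobule_id, feats$lobule_id)
    if (length(bad)) {
      stop("unknown lobule ids in review table: ",
           paste(bad, collapse = ", "))
    }
    feats$review_label[match(labels$lobule_id, feats$lobule_id)] <-
      labels$label
    drop <- feats$review_label == "FP"
    feats <- feats[!drop, , drop = FALSE]
    masks <- masks[!drop]
  }
  if (!is.null(fn_masks)) {
    for (m in fn_masks) {
      idx <- which(m, arr.ind = TRUE)
      new_id <- if (nrow(feats)) max(lobules$features$lobule_id,
                                     feats$lobule_id) + 1L else 1L
      feats <- rbind(feats, data.frame(
        lobule_id = new_id,
        centroid_row = mean(idx[, 1]) - 1,
        centroid_col = mean(idx[, 2]) - 1,
        area_px = sum(m),
        area_mm2 = area_px_to_mm2(sum(m), lobules$pixel_size_um),
        mean_stddevn = NA_real_, roundness = NA_real_,
        diff_of_means = NA_real_, border_contrast = NA_real_,
        review_label = "FN-added", stringsAsFactors = FALSE))
      masks <- c(masks, list(m))
    }
  }
  lab <- matrix(0L, nrow(lobules$labels), ncol(lobules$labels))
  for (i in seq_along(masks)) lab[masks[[i]]] <- feats$lobule_id[i]
  structure(list(labels = lab, features = feats, masks = masks,
                 pixel_size_um = lobules$pixel_size_um),
            class = "lobule_set")
}
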