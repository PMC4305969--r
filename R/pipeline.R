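#' Pipeline configuration
#'
#' All tunable parameters of the workflow in one serialisable list, each
#' defaulting to the printed value of the original rule set: 10% working
#' scale, scale parameters 100 down to 20, channel weights (1,1,1,2),
#' the lobule criteria, seed tolerance 0.1, growth delta 2, 20% border
#' fraction, stain threshold 0.2, 30 degree dent angle, 30 px^2 minimum
#' nuclear area and the 0.5/2 mm distance bins.
#'
#' @param downsample_fraction working-resolution scale.
#' @param scales segmentation scale parameters, descending.
#' @param weights channel weights (R, G, B, texture).
#' @param shape_weight,compactness shape-heterogeneity term of the merge
#'   cost (see [multires_hierarchy()]).
#' @param criteria a [lobule_criteria()].
#' @param seed_tolerance tumor seed band around the median texture.
#' @param seed_min_area_px minimum segment area entering the seeding median.
#' @param growth_delta maximum texture deviation during tumor accretion.
#' @param border_fraction minimum shared-border fraction for accretion.
#' @param stain_threshold nuclear-region density threshold.
#' @param dent_angle_deg significant-dent angle.
#' @param min_nuclear_area_px minimum nucleus area at full resolution.
#' @param distance_bins_mm category cut points (adjacent/intermediate and
#'   intermediate/distant).
#' @param stain stain reference, see [stain_reference()].
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(downsample_fraction = 0.1,
                            scales = c(100, 80, 60, 40, 20),
                            weights = c(1, 1, 1, 2),
                            shape_weight = 1,
                            compactness = 0.5,
                            criteria = lobule_criteria(),
                            seed_tolerance = 0.1,
                            seed_min_area_px = 50L,
                            growth_delta = 2,
                            border_fraction = 0.2,
                            stain_threshold = 0.2,
                            dent_angle_deg = 30,
                            min_nuclear_area_px = 30L,
                            distance_bins_mm = c(0.5, 2),
                            stain = stain_reference()) {
  stopifnot(downsample_fraction > 0, downsample_fraction <= 1,
            all(diff(scales) < 0), length(weights) == 4L,
            inherits(criteria, "lobule_criteria"),
            seed_tolerance > 0, growth_delta > 0,
            border_fraction >= 0, border_fraction <= 1,
            stain_threshold > 0, dent_angle_deg > 0,
            min_nuclear_area_px >= 1, length(distance_bins_mm) == 2L,
            inherits(stain, "stain_reference"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  plain <- jsonlite::read_json(path, simplifyVector = TRUE)
  crit <- do.call(lobule_criteria, as.list(plain$criteria))
  stain <- stain_reference(i0 = plain$stain$i0, hema = plain$stain$hema,
                           dab = plain$stain$dab)
  args <- plain[setdiff(names(plain), c("criteria", "stain"))]
  args$criteria <- crit
  args$stain <- stain
  do.call(pipeline_config, args)
}

# --- slide sources ----------------------------------------------------------
# A pipeline input is either a synthetic_slide (lazy rendering), an
# in-memory full-resolution rgb_raster, or a path to a TIFF/PNM file.

slide_source <- function(input, pixel_size_um = NULL) {
  if (inherits(input, "synthetic_slide")) {
    return(list(kind = "synthetic", slide = input,
                dims = input$config$full_dims,
                pixel_size_um = input$config$pixel_size_um))
  }
  if (is.character(input)) {
    input <- read_image(input, pixel_size_um)
  }
  if (inherits(input, "rgb_raster")) {
    return(list(kind = "raster", image = input,
                dims = dim(input$pixels)[1:2],
                pixel_size_um = input$pixel_size_um))
  }
  stop("unsupported pipeline input")
}

source_working_view <- function(src, fraction) {
  if (src$kind == "synthetic") {
    render_working_view(src$slide)$image
  } else {
    downsample(src$image, fraction)
  }
}

source_tile <- function(src, r0, r1, c0, c1) {
  if (src$kind == "synthetic") {
    render_tile(src$slide, r0, r1, c0, c1)
  } else {
    rgb_raster(src$image$pixels[r0:r1, c0:c1, , drop = FALSE],
               src$pixel_size_um)
  }
}

#' Run the full analysis pipeline
#'
#' Downsamples the slide to working resolution, separates tissue from
#' background, builds the texture-weighted segmentation hierarchy, detects
#' lobules and the coherent tumor mass, quantifies DAB-positive vs
#' hematoxylin-negative nuclei per lobule at full resolution, and relates
#' per-lobule positivity to the distance from the tumor border.
#'
#' @param input a `synthetic_slide`, a full-resolution [rgb_raster], or a
#'   path to a TIFF/PNM image.
#' @param config a [pipeline_config()].
#' @param review optional data.frame of review labels
#'   (`lobule_id`, `label` with `"TP"`/`"FP"`); see [apply_review()].
#' @param fn_masks optional list of working-grid masks for missed lobules.
#' @param outdir optional output directory for CSV/TIFF/JSON artifacts.
#' @param pixel_size_um pixel size when `input` is a file without
#'   resolution tags.
#' @param verbose print stage progress.
#' @return A `pipeline_result`: lobule set, tumor region, per-lobule
#'   measurement table, case summary, regression fit (when defined), and a
#'   run report with stage timings, counts, and warnings.
#' @export
run_pipeline <- function(input, config = pipeline_config(), review = NULL,
                         fn_masks = NULL, outdir = NULL,
                         pixel_size_um = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(timings = c(), counts = c(), warnings = character(0))
  say <- function(...) if (verbose) message(sprintf(...))
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    report$timings[stage] <<- as.numeric(Sys.time() - t0, units = "secs")
    out
  }

  src <- slide_source(input, pixel_size_um)
  say("working view (%.0f%% of %d x %d px)...",
      config$downsample_fraction * 100, src$dims[1], src$dims[2])
  working <- clock("preprocess", {
    wv <- source_working_view(src, config$downsample_fraction)
    tex <- build_texture_layer(wv)
    tm <- tissue_mask_from_image(wv)
    list(image = wv, texture = tex, tissue = tm)
  })
  report$counts["tissue_px"] <- sum(working$tissue$mask)
  if (!any(working$tissue$mask)) {
    report$status <- "no tissue detected"
    return(structure(list(report = report), class = "pipeline_result"))
  }

  say("multiresolution segmentation...")
  hier <- clock("segmentation",
                multires_hierarchy(working$image, working$texture,
                                   working$tissue,
                                   scales = config$scales,
                                   weights = config$weights,
                                   shape_weight = config$shape_weight,
                                   compactness = config$compactness))
  for (lv in hier$levels) {
    report$counts[sprintf("segments_scale_%g", lv$scale)] <-
      nrow(lv$features)
  }

  say("lobule classification...")
  lobules <- clock("lobules", {
    init <- lapply(0:3, function(l) initial_classify(hier, l,
                                                     config$criteria))
    report$counts["initial_candidates"] <- length(unlist(init))
    refine_lobules(hier, init, config$criteria)
  })
  report$counts["lobules_detected"] <- nrow(lobules$features)

  if (!is.null(review) || !is.null(fn_masks)) {
    lobules <- apply_review(lobules, review, fn_masks)
    report$counts["lobules_evaluated"] <- nrow(lobules$features)
  }

  say("tumor detection...")
  tumor <- clock("tumor", tryCatch({
    detect_tumor(hier, lobules$labels,
                 seed_tolerance = config$seed_tolerance,
                 seed_min_area_px = config$seed_min_area_px,
                 max_delta = config$growth_delta,
                 min_border_fraction = config$border_fraction)
  }, error = function(e) {
    report$warnings <<- c(report$warnings,
                          paste("tumor detection failed:", e$message))
    NULL
  }))
  if (!is.null(tumor)) {
    report$counts["tumor_px"] <- sum(tumor$mask)
    report$counts["tumor_components"] <-
      max(label_components(tumor$mask, 4L))
  }

  say("per-lobule nuclear positivity (%d lobules)...",
      nrow(lobules$features))
  meas <- clock("positivity",
                measure_lobules(src, lobules, tumor, config))
  report$counts["nuclei_total"] <- sum(meas$n_pos + meas$n_neg)

  summary <- summarize_case(meas)
  fit <- tryCatch(fit_regression(meas), error = function(e) NULL)
  report$status <- "ok"

  result <- structure(list(lobules = lobules, tumor = tumor,
                           measurements = meas, summary = summary,
                           regression = fit, report = report,
                           working = working, hierarchy = hier),
                      class = "pipeline_result")
  if (!is.null(outdir)) write_artifacts(result, outdir)
  result
}

# full-resolution positivity for every lobule in the set
measure_lobules <- function(src, lobules, tumor, config) {
  frac <- config$downsample_fraction
  dims_full <- src$dims
  rows_w <- nn_index(dims_full[1], frac)
  cols_w <- nn_index(dims_full[2], frac)
  rows <- lapply(seq_len(nrow(lobules$features)), function(k) {
    f <- lobules$features[k, ]
    m <- lobules$masks[[k]]
    idx <- which(m, arr.ind = TRUE)
    pad <- round(1 / frac)
    r0 <- max(1L, rows_w[min(idx[, 1])] - pad)
    r1 <- min(dims_full[1], rows_w[max(idx[, 1])] + pad)
    c0 <- max(1L, cols_w[min(idx[, 2])] - pad)
    c1 <- min(dims_full[2], cols_w[max(idx[, 2])] + pad)
    tile <- source_tile(src, r0, r1, c0, c1)
    # nearest-working-pixel upsampling of the lobule mask onto the tile grid
    wi <- pmin(pmax(findInterval(r0:r1, rows_w - round(1 / frac) / 2), 1L),
               length(rows_w))
    wj <- pmin(pmax(findInterval(c0:c1, cols_w - round(1 / frac) / 2), 1L),
               length(cols_w))
    roi <- m[wi, wj]
    pos <- lobule_positivity(tile, roi, config$stain,
                             stain_threshold = config$stain_threshold,
                             min_area_px = config$min_nuclear_area_px,
                             dent_angle_deg = config$dent_angle_deg)
    d <- if (is.null(tumor)) NA_real_ else {
      lobule_distance(f$centroid_row, f$centroid_col, tumor)
    }
    data.frame(lobule_id = f$lobule_id,
               distance_mm = d,
               category = if (is.na(d)) NA_character_ else
                 as.character(categorize_distance(d,
                                                  config$distance_bins_mm)),
               n_pos = pos$n_pos, n_neg = pos$n_neg, ratio = pos$ratio,
               area_mm2 = f$area_mm2,
               review_label = f$review_label,
               inside_tumor = if (is.null(tumor)) NA else
                 tumor$mask[round(f$centroid_row) + 1L,
                            round(f$centroid_col) + 1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$report$status)) cat("  status:", x$report$status, "\n")
  if (!is.null(x$lobules)) {
    cat(sprintf("  lobules: %d\n", nrow(x$lobules$features)))
  }
  if (!is.null(x$tumor)) cat(sprintf("  tumor px: %d\n", sum(x$tumor$mask)))
  if (!is.null(x$summary)) print(x$summary)
  if (!is.null(x$regression)) {
    cat(sprintf("  regression: %.2f %%/mm (intercept %.2f%%)\n",
                x$regression$slope, x$regression$intercept))
  }
  invisible(x)
}

write_artifacts <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$lobules$features,
                   file.path(outdir, "lobules.csv"), row.names = FALSE)
  utils::write.csv(result$measurements,
                   file.path(outdir, "lobule_measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(result$summary, file.path(outdir, "case_summary.csv"),
                   row.names = FALSE)
  if (!is.null(result$regression)) {
    jsonlite::write_json(result$regression,
                         file.path(outdir, "regression.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_tiff(result$lobules$labels, file.path(outdir, "lobule_labels.tif"),
             pixel_size_um = result$lobules$pixel_size_um)
  if (!is.null(result$tumor)) {
    write_tiff(result$tumor$mask * 255L, file.path(outdir, "tumor_mask.tif"),
               pixel_size_um = result$tumor$pixel_size_um)
  }
  write_tiff(raster_layer(result$working$texture$values,
                          result$working$texture$pixel_size_um),
             file.path(outdir, "texture_layer.tif"))
  rep <- result$report
  jsonlite::write_json(list(status = rep$status,
                            timings_s = as.list(round(rep$timings, 2)),
                            counts = as.list(rep$counts),
                            warnings = rep$warnings),
                       file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Detection-quality summary from review labels
#'
#' @param lobules a reviewed `lobule_set` (labels applied before FP removal
#'   are also accepted as a plain data.frame with a `review_label` column).
#' @return List `n_tp`, `n_fp`, `n_fn`, `tp_fraction` where the fraction is
#'   `n_tp / (n_tp + n_fp)`.
#' @export
detection_quality <- function(lobules) {
  labs <- if (inherits(lobules, "lobule_set")) {
    lobules$features$review_label
  } else if (!is.null(lobules$review_label)) {
    lobules$review_label
  } else {
    lobules$label
  }
  labs[labs == "FN"] <- "FN-added"
  labs <- labs[labs != "unreviewed"]
  if (!length(labs)) stop("no reviewed lobules")
  n_tp <- sum(labs == "TP")
  n_fp <- sum(labs == "FP")
  n_fn <- sum(labs == "FN-added")
  list(n_tp = n_tp, n_fp = n_fp, n_fn = n_fn,
       tp_fraction = if (n_tp + n_fp == 0) NA_real_ else
         n_tp / (n_tp + n_fp))
}
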