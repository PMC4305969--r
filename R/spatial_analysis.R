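#' Distance from a lobule centre to the nearest tumor border
#'
#' Euclidean distance (in mm) from the lobule's area centroid to the nearest
#' tumor border pixel on the working grid.
#'
#' @param centroid_row,centroid_col lobule centroid, 0-based pixel-centre
#'   working coordinates.
#' @param tumor a `tumor_region` with a non-empty mask.
#' @param pixel_size_um working pixel size in micrometres.
#' @return Distance in mm (0 if the centroid lies on the border).
#' @export
lobule_distance <- function(centroid_row, centroid_col, tumor,
                            pixel_size_um = tumor$pixel_size_um) {
  stopifnot(inherits(tumor, "tumor_region"))
  if (!any(tumor$mask)) stop("empty tumor region: distance undefined")
  border <- which(tumor_border(tumor), arr.ind = TRUE)
  d_px <- sqrt(min((border[, 1] - 1 - centroid_row)^2 +
                   (border[, 2] - 1 - centroid_col)^2))
  d_px * pixel_size_um / 1000
}

#' Distance category of a lobule
#'
#' Adjacent `< 0.5 mm`, intermediate `0.5-2 mm` (both bounds included),
#' distant `> 2 mm`.  The printed interval notation overlaps at the
#' boundaries; both 0.5 and 2.0 resolve to intermediate so the categories
#' partition `[0, Inf)`.
#'
#' @param distance_mm non-negative distance in mm (vectorised).
#' @param bins_mm the two cut points (default 0.5 and 2 mm).
#' @return Factor with levels `adjacent`, `intermediate`, `distant`.
#' @export
categorize_distance <- function(distance_mm, bins_mm = c(0.5, 2)) {
  distance_mm <- as.numeric(distance_mm)
  if (any(distance_mm < 0, na.rm = TRUE)) {
    stop("distance must be non-negative")
  }
  f <- cut(distance_mm, breaks = c(-Inf, bins_mm[1], bins_mm[2], Inf),
           labels = c("adjacent", "intermediate", "distant"),
           right = FALSE)
  # cut(right = FALSE) puts the upper bound into "distant"; the printed
  # binning keeps the closed upper bound (2.0 mm) in "intermediate"
  f[!is.na(distance_mm) & distance_mm == bins_mm[2]] <- "intermediate"
  f
}

#' Per-case summary of positivity by distance category
#'
#' For each category, the unweighted arithmetic mean of per-lobule positive
#' percentages over lobules with a defined ratio, plus the lobule count --
#' the six-column row layout of the per-case summary tables.  Categories
#' with no lobules report `NA` for the mean.
#'
#' @param measurements data.frame with columns `distance_mm`, `n_pos`,
#'   `n_neg` and `ratio` (in `[0, 1]` or `NA`).
#' @return A `case_summary` data.frame with one row per category:
#'   `category`, `mean_positivity_pct`, `n_lobules`.
#' @export
summarize_case <- function(measurements) {
  cats <- c("adjacent", "intermediate", "distant")
  cat_f <- categorize_distance(measurements$distance_mm)
  rows <- lapply(cats, function(cc) {
    sel <- cat_f == cc
    r <- measurements$ratio[sel]
    r <- r[!is.na(r)]
    data.frame(category = cc,
               mean_positivity_pct = if (length(r)) mean(r) * 100 else
                 NA_real_,
               n_lobules = sum(sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("case_summary", "data.frame")
  out
}

#' @export
print.case_summary <- function(x, ...) {
  fmt <- function(m) ifelse(is.na(m), "-", sprintf("%.1f%%", m))
  cat(sprintf("%-13s %10s %8s\n", "category", "mean pos.", "lobules"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-13s %10s %8d\n", x$category[i],
                fmt(x$mean_positivity_pct[i]), x$n_lobules[i]))
  }
  invisible(x)
}

#' Regression of positivity on distance to tumor
#'
#' Ordinary least squares of positive percentage on distance (mm) across
#' lobules, the per-case trend line of the scatter display.
#'
#' @param measurements data.frame with `distance_mm` and `ratio`.
#' @return List `slope` (percentage points per mm) and `intercept` (%).
#' @export
fit_regression <- function(measurements) {
  ok <- !is.na(measurements$ratio)
  d <- measurements$distance_mm[ok]
  y <- measurements$ratio[ok] * 100
  if (length(unique(d)) < 2L) {
    stop("need at least 2 distinct distances with defined ratios")
  }
  fit <- stats::lm.fit(cbind(1, d), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]))
}
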