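stub_tumor <- function(mask) {
  structure(list(mask = mask, segment_ids = integer(0),
                 pixel_size_um = 5.6), class = "tumor_region")
}

test_that("lobule distance is centroid-to-nearest-border in mm", {
  mask <- matrix(FALSE, 50, 200)
  mask[, 1:40] <- TRUE
  tum <- stub_tumor(mask)
  # centroid on the border -> 0  (border column is 40, 0-based col 39)
  expect_equal(lobule_distance(10, 39, tum), 0)
  # 100 working px from the border at 5.6 um/px -> 0.56 mm
  expect_equal(lobule_distance(10, 139, tum), 100 * 5.6 / 1000)
  # centroid inside the mass still gets a non-negative distance
  expect_gte(lobule_distance(25, 5, tum), 0)
  expect_error(lobule_distance(1, 1, stub_tumor(matrix(FALSE, 5, 5))),
               "empty tumor")
})

test_that("distance categories use the printed bins with closed 2.0", {
  expect_equal(as.character(categorize_distance(0.3)), "adjacent")
  expect_equal(as.character(categorize_distance(0.5)), "intermediate")
  expect_equal(as.character(categorize_distance(2.0)), "intermediate")
  expect_equal(as.character(categorize_distance(2.5)), "distant")
  expect_error(categorize_distance(-1), "non-negative")
  # categories partition [0, Inf): every distance lands in exactly one
  d <- seq(0, 5, by = 0.01)
  expect_false(any(is.na(categorize_distance(d))))
})

test_that("pixel areas convert to the printed mm^2 bounds", {
  expect_equal(signif(area_px_to_mm2(2000, 5.6), 3), 0.0627)
  expect_equal(signif(area_px_to_mm2(14000, 5.6), 3), 0.439)
  expect_equal(area_px_to_mm2(0, 5.6), 0)
})

test_that("case summaries mirror the six-column table layout", {
  meas <- data.frame(
    distance_mm = c(0.2, 0.3, 1.0, 3.0),
    ratio = c(0.10, 0.20, NA, 0.07))
  s <- summarize_case(meas)
  expect_equal(s$category, c("adjacent", "intermediate", "distant"))
  expect_equal(s$mean_positivity_pct[1], 15)  # mean of 10% and 20%
  expect_equal(s$n_lobules, c(2L, 1L, 1L))
  expect_equal(s$mean_positivity_pct[3], 7)   # single lobule at 7%

  none <- summarize_case(data.frame(distance_mm = c(1, 3),
                                    ratio = c(0.1, 0.2)))
  expect_true(is.na(none$mean_positivity_pct[1]))  # empty category -> "-"
  expect_equal(none$n_lobules[1], 0L)
})

test_that("the regression line is ordinary least squares of % on mm", {
  fit <- fit_regression(data.frame(distance_mm = c(1, 2),
                                   ratio = c(0.10, 0.20)))
  expect_equal(fit$slope, 10)
  expect_equal(fit$intercept, 0)
  flat <- fit_regression(data.frame(distance_mm = c(1, 2, 3),
                                    ratio = c(0.2, 0.2, 0.2)))
  expect_equal(flat$slope, 0)
  expect_error(fit_regression(data.frame(distance_mm = c(1, 1),
                                         ratio = c(0.1, 0.2))),
               "distinct")
})
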