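make_simple_inputs <- function(arr, pixel_size = 5.6) {
  img <- rgb_raster(arr, pixel_size)
  tex <- raster_layer(matrix(0, dim(arr)[1], dim(arr)[2]), pixel_size)
  msk <- tissue_mask(matrix(TRUE, dim(arr)[1], dim(arr)[2]), pixel_size)
  list(img = img, tex = tex, msk = msk)
}

test_that("constant tissue yields one segment at every level", {
  inp <- make_simple_inputs(array(100, c(12, 12, 3)))
  # spectral-only: every merge has zero cost, so one segment survives at
  # every cut (the shape term would deliberately resist huge uniform blobs)
  h <- multires_hierarchy(inp$img, inp$tex, inp$msk,
                          scales = c(30, 20, 10, 5, 2), shape_weight = 0)
  for (lv in h$levels) expect_equal(nrow(lv$features), 1L)
})

test_that("two contrasting half-planes stay two segments", {
  arr <- array(0, c(16, 16, 3)); arr[, 9:16, ] <- 200
  inp <- make_simple_inputs(arr)
  h <- multires_hierarchy(inp$img, inp$tex, inp$msk,
                          scales = c(30, 20, 10, 5, 2),
                          weights = c(1, 0, 0, 0), shape_weight = 0)
  # cost of the single remaining cross-boundary merge in closed form:
  # 256 px, half 0 / half 200 -> sd 100 -> cost = 256*100 = 25600 > 30^2
  for (lv in h$levels) expect_equal(nrow(lv$features), 2L)
  expect_gt(max(h$merges$cost), 30^2)
})

test_that("levels partition the mask, nest strictly, and counts are
           monotone", {
  fix <- small_hierarchy()
  h <- fix$hier
  counts <- vapply(h$levels, function(lv) nrow(lv$features), numeric(1))
  expect_true(all(diff(counts) >= 0))   # finer level never has fewer
  for (lv in h$levels) {
    expect_true(all((lv$labels > 0) == h$mask))  # exact partition of tissue
  }
  for (i in 2:5) {
    fine <- h$levels[[i]]; coarse <- h$levels[[i - 1]]
    # each fine segment lies inside exactly one coarse segment
    inside <- fine$labels > 0
    pairs <- unique(cbind(fine$labels[inside], coarse$labels[inside]))
    expect_equal(nrow(pairs), nrow(fine$features))
    # and the parent link agrees
    expect_equal(unname(pairs[match(fine$features$id, pairs[, 1]), 2]),
                 fine$features$parent)
  }
})

test_that("merge costs are monotone and match the exhaustive oracle", {
  set.seed(11)
  arr <- array(runif(6 * 6 * 3, 0, 255), c(6, 6, 3))
  tex <- matrix(runif(36, 0, 40), 6, 6)
  mask <- matrix(TRUE, 6, 6)
  channels <- array(0, c(6, 6, 4))
  channels[, , 1:3] <- arr; channels[, , 4] <- tex
  w <- c(1, 1, 1, 2)
  got <- lobulaR:::cpp_mrseg_merges(channels, w, mask, 0, 0.5)
  # (the executed cost sequence is only near-monotone: the area-times-SD
  # criterion lacks Ward's reducibility, so occasional inversions occur;
  # nesting relies on prefix cuts, not monotonicity)
  oracle <- oracle_merge_sequence(channels, w, mask)
  expect_equal(length(oracle), length(got$cost))
  expect_equal(vapply(oracle, `[[`, 0, "cost"), pmax(got$cost, 0),
               tolerance = 1e-8)
  expect_equal(vapply(oracle, `[[`, 0L, "a"), got$a)
  expect_equal(vapply(oracle, `[[`, 0L, "b"), got$b)
})

test_that("incremental segment features equal recomputation from pixels", {
  fix <- small_hierarchy()
  lv <- fix$hier$levels[[2]]
  tex <- fix$hier$channels[, , 4]
  raw <- fix$hier$stddevn
  ids <- sample(lv$features$id, 5)
  for (id in ids) {
    m <- lv$labels == id
    row <- lv$features[lv$features$id == id, ]
    expect_equal(row$area_px, sum(m))
    expect_equal(row$mean_texture, mean(tex[m]), tolerance = 1e-9)
    expect_equal(row$mean_stddevn, mean(raw[m]), tolerance = 1e-9)
  }
})

test_that("roundness scores analytic and rasterised shapes as defined", {
  # a perfect disk: enclosing, inscribed, and equivalent radii coincide
  expect_equal(roundness_from_radii(1, 1, pi), 0)
  expect_equal(roundness_from_radii(2.5, 2.5, pi * 2.5^2), 0)
  # 2:1 rectangle (2a x a) in closed form:
  a <- 1
  expect_equal(roundness_from_radii(sqrt(5) / 2 * a, a / 2, 2 * a^2),
               (sqrt(5) / 2 - 1 / 2) / sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(roundness_from_radii(sqrt(5) / 2, 1 / 2, 2), 0.7746,
               tolerance = 1e-4)
  # rasterised disk scores near 0
  expect_lt(mask_roundness(disk_mask(81, 30)), 0.06)
  # rasterised 2:1 rectangle close to the closed form
  rect <- matrix(FALSE, 60, 110); rect[11:40, 11:70] <- TRUE
  expect_equal(mask_roundness(rect), 0.7746, tolerance = 0.05)
  # a 1-px line of length 50 is far outside the lobule range
  line <- matrix(FALSE, 5, 60); line[3, 6:55] <- TRUE
  expect_gt(mask_roundness(line), 1.3)
})

test_that("border contrast follows the strip definition", {
  # two half-planes with distinct texture values: strips are the two
  # columns flanking the boundary
  lab <- matrix(1L, 10, 10); lab[, 6:10] <- 2L
  layer <- matrix(10, 10, 10); layer[, 1:5] <- 30
  level <- list(labels = lab)
  expect_equal(border_contrast(level, 1L, 2L, layer), 0.5)   # (30-10)/40
  expect_equal(border_contrast(level, 2L, 1L, layer), -0.5)  # sign flips
  layer2 <- matrix(5, 10, 10)
  expect_equal(border_contrast(level, 1L, 2L, layer2), 0)    # equal strips
  far <- matrix(0L, 5, 5); far[1, 1] <- 1L; far[5, 5] <- 2L
  expect_error(border_contrast(list(labels = far), 1L, 2L,
                               matrix(0, 5, 5)), "not adjacent")
})

test_that("diff of means weights neighbours by shared border", {
  lab <- matrix(1L, 12, 12)
  lab[, 9:12] <- 2L      # long border with segment 2
  lab[1, 1] <- 3L        # short border with segment 3
  tex <- matrix(0, 12, 12)
  tex[lab == 1L] <- 25; tex[lab == 2L] <- 18; tex[lab == 3L] <- 18
  level <- lobulaR:::build_level(lab, array(0, c(12, 12, 4)), tex, 100, 0, 5.6,
                                 with_roundness = FALSE)
  expect_equal(diff_of_means(level, 1L), 7)       # 25 - 18, single value
  # all neighbours equal to the segment -> 0
  tex2 <- matrix(25, 12, 12)
  level2 <- lobulaR:::build_level(lab, array(0, c(12, 12, 4)), tex2, 100, 0,
                                  5.6, with_roundness = FALSE)
  expect_equal(diff_of_means(level2, 1L), 0)
})
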