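test_that("downsample is nearest-neighbour with the documented geometry", {
  # 0.56 um/px at 10% -> the 5.6 um/px working pixel size
  img <- rgb_raster(array(100, c(100, 100, 3)), 0.56)
  d <- downsample(img, 0.1)
  expect_equal(d$pixel_size_um, 5.6)
  expect_equal(dim(d$pixels)[1:2], c(10L, 10L))
  expect_true(all(d$pixels == 100))   # constants survive NN resampling

  # 20x20 checkerboard of 2x2 blocks at 50% -> 10x10 of 1x1 cells
  blocks <- outer(0:19, 0:19, function(r, c) {
    ((r %/% 2) + (c %/% 2)) %% 2
  }) * 255
  cb <- rgb_raster(array(rep(blocks, 3), c(20, 20, 3)), 1)
  half <- downsample(cb, 0.5)
  cells <- half$pixels[, , 1] / 255
  expect_equal(cells, outer(0:9, 0:9, function(r, c) (r + c) %% 2))

  expect_error(downsample(img, 0.001), "zero-sized")
  expect_error(downsample(img, 1.5), "scale_fraction")
})

test_that("stddev_to_neighbors matches its definition", {
  expect_equal(stddev_to_neighbors(matrix(7, 5, 5)),
               matrix(0, 5, 5))                 # constant -> all zero
  z <- matrix(0, 9, 9); z[5, 5] <- 3
  expect_equal(stddev_to_neighbors(z)[5, 5], 3) # spike of v -> v
  cb <- outer(1:11, 1:11, function(r, c) (r + c) %% 2)
  s <- stddev_to_neighbors(cb)
  expect_equal(s[6, 6], sqrt(4 / 8))            # checkerboard interior
})

test_that("stddev_to_neighbors equals the brute-force oracle and is
           translation-equivariant", {
  set.seed(42)
  m <- matrix(runif(12 * 15, 0, 255), 12, 15)
  expect_equal(stddev_to_neighbors(m), oracle_stddevn(m), tolerance = 1e-12)
  # shifting the input shifts the output (away from borders)
  shifted <- m[2:12, ]
  expect_equal(stddev_to_neighbors(shifted)[2:10, 2:14],
               stddev_to_neighbors(m)[3:11, 2:14])
})

test_that("texture layer composes the three operators and ignores red/green", {
  const <- rgb_raster(array(120, c(32, 32, 3)), 5.6)
  expect_true(all(build_texture_layer(const)$values == 0))

  rg_only <- array(120, c(32, 32, 3))
  set.seed(1)
  rg_only[, , 1] <- runif(32 * 32, 0, 255)
  rg_only[, , 2] <- runif(32 * 32, 0, 255)
  expect_true(all(build_texture_layer(rgb_raster(rg_only, 5.6))$values == 0))

  # brute-force composition on a checkerboard blue channel
  arr <- array(120, c(32, 32, 3))
  arr[, , 3] <- outer(1:32, 1:32, function(r, c) ((r + c) %% 2) * 200)
  got <- build_texture_layer(rgb_raster(arr, 5.6))$values
  expected <- gaussian_smooth(median3(oracle_stddevn(arr[, , 3])), 11L)
  expect_equal(got, pmax(expected, 0), tolerance = 1e-10)
  expect_true(all(got >= 0))
})

test_that("tissue mask separates a gray disk from white glass", {
  arr <- array(250, c(90, 90, 3))
  d <- disk_mask(90, 28)
  for (k in 1:3) arr[, , k][d] <- 120
  tm <- tissue_mask_from_image(rgb_raster(arr, 5.6), small_area_px = 5L)
  expect_gt(sum(tm$mask & d) / sum(tm$mask | d), 0.8)
  # partition: every pixel is exactly one of tissue / background
  expect_true(all(tm$mask | !tm$mask))
})

test_that("tissue mask degenerates to all-background with a warning", {
  arr <- array(250, c(30, 30, 3))
  expect_warning(tm <- tissue_mask_from_image(rgb_raster(arr, 5.6)),
                 "background")
  expect_false(any(tm$mask))
})

test_that("small enclosed areas are reclassified", {
  arr <- array(120, c(60, 60, 3))          # gray tissue field
  arr[28:32, 28:34, ] <- 250               # small white hole
  tm <- tissue_mask_from_image(rgb_raster(arr, 5.6), small_area_px = 60L)
  expect_true(all(tm$mask[29:31, 29:33]))  # hole reclassified as tissue
  # reclassification never touches components above the limit
  arr2 <- array(120, c(80, 80, 3))
  big_hole <- disk_mask(80, 12, c(40, 40))
  for (k in 1:3) arr2[, , k][big_hole] <- 250
  tm2 <- tissue_mask_from_image(rgb_raster(arr2, 5.6), small_area_px = 25L)
  # the hole core survives as background (its smoothed rim may attach to
  # tissue, but an above-limit component is never flipped)
  expect_false(any(tm2$mask[disk_mask(80, 4, c(40, 40))]))
})
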