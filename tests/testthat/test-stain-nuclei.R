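test_that("HSD deconvolution inverts the Beer-Lambert forward model", {
  ref <- stain_reference()
  # pure background -> zero density in both channels
  bg <- tile_from_pixel(ref$i0)
  lay <- hsd_deconvolve(bg, ref)
  expect_equal(max(abs(lay$dab$values)), 0)
  expect_equal(max(abs(lay$hema$values)), 0)

  # pure DAB at several concentrations: dab recovers c, hema stays 0
  for (conc in c(0.1, 0.4, 0.9)) {
    tile <- tile_from_pixel(forward_pixel(0, conc, ref))
    lay <- hsd_deconvolve(tile, ref)
    expect_equal(lay$dab$values[1, 1], conc, tolerance = 1e-6)
    expect_equal(lay$hema$values[1, 1], 0, tolerance = 1e-6)
  }
  # 50/50 mix: both positive, ratio matches the simulated concentrations
  tile <- tile_from_pixel(forward_pixel(0.3, 0.3, ref))
  lay <- hsd_deconvolve(tile, ref)
  expect_equal(lay$dab$values[1, 1] / lay$hema$values[1, 1], 1,
               tolerance = 1e-6)
  expect_equal(lay$dab$values[1, 1] + lay$hema$values[1, 1], 0.6,
               tolerance = 1e-6)
  # asymmetric mix round-trips
  tile <- tile_from_pixel(forward_pixel(0.5, 0.2, ref))
  lay <- hsd_deconvolve(tile, ref)
  expect_equal(lay$hema$values[1, 1], 0.5, tolerance = 1e-6)
  expect_equal(lay$dab$values[1, 1], 0.2, tolerance = 1e-6)
})

test_that("zero-intensity pixels are clamped with a warning", {
  arr <- array(100, c(3, 3, 3)); arr[1, 1, ] <- 0
  expect_warning(lay <- hsd_deconvolve(rgb_raster(arr, 0.56)), "clamped")
  expect_true(all(is.finite(lay$dab$values)))
})

test_that("nuclear regions apply threshold and dominance, disjointly", {
  mk <- function(dab, hema) {
    list(dab = raster_layer(matrix(dab, 2, 2), 0.56),
         hema = raster_layer(matrix(hema, 2, 2), 0.56))
  }
  r <- nuclear_regions(mk(0.3, 0.1))
  expect_true(all(r$mask_dab) && !any(r$mask_hema))
  r <- nuclear_regions(mk(0.15, 0.15))
  expect_false(any(r$mask_dab) || any(r$mask_hema))
  r <- nuclear_regions(mk(0.25, 0.30))
  expect_true(all(r$mask_hema) && !any(r$mask_dab))
  # disjointness holds for arbitrary layers
  set.seed(5)
  lay <- list(dab = raster_layer(matrix(runif(400, 0, 1), 20), 0.56),
              hema = raster_layer(matrix(runif(400, 0, 1), 20), 0.56))
  r <- nuclear_regions(lay)
  expect_false(any(r$mask_dab & r$mask_hema))
})

test_that("watershed splits overlapping blobs along the ridge", {
  n <- 40
  d1 <- outer(1:n, 1:n, function(r, c) sqrt((r - 20)^2 + (c - 14)^2))
  d2 <- outer(1:n, 1:n, function(r, c) sqrt((r - 20)^2 + (c - 26)^2))
  dens <- exp(-d1^2 / 50) + exp(-d2^2 / 50)
  mask <- dens > 0.2
  lab <- split_nuclei(mask, dens, min_area_px = 10L)
  expect_equal(max(lab), 2L)
  # the ridge is the perpendicular bisector: basin membership by side
  got_left <- lab[20, 10]; got_right <- lab[20, 30]
  expect_true(got_left != got_right)
  side <- lab[mask & col(lab) <= 18]
  expect_true(all(side == got_left))
  side_r <- lab[mask & col(lab) >= 22]
  expect_true(all(side_r == got_right))

  # an isolated single-peak disk stays one nucleus
  dd <- outer(1:21, 1:21, function(r, c) (r - 11)^2 + (c - 11)^2)
  lab1 <- split_nuclei(disk_mask(21, 7), exp(-dd / 30), 10L)
  expect_equal(max(lab1), 1L)

  # speckles below the minimum area are removed
  spk <- matrix(FALSE, 15, 15); spk[7:8, 7:8] <- TRUE
  expect_equal(max(split_nuclei(spk, matrix(1, 15, 15), 30L)), 0L)
})

test_that("dent cutting separates a figure-eight and spares convex shapes", {
  # convex disk: no concave vertex, returned uncut
  expect_length(dent_cut(disk_mask(25, 9), 30, 20L), 1L)

  # two overlapping disks: waist dents beyond 30 degrees, cut in two
  eight <- disk_mask(41, 10, c(21, 13)) | disk_mask(41, 10, c(21, 29))
  frags <- dent_cut(eight, 30, 20L)
  expect_length(frags, 2L)
  areas <- vapply(frags, sum, numeric(1))
  expect_true(all(areas > 200))

  # shallow dent below the angle threshold stays uncut: a disk with a
  # 1-px nick has tangent turning well under 30 degrees after 1-px
  # polygon simplification
  nick <- disk_mask(31, 12)
  nick[16, 28] <- FALSE
  expect_length(dent_cut(nick, 30, 20L), 1L)
})

test_that("border smoothing removes spurs and keeps labels disjoint", {
  d <- disk_mask(25, 8)
  lab <- matrix(0L, 25, 25); lab[d] <- 1L
  sm <- postprocess_nuclei(lab, min_area_px = 10L)
  expect_gt(sum(sm == 1L), 0.9 * sum(d))    # disk ~unchanged

  spur <- d; spur[13, 22] <- TRUE           # 1-px spur off the boundary
  lab2 <- matrix(0L, 25, 25); lab2[spur] <- 1L
  sm2 <- postprocess_nuclei(lab2, min_area_px = 10L)
  expect_false(sm2[13, 22] == 1L && sum(sm2 == 1L) == sum(spur))

  # object shrunk below the minimum area disappears
  tiny <- matrix(0L, 10, 10); tiny[5, 4:6] <- 1L
  expect_equal(max(postprocess_nuclei(tiny, min_area_px = 5L)), 0L)
})

test_that("lobule positivity recovers the rendered positive fraction", {
  sl <- small_slide()
  tr <- sl$truth$lobules
  # render the first planted lobule's tile and count
  lb <- sl$scene$lobules[[1]]
  pad <- 30
  r0 <- max(1, round(lb$center_full[1] - lb$radius_full - pad))
  r1 <- min(sl$config$full_dims[1], round(lb$center_full[1] + lb$radius_full + pad))
  c0 <- max(1, round(lb$center_full[2] - lb$radius_full - pad))
  c1 <- min(sl$config$full_dims[2], round(lb$center_full[2] + lb$radius_full + pad))
  tile <- render_tile(sl, r0, r1, c0, c1)
  roi <- outer(r0:r1, c0:c1, function(r, c) {
    (r - lb$center_full[1])^2 + (c - lb$center_full[2])^2 <=
      (lb$radius_full + 10)^2
  })
  pos <- lobule_positivity(tile, roi)
  truth_frac <- tr$positive_fraction[tr$lobule_id == lb$id]
  expect_lt(abs(pos$ratio - truth_frac), 0.05)
  expect_gt(pos$n_pos + pos$n_neg, 50)

  # zero nuclei -> NA ratio
  blank <- rgb_raster(array(245, c(30, 30, 3)), 0.56)
  p0 <- lobule_positivity(blank, matrix(TRUE, 30, 30))
  expect_true(is.na(p0$ratio))
  expect_equal(p0$n_pos + p0$n_neg, 0)
})
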