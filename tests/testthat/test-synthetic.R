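test_that("slides are deterministic for a fixed seed", {
  cfg <- small_synth_config(seed = 3L)
  a <- generate_slide(cfg)
  b <- generate_slide(cfg)
  expect_identical(a$truth$lobules, b$truth$lobules)
  ta <- render_grid(a, 101:140, 201:260)
  tb <- render_grid(b, 101:140, 201:260)
  expect_identical(ta, tb)
})

test_that("tile rendering is consistent with the working view", {
  sl <- small_slide()
  tr <- sl$truth
  wv <- render_working_view(sl)
  # the working view is the exact nearest-neighbour downsample: re-render a
  # block of sampled coordinates as a sub-grid and compare
  rows <- tr$rows_w[11:30]; cols <- tr$cols_w[11:40]
  sub <- render_grid(sl, rows, cols)
  expect_equal(sub, wv$image$pixels[11:30, 11:40, , drop = FALSE])
})

test_that("ground truth bookkeeping matches the configuration", {
  sl <- small_slide()
  cfg <- sl$config
  tr <- sl$truth$lobules
  expect_equal(nrow(tr), sum(cfg$n_lobules_per_band))
  # per-band positive fractions as configured (exact generator bookkeeping)
  for (band in names(cfg$n_lobules_per_band)) {
    n_b <- cfg$n_lobules_per_band[[band]]
    if (n_b == 0) next
    got <- tr$positive_fraction[tr$band == band]
    expect_equal(got, rep(cfg$band_positive_fraction[[band]], n_b),
                 tolerance = 0.01)
    expect_equal(tr$n_pos[tr$band == band],
                 round(cfg$band_positive_fraction[[band]] *
                         tr$n_nuclei[tr$band == band]))
  }
  # distances lie in the configured sampling bands
  for (i in seq_len(nrow(tr))) {
    rng <- cfg$band_distance_mm[[tr$band[i]]]
    expect_gte(tr$distance_mm[i], rng[1] - 0.05)
    expect_lte(tr$distance_mm[i], rng[2] + 0.05)
  }
  # counts are positive and areas inside the acceptance window
  expect_true(all(tr$n_nuclei > 0))
  expect_true(all(tr$area_w_px >= 2000 & tr$area_w_px <= 14000))
})

test_that("a zero-lobule configuration renders tumor and stroma only", {
  cfg <- small_synth_config(seed = 2L)
  cfg$n_lobules_per_band <- c(adjacent = 0L, intermediate = 0L,
                              distant = 0L)
  sl <- generate_slide(cfg)
  expect_equal(nrow(sl$truth$lobules), 0L)
  expect_false(any(sl$truth$lobule_labels_w > 0))
  expect_gt(sum(sl$truth$tumor_w), 0)
})

test_that("mask downsampling keeps structures connected", {
  sl <- small_slide()
  lab <- sl$truth$lobule_labels_w
  for (id in sort(unique(lab[lab > 0]))) {
    comp <- label_components(lab == id, 4L)
    expect_equal(max(comp), 1L)
  }
  expect_equal(max(label_components(sl$truth$tumor_w, 4L)), 1L)
})

test_that("working-resolution lobule texture sits in the printed range", {
  sl <- small_slide()
  wv <- render_working_view(sl)
  raw <- stddev_to_neighbors(wv$image$pixels[, , 3])
  lab <- sl$truth$lobule_labels_w
  for (id in sort(unique(lab[lab > 0]))) {
    m <- mean(raw[lab == id])
    expect_gt(m, 15); expect_lt(m, 36)
  }
  stroma <- wv$tissue & !wv$tumor & lab == 0
  expect_lt(mean(raw[stroma]), 10)
})

test_that("lobulitis measurably degrades the lobule texture signature", {
  plain <- small_slide()
  sick <- cached("lobulitis_slide", function() {
    generate_slide(small_synth_config(lobulitis = TRUE))
  })
  raw_p <- stddev_to_neighbors(render_working_view(plain)$image$pixels[, , 3])
  raw_s <- stddev_to_neighbors(render_working_view(sick)$image$pixels[, , 3])
  mean_in <- function(raw, sl) {
    lab <- sl$truth$lobule_labels_w
    mean(raw[lab > 0])
  }
  # the inflammatory infiltrate disrupts the regular ring texture: the
  # stddev-n signature moves up and out of its tight class
  expect_gt(mean_in(raw_s, sick), mean_in(raw_p, plain) + 3)
})
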