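test_that("the printed rule set gates candidates as specified", {
  crit <- lobule_criteria()
  base <- list(mean_stddevn = 25, area_px = 5000, roundness = 0.5,
               diff_of_means = 10, border_contrast = 0.6)
  expect_true(lobulaR:::passes_full_criteria(base, crit))
  # each printed bound rejects on its own
  cases <- list(
    list(mean_stddevn = 10),     # below 15-36
    list(mean_stddevn = 40),     # above 15-36
    list(area_px = 1000),        # below 2000 px^2
    list(area_px = 15000),       # above 14000 px^2
    list(roundness = 1.4),       # above 1.3
    list(diff_of_means = 4.9),   # below 5
    list(border_contrast = 0.39) # below 0.4
  )
  for (ch in cases) {
    f <- utils::modifyList(base, ch)
    expect_false(lobulaR:::passes_full_criteria(f, crit))
  }
  # reduced criteria drop minimum area and border contrast only
  red_ok <- utils::modifyList(base, list(area_px = 100,
                                         border_contrast = -1))
  expect_true(lobulaR:::passes_reduced_criteria(red_ok, crit))
  expect_false(lobulaR:::passes_reduced_criteria(
    utils::modifyList(red_ok, list(diff_of_means = 2)), crit))
})

test_that("initial classification + refinement find the planted lobules", {
  fix <- small_hierarchy()
  crit <- lobule_criteria()
  init <- lapply(0:3, function(l) initial_classify(fix$hier, l, crit))
  expect_gt(length(unlist(init)), 0)
  lob <- refine_lobules(fix$hier, init, crit)
  truth <- fix$slide$truth
  hits <- vapply(seq_len(nrow(truth$lobules)), function(i) {
    gl <- truth$lobule_labels_w == truth$lobules$lobule_id[i]
    if (!length(lob$masks)) return(0)
    max(vapply(lob$masks,
               function(m) sum(m & gl) / sum(m | gl), numeric(1)))
  }, numeric(1))
  expect_gte(sum(hits >= 0.3), 2)   # at least 2 of the 3 planted lobules
})

test_that("every accepted lobule re-passes the full criteria from its mask", {
  fix <- small_hierarchy()
  crit <- lobule_criteria()
  init <- lapply(0:3, function(l) initial_classify(fix$hier, l, crit))
  lob <- refine_lobules(fix$hier, init, crit)
  for (k in seq_along(lob$masks)) {
    f <- lobulaR:::mask_full_features(fix$hier, lob$masks[[k]], crit)
    expect_true(lobulaR:::passes_full_criteria(f, crit),
                label = sprintf("lobule %d re-passes", k))
  }
})

test_that("review labels gate the evaluated set", {
  fix <- small_hierarchy()
  crit <- lobule_criteria()
  init <- lapply(0:3, function(l) initial_classify(fix$hier, l, crit))
  lob <- refine_lobules(fix$hier, init, crit)
  skip_if(nrow(lob$features) < 2, "needs at least two detections")
  ids <- lob$features$lobule_id

  # empty review keeps everything unreviewed
  same <- apply_review(lob, NULL)
  expect_equal(nrow(same$features), nrow(lob$features))
  expect_true(all(same$features$review_label == "unreviewed"))

  # FP excluded, FN outline added
  labels <- data.frame(lobule_id = ids[1:2], label = c("TP", "FP"))
  fn <- matrix(FALSE, nrow(lob$labels), ncol(lob$labels))
  fn[10:20, 10:20] <- TRUE
  rev <- apply_review(lob, labels, fn_masks = list(fn))
  expect_equal(nrow(rev$features), nrow(lob$features) - 1L + 1L)
  expect_false(ids[2] %in% rev$features$lobule_id)
  expect_true(any(rev$features$review_label == "FN-added"))

  expect_error(apply_review(lob, data.frame(lobule_id = 999L, label = "TP")),
               "unknown lobule ids")
})

test_that("classification is deterministic", {
  fix <- small_hierarchy()
  crit <- lobule_criteria()
  a <- initial_classify(fix$hier, 0L, crit)
  b <- initial_classify(fix$hier, 0L, crit)
  expect_identical(a, b)
})
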