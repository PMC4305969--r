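# Shared fixtures.  Expensive objects (synthetic slides, pipeline runs) are
# built once per session and cached.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, builder(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# a compact synthetic slide: 3 lobules over two bands, small enough for
# per-test segmentation (~260 x 360 working pixels)
small_synth_config <- function(seed = 7L, lobulitis = FALSE) {
  synth_config(seed = seed,
               full_dims = c(2600L, 4400L),
               n_lobules_per_band = c(adjacent = 1L, intermediate = 2L,
                                      distant = 0L),
               band_distance_mm = list(adjacent = c(0.30, 0.45),
                                       intermediate = c(0.55, 0.85),
                                       distant = c(0.95, 1.15)),
               lobule_area_working_px = c(2500, 4500),
               lobulitis = lobulitis)
}

small_slide <- function() cached("small_slide", function() {
  generate_slide(small_synth_config())
})

small_hierarchy <- function() cached("small_hier", function() {
  sl <- small_slide()
  wv <- render_working_view(sl)
  tex <- build_texture_layer(wv$image)
  tm <- tissue_mask_from_image(wv$image)
  list(slide = sl, view = wv, texture = tex, tissue = tm,
       hier = multires_hierarchy(wv$image, tex, tm))
})

# the spec's default end-to-end world: 12 lobules, 5/10/15% positivity by
# band, fixed seed
default_e2e_run <- function() cached("e2e_run", function() {
  slide <- generate_slide(synth_config(seed = 1L))
  list(slide = slide, result = run_pipeline(slide))
})

# circular mask helper
disk_mask <- function(n, radius, center = c((n + 1) / 2, (n + 1) / 2)) {
  outer(seq_len(n), seq_len(n), function(r, c) {
    (r - center[1])^2 + (c - center[2])^2 <= radius^2
  })
}

# a hand-built single-level segment graph for tumor seeding/growth tests:
# horizontal stripes with prescribed texture means
stripe_hierarchy <- function(means, widths = rep(10L, length(means)),
                             ncol = 40L) {
  nr <- sum(widths)
  lab <- matrix(0L, nr, ncol)
  tex <- matrix(0, nr, ncol)
  r0 <- 1L
  for (i in seq_along(means)) {
    rows <- r0:(r0 + widths[i] - 1L)
    lab[rows, ] <- i
    tex[rows, ] <- means[i]
    r0 <- r0 + widths[i]
  }
  feats <- data.frame(id = seq_along(means),
                      area_px = widths * ncol,
                      mean_r = 0, mean_g = 0, mean_b = 0,
                      mean_texture = means, mean_stddevn = means,
                      roundness = 0.5, parent = NA_integer_)
  structure(list(
    levels = list(NULL, NULL, NULL,
                  structure(list(level_index = 3L, scale = 40,
                                 labels = lab, features = feats,
                                 adjacency = lobulaR:::cpp_label_adjacency(lab),
                                 perimeter = lobulaR:::cpp_label_perimeter(lab),
                                 pixel_size_um = 5.6),
                            class = "seg_level")),
    merges = NULL, channels = NULL,
    stddevn = tex, mask = lab > 0L, pixel_size_um = 5.6),
    class = "seg_hierarchy")
}
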