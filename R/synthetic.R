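#' Configuration of a synthetic IHC slide
#'
#' The generator emulates the tissue classes the detection rules target, at
#' the calibrated geometry of a 20x scan (0.56 um/px): a white glass
#' background; an eosin-tinted, low-texture stromal plate; mammary lobules as
#' round clusters of tubules (rings of nuclei around bright lumens) whose
#' nucleus-scale intensity alternation produces the bright stddev-n blobs the
#' classifier keys on; and a coherent, irregular tumor mass rendered as a
#' dense nucleus sheet of intermediate texture.  Nuclei absorb light
#' following Beer-Lambert mixing of the hematoxylin and DAB reference
#' spectra, so the HSD deconvolution has an exact forward-model inverse.
#' Each lobule's DAB-positive fraction is set by its distance band.
#'
#' All randomness derives from `seed`; pixel noise is a coordinate-hashed
#' field, so any sub-grid renders identically no matter how the slide is
#' tiled.
#'
#' @param seed integer seed fixing the whole scene.
#' @param full_dims full-resolution grid (rows, cols); the default
#'   5600 x 10400 px spans 3.1 x 5.8 mm, enough for a distant band beyond
#'   2 mm from the tumor border.
#' @param pixel_size_um full-resolution pixel size.
#' @param working_scale downsampling fraction of the working view.
#' @param n_lobules_per_band lobules per distance band
#'   (adjacent, intermediate, distant).
#' @param band_positive_fraction DAB-positive nucleus fraction per band.
#' @param band_distance_mm sampling range of centroid-to-tumor-border
#'   distance per band, chosen inside the analysis bins <0.5 / 0.5-2 / >2 mm.
#' @param lobule_area_working_px sampling range of lobule area at working
#'   resolution (inside the 2000-14000 px^2 acceptance window).
#' @param tubule_spacing_px,ring_radius_px,lumen_radius_px tubule geometry in
#'   full-resolution pixels.
#' @param nucleus_radius_px mean nucleus radius (~3.4 um).
#' @param nucleus_density peak optical density of a nucleus (either stain).
#' @param stroma_density,stroma_noise eosin density of stroma and its
#'   value-noise amplitude.
#' @param tumor_cyto_density extra eosin density inside the tumor mass.
#' @param tumor_nucleus_spacing_px lattice spacing of the tumor nucleus
#'   sheet; smaller = denser = smoother at working resolution.
#' @param noise_sd Gaussian intensity noise (0-255 scale).
#' @param lobulitis if `TRUE`, scatter dense small immune-cell nuclei around
#'   tubules, emulating lymphocytic lobulitis (the dominant real-world
#'   failure mode of lobule detection).
#' @param i0 background (glass) intensity per channel.
#' @return A `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         full_dims = c(5600L, 10400L),
                         pixel_size_um = 0.56,
                         working_scale = 0.1,
                         n_lobules_per_band = c(adjacent = 4L,
                                                intermediate = 4L,
                                                distant = 4L),
                         band_positive_fraction = c(adjacent = 0.05,
                                                    intermediate = 0.10,
                                                    distant = 0.15),
                         band_distance_mm = list(
                           adjacent = c(0.30, 0.45),
                           intermediate = c(0.70, 1.80),
                           distant = c(2.10, 2.60)),
                         lobule_area_working_px = c(3000, 6500),
                         tubule_spacing_px = 115,
                         ring_radius_px = 42,
                         lumen_radius_px = 26,
                         nucleus_radius_px = 6,
                         nucleus_density = 0.50,
                         stroma_density = 0.30,
                         stroma_noise = 0.03,
                         tumor_cyto_density = 0.18,
                         tumor_nucleus_spacing_px = 9,
                         noise_sd = 0.9,
                         stroma_fiber_noise = 0,
                         fibroblast_spacing_px = 65,
                         fibroblast_radius_px = 3.2,
                         fibroblast_density = 0,
                         lobulitis = FALSE,
                         i0 = c(245, 245, 245)) {
  stopifnot(all(full_dims >= 100), pixel_size_um > 0,
            working_scale > 0, working_scale <= 1,
            all(band_positive_fraction >= 0),
            all(band_positive_fraction <= 1))
  structure(as.list(environment()), class = "synth_config")
}

# deterministic coordinate-hash uniform field in [0, 1)
hash01 <- function(r, c, k, seed) {
  x <- sin(r * 12.9898 + c * 78.2330 + k * 37.7190 +
             seed * 0.6180339) * 43758.5453
  x - floor(x)
}

# hash-based standard normal field (Box-Muller)
hash_normal <- function(r, c, k, seed) {
  u1 <- pmax(hash01(r, c, k * 2 + 11, seed), 1e-12)
  u2 <- hash01(r, c, k * 2 + 12, seed)
  sqrt(-2 * log(u1)) * cos(2 * pi * u2)
}

# smooth value noise on a coarse lattice, bilinear with smoothstep weights
value_noise <- function(r, c, cell, k, seed) {
  ri <- floor(r / cell); ci <- floor(c / cell)
  fr <- r / cell - ri; fc <- c / cell - ci
  sr <- fr * fr * (3 - 2 * fr); sc <- fc * fc * (3 - 2 * fc)
  v00 <- hash01(ri, ci, k, seed);     v10 <- hash01(ri + 1, ci, k, seed)
  v01 <- hash01(ri, ci + 1, k, seed); v11 <- hash01(ri + 1, ci + 1, k, seed)
  v00 * (1 - sr) * (1 - sc) + v10 * sr * (1 - sc) +
    v01 * (1 - sr) * sc + v11 * sr * sc
}

# star-shaped blob: radius(theta) = r0 * (1 + sum a_k cos(k theta + phi_k))
star_shape <- function(center, r0, amps, phases, ks) {
  list(center = center, r0 = r0, amps = amps, phases = phases, ks = ks)
}

star_radius <- function(shape, theta) {
  f <- rep(1, length(theta))
  for (i in seq_along(shape$ks)) {
    f <- f + shape$amps[i] * cos(shape$ks[i] * theta + shape$phases[i])
  }
  shape$r0 * f
}

star_inside <- function(shape, r, c) {
  dr <- r - shape$center[1]; dc <- c - shape$center[2]
  rho <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  rho <= star_radius(shape, theta)
}

# tumor mass boundary: everything left of a wavy vertical invasive edge
tumor_inside <- function(shape, r, c) {
  f <- rep(1, length(r))
  for (i in seq_along(shape$ks)) {
    f <- f + shape$amps[i] *
      cos(shape$ks[i] * pi * r / shape$nr + shape$phases[i])
  }
  c <= shape$b0 * shape$nc * f
}

# elliptical tissue plate with a wavy edge
ellipse_inside <- function(shape, r, c) {
  dr <- (r - shape$center[1]) / shape$ar
  dc <- (c - shape$center[2]) / shape$ac
  rho <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc)
  f <- rep(1, length(theta))
  for (i in seq_along(shape$ks)) {
    f <- f + shape$amps[i] * cos(shape$ks[i] * theta + shape$phases[i])
  }
  rho <= f
}

#' Generate a synthetic slide with ground truth
#'
#' Builds the deterministic scene (tissue plate, tumor mass, lobules with
#' per-nucleus positions and stain classes) and the working-resolution
#' ground-truth masks.  The full-resolution image is virtual: any tile can
#' be rendered on demand with [render_tile()], and [render_working_view()]
#' produces the exact nearest-neighbour 10% downsample without materialising
#' the gigapixel image.
#'
#' @param config a [synth_config()].
#' @return A `synthetic_slide` with elements `config`, `scene`, and `truth`
#'   (tissue/tumor/lobule masks at working resolution plus a per-lobule
#'   table: centroid, area, distance to tumor border, nucleus counts and the
#'   DAB-positive fraction actually placed).
#' @export
generate_slide <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  nr <- config$full_dims[1]; nc <- config$full_dims[2]
  wpx <- config$pixel_size_um / config$working_scale   # working um/px
  mm_px <- 1000 / wpx                                  # working px per mm

  tissue_shape <- list(center = c(nr / 2, nc / 2),
                       ar = 0.46 * nr, ac = 0.46 * nc,
                       ks = 2:5, amps = stats::runif(4, 0.01, 0.04),
                       phases = stats::runif(4, 0, 2 * pi))
  # coherent mass occupying the left end of the section up to a wavy
  # vertical invasive edge -- the workflow assumes a tumor-dominant slide,
  # so the mass takes a realistic share of the tissue plate
  tumor_shape <- list(type = "wall", nc = nc, nr = nr, b0 = 0.40,
                      ks = 1:4, amps = stats::runif(4, 0.02, 0.07),
                      phases = stats::runif(4, 0, 2 * pi))

  # working-resolution sample coordinates (exact nearest-neighbour grid)
  rows_w <- nn_index(nr, config$working_scale)
  cols_w <- nn_index(nc, config$working_scale)
  Rw <- matrix(rows_w, length(rows_w), length(cols_w))
  Cw <- matrix(cols_w, length(rows_w), length(cols_w), byrow = TRUE)
  tissue_w <- matrix(ellipse_inside(tissue_shape, as.vector(Rw),
                                    as.vector(Cw)),
                     length(rows_w), length(cols_w))
  tumor_w <- matrix(tumor_inside(tumor_shape, as.vector(Rw), as.vector(Cw)),
                    length(rows_w), length(cols_w)) & tissue_w

  # distance (working px) of every working pixel to the tumor border
  tregion <- structure(list(mask = tumor_w, pixel_size_um = wpx),
                       class = "tumor_region")
  border_w <- tumor_border(tregion)
  dist_map <- distance_transform(!border_w)     # px to nearest border pixel
  tissue_edt <- distance_transform(tissue_w)

  # --- place lobules by rejection against band distance and overlap -------
  bands <- names(config$n_lobules_per_band)
  lobules <- list()
  placed <- matrix(numeric(0), 0, 3)   # row_w, col_w, radius_w
  lid <- 0L
  for (band in bands) {
    n_b <- config$n_lobules_per_band[[band]]
    d_rng <- config$band_distance_mm[[band]] * mm_px
    for (i in seq_len(n_b)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        area_w <- stats::runif(1, config$lobule_area_working_px[1],
                               config$lobule_area_working_px[2])
        r_w <- sqrt(area_w / pi)
        d_lo <- max(d_rng[1], r_w + 12)
        if (d_lo >= d_rng[2]) next
        d_target <- stats::runif(1, d_lo, d_rng[2])
        # the lobule spacing buffer and the distance-band tolerance relax
        # over the retries so crowded layouts remain solvable
        buffer <- if (try <= 300L) 10 else if (try <= 600L) 4 else 0
        tol <- if (try <= 500L) 3 else 6
        cand <- which(abs(dist_map - d_target) <= tol & tissue_w &
                        !tumor_w & dist_map > r_w + 8 &
                        tissue_edt > r_w + 25)
        if (!length(cand)) next
        if (nrow(placed)) {
          cr <- (cand - 1L) %% nrow(tissue_w) + 1L
          cc <- (cand - 1L) %/% nrow(tissue_w) + 1L
          free <- rep(TRUE, length(cand))
          for (p in seq_len(nrow(placed))) {
            free <- free & (placed[p, 1] - cr)^2 + (placed[p, 2] - cc)^2 >=
              (placed[p, 3] + r_w + buffer)^2
          }
          cand <- cand[free]
          if (!length(cand)) next
        }
        pick <- cand[sample.int(length(cand), 1L)]
        pr <- (pick - 1L) %% nrow(tissue_w) + 1L
        pc <- (pick - 1L) %/% nrow(tissue_w) + 1L
        placed <- rbind(placed, c(pr, pc, r_w))
        lid <- lid + 1L
        lobules[[lid]] <- make_lobule(config, lid, band,
                                      center_full = c(rows_w[pr], cols_w[pc]),
                                      radius_full = r_w / config$working_scale)
        ok <- TRUE
        break
      }
      if (!ok) {
        n_feas <- sum(abs(dist_map - mean(d_rng)) <= 3 & tissue_w &
                        !tumor_w & dist_map > 40 & tissue_edt > 50)
        stop(sprintf(paste0("could not place lobule %d in band '%s' after ",
                            "%d tries (%d pixels near the band centre ",
                            "satisfy the geometry; placed so far: %d)"),
                     i, band, 1000L, n_feas, lid))
      }
    }
  }

  # tumor nucleus sheet: jittered lattice clipped to the blob
  sp <- config$tumor_nucleus_spacing_px
  # stratified placement: one nucleus uniform within each lattice cell.
  # A lightly jittered lattice would beat against the 10x nearest-neighbour
  # sampling grid and imprint slow moire texture waves on the working view;
  # fully random (Poisson) placement clumps and overshoots the texture.
  c_max <- tumor_shape$b0 * nc * 1.35
  gr <- seq(1, nr - sp, by = sp)
  gc <- seq(1, c_max - sp, by = sp)
  n_tn <- length(gr) * length(gc)
  tn_r <- rep(gr, times = length(gc)) + stats::runif(n_tn, 0, sp)
  tn_c <- rep(gc, each = length(gr)) + stats::runif(n_tn, 0, sp)
  inside <- tumor_inside(tumor_shape, tn_r, tn_c) &
    ellipse_inside(tissue_shape, tn_r, tn_c)
  tn_r <- tn_r[inside]; tn_c <- tn_c[inside]
  # nested carcinoma: two-level nucleus density quantised over ~170 um
  # patches.  The sharp patch boundaries fragment the mass into many
  # segments at the finest scales (so the non-lobule median texture falls
  # inside the tumor), while the patch texture means differ by well under
  # the growth rule's delta of 2, so accretion sweeps the whole mass.
  vn_t <- value_noise(tn_r, tn_c, 300, 7L, config$seed)
  tumor_nuclei <- data.frame(
    r = tn_r, c = tn_c,
    rad = config$nucleus_radius_px * stats::runif(length(tn_r), 0.72, 0.85),
    peak = config$nucleus_density * ifelse(vn_t > 0.5, 1.04, 0.96) *
      stats::runif(length(tn_r), 0.98, 1.02))

  # scattered fibroblast nuclei give the stroma its realistic baseline
  # texture (raw stddev-n ~6-8 vs 15-36 in lobules); excluded from lobule
  # disks and the tumor mass, which carry their own cell populations
  fsp <- config$fibroblast_spacing_px
  fgr <- seq(1, nr, by = fsp)
  fgc <- seq(1, nc, by = fsp)
  fb_r <- rep(fgr, times = length(fgc)) +
    stats::runif(length(fgr) * length(fgc), -fsp / 2.2, fsp / 2.2)
  fb_c <- rep(fgc, each = length(fgr)) +
    stats::runif(length(fgr) * length(fgc), -fsp / 2.2, fsp / 2.2)
  fb_keep <- ellipse_inside(tissue_shape, fb_r, fb_c) &
    !tumor_inside(tumor_shape, fb_r, fb_c)
  for (lb in lobules) {
    fb_keep <- fb_keep &
      ((fb_r - lb$center_full[1])^2 + (fb_c - lb$center_full[2])^2 >
         (lb$radius_full + 8)^2)
  }
  stroma_nuclei <- data.frame(
    r = fb_r[fb_keep], c = fb_c[fb_keep],
    rad = config$fibroblast_radius_px *
      stats::runif(sum(fb_keep), 0.8, 1.2),
    peak = config$fibroblast_density *
      stats::runif(sum(fb_keep), 0.8, 1.2))

  # ground-truth lobule masks + table at working resolution
  lob_lab_w <- matrix(0L, length(rows_w), length(cols_w))
  truth_rows <- list()
  for (lb in lobules) {
    m <- (Rw - lb$center_full[1])^2 + (Cw - lb$center_full[2])^2 <=
      lb$radius_full^2
    lob_lab_w[m] <- lb$id
    idx <- which(m, arr.ind = TRUE)
    ctr_r <- mean(idx[, 1]); ctr_c <- mean(idx[, 2])
    bidx <- which(border_w, arr.ind = TRUE)
    d_mm <- sqrt(min((bidx[, 1] - ctr_r)^2 + (bidx[, 2] - ctr_c)^2)) / mm_px
    truth_rows[[lb$id]] <- data.frame(
      lobule_id = lb$id, band = lb$band,
      centroid_row_w = ctr_r - 1, centroid_col_w = ctr_c - 1,
      area_w_px = sum(m),
      distance_mm = d_mm,
      n_nuclei = nrow(lb$nuclei),
      n_pos = sum(lb$nuclei$stain == "dab"),
      positive_fraction = mean(lb$nuclei$stain == "dab"),
      stringsAsFactors = FALSE)
  }
  truth <- list(
    tissue_w = tissue_w, tumor_w = tumor_w, lobule_labels_w = lob_lab_w,
    lobules = if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(),
    rows_w = rows_w, cols_w = cols_w,
    working_pixel_size_um = wpx)

  structure(list(config = config,
                 scene = list(tissue = tissue_shape, tumor = tumor_shape,
                              tumor_nuclei = tumor_nuclei,
                              stroma_nuclei = stroma_nuclei,
                              lobules = lobules),
                 truth = truth),
            class = "synthetic_slide")
}

# one lobule: hex-packed tubules, each a ring of nuclei around a lumen.
# The lobule radius is tied to the actual tubule extent so the content fills
# its ground-truth disk with a crisp edge (real lobules carry tubules to
# their border; a sparse rim would create an artificial intermediate-texture
# halo).
make_lobule <- function(config, id, band, center_full, radius_full) {
  s <- config$tubule_spacing_px
  reach <- config$ring_radius_px * 1.08 + config$nucleus_radius_px * 1.15 + 3
  rr <- radius_full - reach
  # concentric-ring tubule packing: tubules fill the lobule disk uniformly
  # out to its boundary (real lobules carry tubules to their edge; gaps in
  # the outer band would create a low-texture halo with no anatomical
  # counterpart)
  radii <- seq(rr, 0, by = -0.87 * s)
  centers <- NULL
  for (rk in radii) {
    n_k <- max(1L, round(2 * pi * rk / s))
    ang <- seq(0, 2 * pi, length.out = n_k + 1L)[-(n_k + 1L)] +
      stats::runif(1, 0, 2 * pi)
    jit <- if (rk == rr) 0 else 4      # keep the outline ring crisp
    centers <- rbind(centers,
                     cbind(rk * sin(ang) + stats::runif(n_k, -jit, jit),
                           rk * cos(ang) + stats::runif(n_k, -jit, jit)))
  }
  radius_full <- max(sqrt(rowSums(centers^2))) + reach
  nuc <- list()
  for (t in seq_len(nrow(centers))) {
    ring_r <- config$ring_radius_px * stats::runif(1, 0.92, 1.08)
    n_n <- max(6L, floor(2 * pi * ring_r / (2.3 * config$nucleus_radius_px)))
    ang <- seq(0, 2 * pi, length.out = n_n + 1L)[-(n_n + 1L)] +
      stats::runif(1, 0, 2 * pi) + stats::runif(n_n, -0.04, 0.04)
    rad_i <- ring_r + stats::runif(n_n, -1.5, 1.5)
    nuc[[t]] <- data.frame(
      r = center_full[1] + centers[t, 1] + rad_i * sin(ang),
      c = center_full[2] + centers[t, 2] + rad_i * cos(ang),
      rad = config$nucleus_radius_px * stats::runif(n_n, 0.85, 1.15),
      tubule = t)
  }
  nuclei <- do.call(rbind, nuc)
  if (isTRUE(config$lobulitis)) {
    n_extra <- round(nrow(nuclei) * 1.5)
    rho <- radius_full * sqrt(stats::runif(n_extra))
    th <- stats::runif(n_extra, 0, 2 * pi)
    nuclei <- rbind(nuclei, data.frame(
      r = center_full[1] + rho * sin(th),
      c = center_full[2] + rho * cos(th),
      rad = config$nucleus_radius_px * stats::runif(n_extra, 0.45, 0.6),
      tubule = 0L))
  }
  frac <- config$band_positive_fraction[[band]]
  n_pos <- round(frac * nrow(nuclei))
  stain <- rep("hema", nrow(nuclei))
  if (n_pos > 0) stain[sample.int(nrow(nuclei), n_pos)] <- "dab"
  nuclei$stain <- stain
  list(id = id, band = band, center_full = center_full,
       radius_full = radius_full, tubule_centers = centers,
       nuclei = nuclei)
}

hex_points <- function(radius, spacing) {
  if (radius < 0) return(matrix(numeric(0), 0, 2))
  ny <- ceiling(radius / (spacing * sqrt(3) / 2))
  pts <- list()
  k <- 0L
  for (iy in -ny:ny) {
    y <- iy * spacing * sqrt(3) / 2
    off <- if (iy %% 2 == 0) 0 else spacing / 2
    nx <- ceiling(radius / spacing) + 1L
    for (ix in -nx:nx) {
      x <- ix * spacing + off
      if (x^2 + y^2 <= radius^2) {
        k <- k + 1L
        pts[[k]] <- c(y, x)
      }
    }
  }
  if (!k) return(matrix(numeric(0), 0, 2))
  do.call(rbind, pts)
}

# --- rendering --------------------------------------------------------------

#' Render the virtual full-resolution image on an arbitrary pixel grid
#'
#' @param slide a `synthetic_slide`.
#' @param rows,cols increasing integer vectors of full-resolution
#'   coordinates; the result is the outer grid `rows x cols`.
#' @return Numeric array `length(rows) x length(cols) x 3` of intensities.
#' @export
render_grid <- function(slide, rows, cols) {
  cfg <- slide$config
  sc <- slide$scene
  nrg <- length(rows); ncg <- length(cols)
  Rm <- matrix(rows, nrg, ncg)
  Cm <- matrix(cols, nrg, ncg, byrow = TRUE)
  tissue <- matrix(ellipse_inside(sc$tissue, as.vector(Rm), as.vector(Cm)),
                   nrg, ncg)
  tumor <- matrix(tumor_inside(sc$tumor, as.vector(Rm), as.vector(Cm)),
                  nrg, ncg) & tissue

  a_e <- matrix(0, nrg, ncg)
  a_h <- matrix(0, nrg, ncg)
  a_d <- matrix(0, nrg, ncg)

  vn <- matrix(value_noise(as.vector(Rm), as.vector(Cm), 120, 3, cfg$seed),
               nrg, ncg)
  a_e[tissue] <- cfg$stroma_density + cfg$stroma_noise * (vn[tissue] - 0.5)
  # fine-scale collagen fibre texture
  fib <- matrix(value_noise(as.vector(Rm), as.vector(Cm), 12, 9L, cfg$seed),
                nrg, ncg)
  a_e[tissue] <- a_e[tissue] +
    cfg$stroma_fiber_noise * (fib[tissue] - 0.5)
  a_e[a_e < 0] <- 0
  a_e[tumor] <- a_e[tumor] + cfg$tumor_cyto_density

  # tumor nuclei (hematoxylin), density varying across nests
  tn <- sc$tumor_nuclei
  cpp_stamp_disks(a_h, rows, cols, tn$r, tn$c, tn$rad, tn$peak, 1.5, 0L)
  # stromal fibroblast nuclei
  fb <- sc$stroma_nuclei
  cpp_stamp_disks(a_h, rows, cols, fb$r, fb$c, fb$rad, fb$peak, 1.5, 0L)
  # lobules: lumens (eosin cleared) and tubule nuclei
  r0 <- rows[1]; r1 <- rows[nrg]; c0 <- cols[1]; c1 <- cols[ncg]
  for (lb in sc$lobules) {
    reach <- lb$radius_full + 20
    if (lb$center_full[1] < r0 - reach || lb$center_full[1] > r1 + reach ||
        lb$center_full[2] < c0 - reach || lb$center_full[2] > c1 + reach) {
      next
    }
    tc <- lb$tubule_centers
    cpp_stamp_disks(a_e, rows, cols,
                    lb$center_full[1] + tc[, 1], lb$center_full[2] + tc[, 2],
                    rep(cfg$lumen_radius_px, nrow(tc)),
                    rep(0.85, nrow(tc)), 2, 1L)   # lumens are nearly clear
    nuc <- lb$nuclei
    dab <- nuc$stain == "dab"
    if (any(dab)) {
      cpp_stamp_disks(a_d, rows, cols, nuc$r[dab], nuc$c[dab], nuc$rad[dab],
                      rep(cfg$nucleus_density, sum(dab)), 1.5, 0L)
    }
    if (any(!dab)) {
      cpp_stamp_disks(a_h, rows, cols, nuc$r[!dab], nuc$c[!dab],
                      nuc$rad[!dab],
                      rep(cfg$nucleus_density, sum(!dab)), 1.5, 0L)
    }
  }

  ref <- stain_reference(i0 = cfg$i0)
  eos <- c(0.093, 0.954, 0.283)
  eos <- eos / mean(eos)
  img <- array(0, c(nrg, ncg, 3L))
  for (k in 1:3) {
    od <- a_h * ref$hema[k] + a_d * ref$dab[k] + a_e * eos[k]
    base <- cfg$i0[k] * exp(-od)
    noise <- matrix(hash_normal(as.vector(Rm), as.vector(Cm), k, cfg$seed),
                    nrg, ncg)
    img[, , k] <- pmin(255, pmax(0, base + cfg$noise_sd * noise))
  }
  img
}

#' Render a contiguous full-resolution tile
#'
#' @param slide a `synthetic_slide`.
#' @param r0,r1,c0,c1 inclusive full-resolution bounds.
#' @return An [rgb_raster] at full resolution.
#' @export
render_tile <- function(slide, r0, r1, c0, c1) {
  stopifnot(r0 >= 1, c0 >= 1, r1 <= slide$config$full_dims[1],
            c1 <= slide$config$full_dims[2], r0 <= r1, c0 <= c1)
  rgb_raster(render_grid(slide, r0:r1, c0:c1), slide$config$pixel_size_um)
}

#' Working-resolution view of a synthetic slide
#'
#' The exact nearest-neighbour downsample of the virtual full-resolution
#' image (only the sampled pixels are rendered), plus the ground-truth masks
#' on the same grid.
#'
#' @param slide a `synthetic_slide`.
#' @return List: `image` ([rgb_raster] at working resolution), `tissue`,
#'   `tumor` (logical masks), `lobule_labels` (integer matrix).
#' @export
render_working_view <- function(slide) {
  tr <- slide$truth
  img <- render_grid(slide, tr$rows_w, tr$cols_w)
  list(image = rgb_raster(img, tr$working_pixel_size_um),
       tissue = tr$tissue_w, tumor = tr$tumor_w,
       lobule_labels = tr$lobule_labels_w)
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_slide> %d x %d px @ %.2f um/px, ",
                     "%d lobules, %d tumor nuclei\n"),
              x$config$full_dims[1], x$config$full_dims[2],
              x$config$pixel_size_um, length(x$scene$lobules),
              nrow(x$scene$tumor_nuclei)))
  invisible(x)
}
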