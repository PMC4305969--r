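# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the implementation they check.

# per-pixel RMS deviation to the 8-neighbourhood
oracle_stddevn <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    for (c in seq_len(ncol(m))) {
      acc <- 0; n <- 0
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nrow(m) || cc < 1 || cc > ncol(m)) next
        acc <- acc + (m[rr, cc] - m[r, c])^2
        n <- n + 1
      }
      out[r, c] <- sqrt(acc / n)
    }
  }
  out
}

# Otsu by direct minimisation of within-class variance over bin edges
oracle_otsu <- function(values, n_bins = 256L) {
  v <- as.numeric(values)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1L)
  best <- Inf; best_t <- NA
  for (k in 2:n_bins) {
    t <- breaks[k]
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w <- (length(lo) * pop_var(lo) + length(hi) * pop_var(hi)) / length(v)
    if (w < best) { best <- w; best_t <- t }
  }
  best_t
}
pop_var <- function(x) mean((x - mean(x))^2)

# Exhaustive-merge oracle for the spectral-only region-merging cost: at
# every step recompute the cost of EVERY adjacent pair from raw pixel
# membership and merge the global minimum (ties by lowest id pair).
oracle_merge_sequence <- function(channels, weights, mask) {
  nr <- dim(channels)[1]; nc <- dim(channels)[2]; nch <- dim(channels)[3]
  px_id <- function(r, c) r + (c - 1L) * nr
  members <- list()
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (mask[r, c]) members[[as.character(px_id(r, c))]] <- px_id(r, c)
  }
  hval <- function(pxs) {
    h <- 0
    for (k in seq_len(nch)) {
      v <- channels[, , k][pxs]
      h <- h + weights[k] * length(v) * sqrt(pop_var(v))
    }
    h
  }
  adjacent <- function(pa, pb) {
    for (p in pa) {
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d[1] + d[2] * nr
        rr <- r + d[1]; cc <- c + d[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (q %in% pb) return(TRUE)
      }
    }
    FALSE
  }
  seq_out <- list()
  repeat {
    ids <- as.integer(names(members))
    best <- NULL
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (j <= i) next
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        pa <- members[[as.character(a)]]; pb <- members[[as.character(b)]]
        if (!adjacent(pa, pb)) next
        cost <- hval(c(pa, pb)) - hval(pa) - hval(pb)
        if (is.null(best) || cost < best$cost - 1e-9 ||
            (abs(cost - best$cost) <= 1e-9 &&
             (a < best$a || (a == best$a && b < best$b)))) {
          best <- list(cost = cost, a = a, b = b)
        }
      }
    }
    if (is.null(best)) break
    seq_out[[length(seq_out) + 1L]] <- best
    members[[as.character(best$a)]] <-
      c(members[[as.character(best$a)]], members[[as.character(best$b)]])
    members[[as.character(best$b)]] <- NULL
  }
  seq_out
}

# Beer-Lambert forward model: intensities of a pixel carrying the given
# hematoxylin / DAB amounts under a stain reference
forward_pixel <- function(a_hema, a_dab, ref = stain_reference()) {
  vapply(1:3, function(k) {
    ref$i0[k] * exp(-(a_hema * ref$hema[k] + a_dab * ref$dab[k]))
  }, numeric(1))
}

tile_from_pixel <- function(px_rgb, nr = 4, nc = 4, pixel_size_um = 0.56) {
  arr <- array(0, c(nr, nc, 3))
  for (k in 1:3) arr[, , k] <- px_rgb[k]
  rgb_raster(arr, pixel_size_um)
}
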