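# Minimal image I/O: baseline TIFF (uncompressed, strip-based, little-endian)
# and PNM (PGM/PPM).  No image I/O package ships with the target platform,
# and only the baseline subset is needed: 8/16-bit grayscale and 8-bit RGB.

#' Read a TIFF or PNM image
#'
#' Supports uncompressed baseline TIFF (8/16-bit grayscale, 8-bit RGB) and
#' binary/ASCII PGM/PPM.  The pixel size is taken from the TIFF resolution
#' tags when present (resolution unit cm or inch), else from the
#' `pixel_size_um` argument.
#'
#' @param path file path.
#' @param pixel_size_um fallback pixel size in micrometres.
#' @return An [rgb_raster] (3-channel input) or [raster_layer] (1-channel).
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  magic <- readBin(path, "raw", n = 2L)
  if (all(magic == charToRaw("II")) || all(magic == charToRaw("MM"))) {
    return(read_tiff(path, pixel_size_um))
  }
  if (magic[1] == charToRaw("P")) {
    return(read_pnm(path, pixel_size_um))
  }
  stop("unrecognised image format (expected TIFF or PNM): ", path)
}

# --- TIFF -------------------------------------------------------------------

tiff_tag <- function(id, type, count, value) {
  list(id = id, type = type, count = count, value = value)
}

#' Write an image as uncompressed baseline TIFF
#'
#' Grayscale matrices are written as 8-bit (values 0-255) or 16-bit (larger
#' values, e.g. label images); [rgb_raster]s as 8-bit RGB.  The pixel size is
#' stored in the resolution tags (pixels per centimetre).
#'
#' @param image an [rgb_raster], [raster_layer], or plain matrix.
#' @param path output path.
#' @param pixel_size_um pixel size to record; taken from the object when it
#'   carries one.
#' @export
write_tiff <- function(image, path, pixel_size_um = NULL) {
  if (inherits(image, "rgb_raster")) {
    px <- round(image$pixels)
    pixel_size_um <- image$pixel_size_um
    spp <- 3L; bps <- 8L
  } else {
    m <- if (inherits(image, "raster_layer")) {
      pixel_size_um <- image$pixel_size_um
      image$values
    } else image
    px <- round(m)
    spp <- 1L
    bps <- if (max(px) > 255 || min(px) < 0) 16L else 8L
    if (bps == 16L && (max(px) > 65535 || min(px) < 0)) {
      stop("matrix values out of range for 16-bit TIFF")
    }
  }
  nr <- if (spp == 3L) dim(px)[1] else nrow(px)
  nc <- if (spp == 3L) dim(px)[2] else ncol(px)
  # interleave row-major
  if (spp == 3L) {
    arr <- aperm(px, c(3, 2, 1))          # channel, col, row
    data <- as.integer(arr)
  } else {
    data <- as.integer(t(px))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")      # IFD offset
  res_ppcm <- if (is.null(pixel_size_um)) 0 else 10000 / pixel_size_um
  n_tags <- 12L
  ifd_size <- 2L + n_tags * 12L + 4L
  extra_off <- 8L + ifd_size
  # extra data: two RATIONALs (x/y resolution), then pixel data
  data_off <- extra_off + 16L
  byte_count <- length(data) * (bps / 8L)
  tags <- list(
    tiff_tag(256L, 3L, 1L, nc),                    # ImageWidth
    tiff_tag(257L, 3L, 1L, nr),                    # ImageLength
    tiff_tag(258L, 3L, 1L, bps),                   # BitsPerSample (spp=1|3*8)
    tiff_tag(259L, 3L, 1L, 1L),                    # Compression = none
    tiff_tag(262L, 3L, 1L, if (spp == 3L) 2L else 1L),  # Photometric
    tiff_tag(273L, 4L, 1L, data_off),              # StripOffsets
    tiff_tag(277L, 3L, 1L, spp),                   # SamplesPerPixel
    tiff_tag(278L, 3L, 1L, nr),                    # RowsPerStrip
    tiff_tag(279L, 4L, 1L, byte_count),            # StripByteCounts
    tiff_tag(282L, 5L, 1L, extra_off),             # XResolution
    tiff_tag(283L, 5L, 1L, extra_off + 8L),        # YResolution
    tiff_tag(296L, 3L, 1L, 3L)                     # ResolutionUnit = cm
  )
  writeBin(n_tags, con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg$id), con, size = 2, endian = "little")
    writeBin(as.integer(tg$type), con, size = 2, endian = "little")
    writeBin(as.integer(tg$count), con, size = 4, endian = "little")
    if (tg$type == 3L) {           # SHORT packed in 4 bytes
      writeBin(as.integer(tg$value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(tg$value), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")   # next IFD
  # rationals: numerator/denominator, pixels per cm
  num <- as.integer(round(res_ppcm * 1000))
  writeBin(c(num, 1000L), con, size = 4, endian = "little")
  writeBin(c(num, 1000L), con, size = 4, endian = "little")
  writeBin(data, con, size = bps / 8L, endian = "little")
  invisible(path)
}

read_tiff <- function(path, pixel_size_um = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  endian <- if (raw[1] == charToRaw("I")) "little" else "big"
  rd <- function(off, size, n = 1L) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size >= 4L)
  }
  ifd_off <- rd(4L, 4L)
  n_tags <- rd(ifd_off, 2L)
  tags <- list()
  for (i in seq_len(n_tags)) {
    base <- ifd_off + 2L + (i - 1L) * 12L
    id <- rd(base, 2L)
    type <- rd(base + 2L, 2L)
    count <- rd(base + 4L, 4L)
    val_off <- base + 8L
    type_size <- c(1L, 1L, 2L, 4L, 8L)[type]
    inline <- type_size * count <= 4L
    value <- if (type == 5L) {                   # RATIONAL
      off <- rd(val_off, 4L)
      rd(off, 4L, 2L)
    } else if (inline) {
      rd(val_off, type_size, count)
    } else {
      off <- rd(val_off, 4L)
      rd(off, type_size, count)
    }
    tags[[as.character(id)]] <- value
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  nc <- need(256L); nr <- need(257L)
  bps <- need(258L, 8L)[1]
  comp <- need(259L, 1L)
  spp <- need(277L, 1L)
  if (comp != 1L) stop("only uncompressed TIFF is supported")
  offs <- need(273L)
  counts <- need(279L)
  if (!is.null(need(282L)) && is.null(pixel_size_um)) {
    r <- need(282L)
    unit <- need(296L, 2L)
    ppu <- r[1] / r[2]
    if (ppu > 0) {
      per_um <- switch(as.character(unit),
                       "2" = ppu / 25400,      # inch
                       "3" = ppu / 10000,      # cm
                       NA)
      if (!is.na(per_um) && per_um > 0) pixel_size_um <- 1 / per_um
    }
  }
  if (is.null(pixel_size_um)) pixel_size_um <- 1
  vals <- integer(0)
  if (bps == 8L) {
    for (i in seq_along(offs)) {
      vals <- c(vals, as.integer(raw[(offs[i] + 1):(offs[i] + counts[i])]))
    }
  } else {
    for (i in seq_along(offs)) {
      n <- counts[i] / 2L
      v <- rd(offs[i], 2L, n)
      vals <- c(vals, ifelse(v < 0, v + 65536L, v))
    }
  }
  if (spp == 3L) {
    arr <- array(vals, dim = c(3L, nc, nr))
    rgb_raster(aperm(arr, c(3, 2, 1)), pixel_size_um)
  } else {
    raster_layer(matrix(vals, nr, nc, byrow = TRUE), pixel_size_um)
  }
}

# --- PNM --------------------------------------------------------------------

#' Write a PGM/PPM image
#'
#' @param image an [rgb_raster] (written as binary PPM) or matrix /
#'   [raster_layer] (binary PGM, 8-bit).
#' @param path output path.
#' @export
write_pnm <- function(image, path) {
  if (inherits(image, "rgb_raster")) {
    px <- round(image$pixels)
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P6", paste(dim(px)[2], dim(px)[1]), "255"), con, sep = "\n")
    arr <- aperm(px, c(3, 2, 1))
    writeBin(as.raw(as.integer(arr)), con)
  } else {
    m <- if (inherits(image, "raster_layer")) image$values else image
    m <- round(m)
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(ncol(m), nrow(m)), "255"), con, sep = "\n")
    writeBin(as.raw(as.integer(t(m))), con)
  }
  invisible(path)
}

read_pnm <- function(path, pixel_size_um = NULL) {
  if (is.null(pixel_size_um)) pixel_size_um <- 1
  raw <- readBin(path, "raw", n = file.info(path)$size)
  txt_head <- rawToChar(raw[1:min(length(raw), 100L)])
  magic <- substr(txt_head, 1, 2)
  # parse header tokens (magic, width, height, maxval), skipping comments
  pos <- 3L
  tokens <- character(0)
  while (length(tokens) < 3L && pos <= length(raw)) {
    ch <- rawToChar(raw[pos])
    if (ch == "#") {
      while (pos <= length(raw) && rawToChar(raw[pos]) != "\n") pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      tok <- ""
      while (pos <= length(raw) && grepl("[0-9]", rawToChar(raw[pos]))) {
        tok <- paste0(tok, rawToChar(raw[pos]))
        pos <- pos + 1L
      }
      tokens <- c(tokens, tok)
    } else {
      pos <- pos + 1L
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  if (magic %in% c("P5", "P6")) {
    data_start <- pos + 1L    # single whitespace after maxval
    n <- w * h * (if (magic == "P6") 3L else 1L)
    vals <- as.integer(raw[data_start:(data_start + n - 1L)])
  } else if (magic %in% c("P2", "P3")) {
    body <- rawToChar(raw[pos:length(raw)])
    vals <- as.integer(strsplit(trimws(gsub("#[^\n]*", "", body)),
                                "[[:space:]]+")[[1]])
  } else {
    stop("unsupported PNM magic: ", magic)
  }
  if (magic %in% c("P6", "P3")) {
    arr <- array(vals, dim = c(3L, w, h))
    rgb_raster(aperm(arr, c(3, 2, 1)) * (255 / maxval), pixel_size_um)
  } else {
    raster_layer(matrix(vals, h, w, byrow = TRUE) * (255 / maxval),
                 pixel_size_um)
  }
}
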