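# Minimal baseline-TIFF support: uncompressed, grayscale, little-endian,
# 8- or 16-bit, one image per page. This is deliberately narrow -- enough to
# round-trip the calibrated stacks this package produces and the plain
# exports common microscopy tools write -- and errors loudly on anything
# fancier (compression, tiles, RGB). No OME-XML, no proprietary formats.

.tif_u16 <- function(raw, off) {
  sum(as.integer(raw[off + 1:2]) * c(1, 256))
}

.tif_u32 <- function(raw, off) {
  sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}

# Read the value array of one IFD entry. types: 3 = SHORT(2), 4 = LONG(4).
.tif_entry_values <- function(raw, entry_off) {
  type <- .tif_u16(raw, entry_off + 2)
  count <- .tif_u32(raw, entry_off + 4)
  size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L,
                 stop("unsupported TIFF field type: ", type))
  total <- size * count
  val_off <- if (total <= 4) entry_off + 8 else .tif_u32(raw, entry_off + 8)
  vapply(seq_len(count), function(i) {
    o <- val_off + (i - 1L) * size
    if (size == 1L) as.numeric(raw[o + 1]) else
      if (size == 2L) .tif_u16(raw, o) else .tif_u32(raw, o)
  }, numeric(1))
}

#' Read a multi-page grayscale TIFF into a list of matrices
#'
#' Supports only what [write_tiff_pages()] emits: little-endian baseline
#' TIFF, uncompressed, single-sample grayscale, 8 or 16 bits per sample,
#' striped storage.
#'
#' @param path file path.
#' @return list of numeric matrices (y, x), one per page.
#' @export
read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file (too short): ", path)
  if (!(raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49))) {
    stop("only little-endian ('II') TIFF is supported")
  }
  if (.tif_u16(raw, 2) != 42) stop("bad TIFF magic number")
  pages <- list()
  ifd_off <- .tif_u32(raw, 4)
  while (ifd_off != 0) {
    n_entries <- .tif_u16(raw, ifd_off)
    tags <- list()
    for (k in seq_len(n_entries)) {
      eo <- ifd_off + 2 + (k - 1L) * 12L
      tags[[as.character(.tif_u16(raw, eo))]] <- .tif_entry_values(raw, eo)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF page missing required tag ", tag)
        default
      } else v
    }
    width <- need(256); height <- need(257)
    bits <- need(258, 1)
    if (need(259, 1) != 1) stop("compressed TIFF not supported")
    if (need(277, 1) != 1) stop("multi-sample (colour) TIFF not supported")
    if (!bits %in% c(8, 16)) stop("only 8/16-bit TIFF supported, got ", bits)
    offs <- need(273); counts <- need(279)
    vals <- unlist(lapply(seq_along(offs), function(i) {
      bytes <- raw[offs[i] + seq_len(counts[i])]
      if (bits == 16) {
        as.integer(bytes[c(TRUE, FALSE)]) + 256L * as.integer(bytes[c(FALSE, TRUE)])
      } else as.integer(bytes)
    }))
    if (length(vals) != width * height) {
      stop(sprintf("TIFF page data length %d does not match %d x %d",
                   length(vals), height, width))
    }
    # strips are row-major; R matrices are column-major
    pages[[length(pages) + 1L]] <-
      matrix(as.numeric(vals), nrow = height, ncol = width, byrow = TRUE)
    ifd_off <- .tif_u32(raw, ifd_off + 2 + n_entries * 12L)
  }
  pages
}

.tif_write_u16 <- function(con, x) {
  writeBin(as.integer(x), con, size = 2, endian = "little")
}

.tif_write_u32 <- function(con, x) {
  # values can exceed .Machine$integer.max in theory; our files are small
  writeBin(as.integer(x), con, size = 4, endian = "little")
}

#' Write matrices as a multi-page 16-bit grayscale TIFF
#'
#' Values are rounded and clamped to the 16-bit range `[0, 65535]` on disk;
#' integer-valued input in range therefore round-trips bit-exactly through
#' [read_tiff_pages()].
#'
#' @param pages list of numeric matrices (y, x), all the same size.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_pages <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, logical(1))))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  if (!all(vapply(pages, function(p) nrow(p) == h && ncol(p) == w, logical(1)))) {
    stop("all pages must share the same dimensions")
  }
  n_tags <- 9L
  strip_len <- 2L * w * h
  ifd_len <- 2L + 12L * n_tags + 4L
  # layout: 8-byte header, then per page [strip][IFD]
  strip_off <- 8 + (seq_along(pages) - 1L) * (strip_len + ifd_len)
  ifd_off <- strip_off + strip_len
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  .tif_write_u16(con, 42)
  .tif_write_u32(con, ifd_off[1])
  entry <- function(tag, type, count, value) {
    .tif_write_u16(con, tag); .tif_write_u16(con, type)
    .tif_write_u32(con, count)
    if (type == 3) { .tif_write_u16(con, value); .tif_write_u16(con, 0) }
    else .tif_write_u32(con, value)
  }
  for (p in seq_along(pages)) {
    vals <- as.integer(pmin(pmax(round(t(pages[[p]])), 0), 65535))
    writeBin(vals, con, size = 2, endian = "little")
    .tif_write_u16(con, n_tags)
    entry(256, 4, 1, w)              # ImageWidth
    entry(257, 4, 1, h)              # ImageLength
    entry(258, 3, 1, 16)             # BitsPerSample
    entry(259, 3, 1, 1)              # Compression: none
    entry(262, 3, 1, 1)              # Photometric: BlackIsZero
    entry(273, 4, 1, strip_off[p])   # StripOffsets
    entry(278, 4, 1, h)              # RowsPerStrip: single strip
    entry(279, 4, 1, strip_len)      # StripByteCounts
    entry(339, 3, 1, 1)              # SampleFormat: unsigned int
    .tif_write_u32(con, if (p < length(pages)) ifd_off[p + 1] else 0)
  }
  invisible(path)
}

.sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write an ImageSeries to disk as TIFF + JSON sidecar
#'
#' Pages are ordered channel-fastest, then z, then time: page
#' `p = c + n_channels * ((z - 1) + n_z * (t - 1))` holds channel `c`,
#' slice `z`, frame `t` (all 1-based). Calibration metadata goes to a JSON
#' sidecar named after the TIFF with extension `.json`.
#'
#' @param series an `ImageSeries`.
#' @param path output TIFF path (`.tif` / `.tiff`).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "ImageSeries"))
  d <- dim(series$pixels)
  pages <- vector("list", d[1] * d[2] * d[3])
  p <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[3])) for (ch in seq_len(d[2])) {
    p <- p + 1L
    pages[[p]] <- matrix(series$pixels[t, ch, z, , ], nrow = d[4], ncol = d[5])
  }
  write_tiff_pages(pages, path)
  meta <- list(
    pixel_size_um = series$pixel_size_um,
    z_spacing_um = series$z_spacing_um,
    frame_times_s = series$frame_times_s,
    channel_names = series$channel_names,
    n_channels = d[2],
    n_z = d[3],
    bleach_frame_index = series$bleach_frame_index
  )
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an ImageSeries from a TIFF + metadata
#'
#' Calibration must come either from the JSON sidecar written by
#' [write_series()] or from the `metadata` argument; it is never silently
#' defaulted. The page count must equal
#' `n_channels * n_z * n_timepoints` exactly.
#'
#' @param path TIFF path.
#' @param metadata optional named list overriding/standing in for the
#'   sidecar: `pixel_size_um`, `n_channels`, `n_z`, and optionally
#'   `z_spacing_um`, `frame_times_s`, `channel_names`,
#'   `bleach_frame_index`.
#' @return an `ImageSeries`.
#' @export
read_series <- function(path, metadata = NULL) {
  side <- .sidecar_path(path)
  meta <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else list()
  if (!is.null(metadata)) meta[names(metadata)] <- metadata
  for (field in c("pixel_size_um", "n_channels", "n_z")) {
    if (is.null(meta[[field]])) {
      stop("missing calibration: supply '", field,
           "' via the JSON sidecar or the metadata argument")
    }
  }
  pages <- read_tiff_pages(path)
  nc <- as.integer(meta$n_channels); nz <- as.integer(meta$n_z)
  if (length(pages) %% (nc * nz) != 0) {
    stop(sprintf(
      "page count %d not divisible by channels x z = %d x %d (expected a multiple of %d)",
      length(pages), nc, nz, nc * nz))
  }
  nt <- length(pages) %/% (nc * nz)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  px <- array(0, dim = c(nt, nc, nz, h, w))
  p <- 0L
  for (t in seq_len(nt)) for (z in seq_len(nz)) for (ch in seq_len(nc)) {
    p <- p + 1L
    px[t, ch, z, , ] <- pages[[p]]
  }
  image_series(
    px,
    pixel_size_um = meta$pixel_size_um,
    z_spacing_um = if (is.null(meta$z_spacing_um)) meta$pixel_size_um else meta$z_spacing_um,
    frame_times_s = if (is.null(meta$frame_times_s)) NULL else meta$frame_times_s,
    channel_names = if (is.null(meta$channel_names)) NULL else meta$channel_names,
    bleach_frame_index = meta$bleach_frame_index
  )
}
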