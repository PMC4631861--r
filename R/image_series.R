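#' Calibrated multi-dimensional image series
#'
#' An `ImageSeries` holds a non-negative pixel array with axes
#' `(time, channel, z, y, x)` together with the physical calibration needed
#' to express measurements in micrometres: the lateral pixel size, the
#' z-spacing, and the acquisition time of every frame. Optionally the index
#' of the photobleach frame is carried along so downstream FRAP analyses can
#' split pre- and post-bleach frames without extra bookkeeping.
#'
#' Coordinate convention: continuous positions are in micrometres with the
#' origin at the centre of pixel `(0, 0)`; pixel indexing is row-major and
#' 0-based in coordinate formulas (R arrays remain 1-based internally), so
#' the centre of pixel `[i, j]` (row i, column j, 0-based) sits at
#' `(x, y) = (j, i) * pixel_size_um`.
#'
#' @param pixels numeric array with `dim` of length 5: `(t, channel, z, y, x)`.
#'   2-D, 3-D or 4-D input is promoted by prepending singleton axes in the
#'   order z, channel, time (i.e. a matrix becomes a single-frame,
#'   single-channel, single-slice series).
#' @param pixel_size_um lateral pixel size in micrometres (> 0).
#' @param z_spacing_um axial slice spacing in micrometres (> 0).
#' @param frame_times_s numeric vector of frame times in seconds, one per
#'   timepoint, strictly increasing.
#' @param channel_names character vector naming the channels.
#' @param bleach_frame_index 1-based index of the photobleach frame, or
#'   `NULL` when the series has no bleach event.
#' @return An object of class `ImageSeries`.
#' @export
image_series <- function(pixels, pixel_size_um, z_spacing_um = pixel_size_um,
                         frame_times_s = NULL, channel_names = NULL,
                         bleach_frame_index = NULL) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, nrow = 1L)
  nd <- length(dim(pixels))
  if (nd < 2L || nd > 5L) {
    stop("pixels must have between 2 (y,x) and 5 (t,c,z,y,x) dimensions")
  }
  while (length(dim(pixels)) < 5L) {
    dim(pixels) <- c(1L, dim(pixels))
  }
  d <- dim(pixels)
  if (is.null(frame_times_s)) frame_times_s <- seq_len(d[1]) - 1
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[2]))
  stopifnot(
    is.numeric(pixel_size_um), length(pixel_size_um) == 1L, pixel_size_um > 0,
    is.numeric(z_spacing_um), length(z_spacing_um) == 1L, z_spacing_um > 0
  )
  if (length(frame_times_s) != d[1]) {
    stop(sprintf("frame_times_s has length %d but the series has %d timepoints",
                 length(frame_times_s), d[1]))
  }
  if (d[1] > 1L && any(diff(frame_times_s) <= 0)) {
    stop("frame_times_s must be strictly increasing")
  }
  if (length(channel_names) != d[2]) {
    stop("channel_names length must match the channel axis")
  }
  if (!is.null(bleach_frame_index)) {
    bleach_frame_index <- as.integer(bleach_frame_index)
    if (bleach_frame_index < 1L || bleach_frame_index > d[1]) {
      stop("bleach_frame_index outside the frame range")
    }
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    stop("pixels must be non-negative and free of NA")
  }
  structure(
    list(pixels = pixels,
         pixel_size_um = pixel_size_um,
         z_spacing_um = z_spacing_um,
         frame_times_s = as.numeric(frame_times_s),
         channel_names = as.character(channel_names),
         bleach_frame_index = bleach_frame_index),
    class = "ImageSeries")
}

#' @export
print.ImageSeries <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "ImageSeries: %d t x %d ch x %d z x %d x %d px  (%.3f um/px, dz %.2f um)\n",
    d[1], d[2], d[3], d[4], d[5], x$pixel_size_um, x$z_spacing_um))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  t = %s s\n", paste(signif(x$frame_times_s, 4), collapse = ", ")))
  if (!is.null(x$bleach_frame_index)) {
    cat(sprintf("  bleach at frame %d (t = %g s)\n", x$bleach_frame_index,
                x$frame_times_s[x$bleach_frame_index]))
  }
  invisible(x)
}

#' Number of timepoints / channels / z-slices of a series
#' @param series an `ImageSeries`.
#' @return integer count.
#' @export
n_frames <- function(series) dim(series$pixels)[1]

#' @rdname n_frames
#' @export
n_channels <- function(series) dim(series$pixels)[2]

#' @rdname n_frames
#' @export
n_slices <- function(series) dim(series$pixels)[3]

#' Extract one 2-D plane as a matrix
#'
#' @param series an `ImageSeries`.
#' @param t,channel,z 1-based indices of the plane.
#' @return numeric matrix (y, x).
#' @export
get_plane <- function(series, t = 1L, channel = 1L, z = 1L) {
  series$pixels[t, channel, z, , , drop = TRUE][, , drop = TRUE]
}

#' Maximum-intensity projection along z
#'
#' Collapses the z-axis by taking, for every `(t, channel, y, x)`, the
#' maximum over all z-slices — the standard projection used before
#' quantifying spinning-disk centrosome stacks. Calibration and frame times
#' are preserved; the output has a z-axis of length 1. The operation is
#' idempotent and commutes with channel selection.
#'
#' @param series an `ImageSeries`.
#' @return an `ImageSeries` with `n_slices(.) == 1`.
#' @export
max_project <- function(series) {
  stopifnot(inherits(series, "ImageSeries"))
  d <- dim(series$pixels)
  if (d[3] == 1L) return(series)
  proj <- apply(series$pixels, c(1, 2, 4, 5), max)
  dim(proj) <- c(d[1], d[2], 1L, d[4], d[5])
  out <- series
  out$pixels <- proj
  out
}

#' Select the most central z-plane of a signal
#'
#' Operationalises "the most central z-plane" of a fluorescent body as the
#' slice with the largest summed intensity inside the analysis window; ties
#' break to the lowest slice index. When `window` is `NULL` the whole frame
#' is the window.
#'
#' @param series an `ImageSeries`.
#' @param t,channel 1-based frame and channel index used for the selection.
#' @param window optional integer vector `c(y0, y1, x0, x1)` of 1-based
#'   inclusive pixel bounds delimiting the analysis window.
#' @return list with `z` (the selected 1-based slice index) and `series`,
#'   a single-z `ImageSeries` containing that slice for all t and channels.
#' @export
central_slice <- function(series, t = 1L, channel = 1L, window = NULL) {
  stopifnot(inherits(series, "ImageSeries"))
  d <- dim(series$pixels)
  if (is.null(window)) window <- c(1L, d[4], 1L, d[5])
  window <- as.integer(window)
  if (window[1] > window[2] || window[3] > window[4] ||
      window[1] < 1L || window[2] > d[4] || window[3] < 1L || window[4] > d[5]) {
    stop("empty or out-of-bounds analysis window")
  }
  sums <- vapply(seq_len(d[3]), function(z) {
    sum(series$pixels[t, channel, z, window[1]:window[2], window[3]:window[4]])
  }, numeric(1))
  z_sel <- which.max(sums)  # which.max returns the first (lowest) maximum
  out <- series
  out$pixels <- series$pixels[, , z_sel, , , drop = FALSE]
  list(z = z_sel, series = out)
}

#' Crop a series laterally
#'
#' @param series an `ImageSeries`.
#' @param window integer vector `c(y0, y1, x0, x1)`, 1-based inclusive.
#' @return list with `series` (the cropped `ImageSeries`) and
#'   `origin_um`, the `(x, y)` position in the parent frame of the centre of
#'   the cropped region's pixel `(0, 0)`.
#' @export
crop_series <- function(series, window) {
  stopifnot(inherits(series, "ImageSeries"))
  d <- dim(series$pixels)
  window <- as.integer(window)
  if (window[1] < 1L || window[2] > d[4] || window[3] < 1L || window[4] > d[5] ||
      window[1] > window[2] || window[3] > window[4]) {
    stop("crop window out of bounds")
  }
  out <- series
  out$pixels <- series$pixels[, , , window[1]:window[2], window[3]:window[4],
                              drop = FALSE]
  list(series = out,
       origin_um = c(x = (window[3] - 1) * series$pixel_size_um,
                     y = (window[1] - 1) * series$pixel_size_um))
}
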