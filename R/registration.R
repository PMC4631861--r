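#' Detect sub-resolution beads in a single-channel image
#'
#' Finds local maxima above an adaptive threshold (robust background plus
#' `n_sigma` robust SDs), refines each by an intensity-weighted centroid in
#' a fixed window, and returns positions in micrometres. Detections whose
#' peaks lie closer together than `merge_radius_um` are ambiguous for
#' matching and are dropped (counted in the `n_merged` attribute), as are
#' peaks whose refinement window would be clipped by the image border.
#'
#' @param image numeric matrix (y, x), typically a max projection.
#' @param pixel_size_um pixel size, um.
#' @param n_sigma detection threshold in robust SDs above the median.
#' @param window_radius_px centroid refinement window half-width, pixels.
#' @param merge_radius_um minimum allowed peak separation, um.
#' @param centroid_frac fraction of the background-subtracted peak height
#'   used as the centroiding cutoff; weights are the cutoff-subtracted
#'   positive intensities (standard thresholded centre of mass, unbiased
#'   for symmetric spots).
#' @return data.frame with columns `x_um`, `y_um`, `peak`; attribute
#'   `n_merged` counts detections dropped by the merge rule. Zero rows for
#'   a blank image.
#' @export
detect_beads <- function(image, pixel_size_um, n_sigma = 6,
                         window_radius_px = 3L, merge_radius_um = 0.5,
                         centroid_frac = 0.2) {
  stopifnot(is.matrix(image), pixel_size_um > 0)
  bg <- stats::median(image)
  spread <- stats::mad(image)
  if (spread == 0) spread <- stats::sd(image)
  if (is.na(spread) || spread == 0) spread <- 1e-12
  thr <- bg + n_sigma * spread
  ny <- nrow(image); nx <- ncol(image)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0), peak = numeric(0))
  attr(empty, "n_merged") <- 0L
  if (ny < 3L || nx < 3L) return(empty)
  # 3x3 local maximum via shifted comparisons (strict on the trailing side
  # so plateaus yield a single detection)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- image
  ge <- function(di, dj) image >= pad[2:(ny + 1L) + di, 2:(nx + 1L) + dj]
  gt <- function(di, dj) image > pad[2:(ny + 1L) + di, 2:(nx + 1L) + dj]
  is_max <- gt(-1, -1) & gt(-1, 0) & gt(-1, 1) & gt(0, -1) &
    ge(0, 1) & ge(1, -1) & ge(1, 0) & ge(1, 1) & (image > thr)
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  # merge rule: drop all members of any too-close pair
  keep <- rep(TRUE, nrow(cand))
  if (nrow(cand) > 1L) {
    dmat <- as.matrix(stats::dist(cand)) * pixel_size_um
    diag(dmat) <- Inf
    keep <- apply(dmat, 1, min) >= merge_radius_um
  }
  n_merged <- sum(!keep)
  cand <- cand[keep, , drop = FALSE]
  r <- as.integer(window_radius_px)
  out <- lapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (i - r < 1L || i + r > ny || j - r < 1L || j + r > nx) return(NULL)
    win <- image[(i - r):(i + r), (j - r):(j + r)]
    cutoff <- bg + centroid_frac * (win[r + 1L, r + 1L] - bg)
    w <- pmax(win - cutoff, 0)
    tot <- sum(w)
    if (tot <= 0) return(NULL)
    rows <- (i - r):(i + r) - 1L  # 0-based pixel indices
    cols <- (j - r):(j + r) - 1L
    cy <- sum(rowSums(w) * rows) / tot
    cx <- sum(colSums(w) * cols) / tot
    c(cx * pixel_size_um, cy * pixel_size_um, image[i, j])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  res <- data.frame(x_um = out[, 1], y_um = out[, 2], peak = out[, 3])
  attr(res, "n_merged") <- n_merged
  res
}

#' Match green and red bead detections
#'
#' Pairs detections by mutual nearest neighbour within `max_radius_um`:
#' a green and a red bead are matched only if each is the other's nearest
#' neighbour and their distance is below the radius. Unmatched detections
#' are discarded and counted. Mutual matching avoids the chaining errors a
#' greedy one-way assignment can make in dense fields.
#'
#' @param green_positions,red_positions n x 2 matrices or data.frames with
#'   columns `x_um`, `y_um` (or plain 2-column numeric).
#' @param max_radius_um maximum pairing distance, um.
#' @return data.frame with columns `gx_um`, `gy_um`, `rx_um`, `ry_um`,
#'   `dx_um`, `dy_um`, `dist_um` (red minus green); attributes
#'   `n_unmatched_green`, `n_unmatched_red`.
#' @export
match_beads <- function(green_positions, red_positions, max_radius_um = 0.3) {
  stopifnot(max_radius_um > 0)
  as_xy <- function(p) {
    if (is.data.frame(p)) p <- as.matrix(p[, c("x_um", "y_um")])
    matrix(as.numeric(p), ncol = 2)
  }
  g <- as_xy(green_positions); r <- as_xy(red_positions)
  empty <- data.frame(gx_um = numeric(0), gy_um = numeric(0),
                      rx_um = numeric(0), ry_um = numeric(0),
                      dx_um = numeric(0), dy_um = numeric(0),
                      dist_um = numeric(0))
  if (nrow(g) == 0L || nrow(r) == 0L) {
    attr(empty, "n_unmatched_green") <- nrow(g)
    attr(empty, "n_unmatched_red") <- nrow(r)
    return(empty)
  }
  d2 <- outer(g[, 1], r[, 1], "-")^2 + outer(g[, 2], r[, 2], "-")^2
  nn_of_g <- apply(d2, 1, which.min)
  nn_of_r <- apply(d2, 2, which.min)
  gi <- seq_len(nrow(g))
  mutual <- nn_of_r[nn_of_g] == gi
  dist <- sqrt(d2[cbind(gi, nn_of_g)])
  sel <- mutual & dist <= max_radius_um
  pairs <- data.frame(
    gx_um = g[sel, 1], gy_um = g[sel, 2],
    rx_um = r[nn_of_g[sel], 1], ry_um = r[nn_of_g[sel], 2]
  )
  pairs$dx_um <- pairs$rx_um - pairs$gx_um
  pairs$dy_um <- pairs$ry_um - pairs$gy_um
  pairs$dist_um <- sqrt(pairs$dx_um^2 + pairs$dy_um^2)
  attr(pairs, "n_unmatched_green") <- nrow(g) - nrow(pairs)
  attr(pairs, "n_unmatched_red") <- nrow(r) - nrow(pairs)
  pairs
}

#' Estimate the systematic channel shift from matched bead pairs
#'
#' Pools matched pairs from one or more calibration images with equal
#' weight and averages the red-minus-green displacement VECTOR (a scalar
#' mean of distances cannot correct direction; the reported magnitude is
#' the norm of the mean vector). Spread is summarised both as the SD and
#' the standard error of the per-bead displacement magnitudes.
#'
#' @param pairs a pair table from [match_beads()], or a list of such tables
#'   (one per calibration image).
#' @return object of class `RegistrationModel`: list with `shift_um`
#'   (named `(x, y)` mean red-minus-green vector), `shift_magnitude_um`,
#'   `se_um` (SE of per-bead magnitudes; `NA` for a single pair), `sd_um`,
#'   `n_beads`, `n_images`.
#' @export
estimate_channel_shift <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- list(pairs)
  n_images <- length(pairs)
  all_pairs <- do.call(rbind, pairs)
  if (is.null(all_pairs) || nrow(all_pairs) == 0L) {
    stop("no matched bead pairs: cannot estimate a channel shift")
  }
  shift <- c(x = mean(all_pairs$dx_um), y = mean(all_pairs$dy_um))
  n <- nrow(all_pairs)
  sd_mag <- if (n > 1L) stats::sd(all_pairs$dist_um) else NA_real_
  structure(
    list(shift_um = shift,
         shift_magnitude_um = sqrt(sum(shift^2)),
         se_um = if (n > 1L) sd_mag / sqrt(n) else NA_real_,
         sd_um = sd_mag,
         n_beads = n,
         n_images = n_images),
    class = "RegistrationModel")
}

#' @export
print.RegistrationModel <- function(x, ...) {
  cat(sprintf(
    "RegistrationModel: shift (%.4f, %.4f) um, |shift| = %.4f um\n",
    x$shift_um[1], x$shift_um[2], x$shift_magnitude_um))
  cat(sprintf("  %d beads from %d image(s); magnitude sd %.4f um, se %.4f um\n",
              x$n_beads, x$n_images, x$sd_um, x$se_um))
  invisible(x)
}

#' Apply a registration model to a red-channel position
#'
#' Pure function: returns `position_red - shift_um`, mapping a red-channel
#' coordinate into the green channel's frame.
#'
#' @param position_red numeric `(x, y)` in um.
#' @param model a `RegistrationModel`.
#' @return corrected `(x, y)` position, um.
#' @export
apply_registration <- function(position_red, model) {
  stopifnot(inherits(model, "RegistrationModel"), length(position_red) == 2L)
  as.numeric(position_red) - as.numeric(model$shift_um)
}

#' Save / load a RegistrationModel as JSON
#' @param model a `RegistrationModel`.
#' @param path JSON path.
#' @return `path` invisibly (write); the model (read).
#' @export
write_registration <- function(model, path) {
  stopifnot(inherits(model, "RegistrationModel"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_registration
#' @export
read_registration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$shift_um <- stats::setNames(as.numeric(x$shift_um), c("x", "y"))
  structure(x, class = "RegistrationModel")
}

#' Full bead-field calibration: detect, match, estimate
#'
#' Convenience wrapper running the calibration chain over one or more
#' two-channel bead `ImageSeries` (green = channel 1, red = channel 2):
#' max-project each stack, detect beads per channel, match mutually-nearest
#' pairs, and pool everything into one [estimate_channel_shift()] model.
#'
#' @param series_list an `ImageSeries` or list of them.
#' @param max_radius_um matching radius, um.
#' @param ... passed to [detect_beads()].
#' @return list with `model` (the `RegistrationModel`) and `pairs`
#'   (per-image list of matched pair tables).
#' @export
calibrate_channels <- function(series_list, max_radius_um = 0.3, ...) {
  if (inherits(series_list, "ImageSeries")) series_list <- list(series_list)
  pair_tables <- lapply(series_list, function(s) {
    proj <- max_project(s)
    g <- detect_beads(get_plane(proj, 1L, 1L, 1L), s$pixel_size_um, ...)
    r <- detect_beads(get_plane(proj, 1L, 2L, 1L), s$pixel_size_um, ...)
    match_beads(g, r, max_radius_um = max_radius_um)
  })
  list(model = estimate_channel_shift(pair_tables), pairs = pair_tables)
}
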