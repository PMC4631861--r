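#' Upscale an image by an integer factor
#'
#' Scales the image up `factor`-fold so each pixel is divided into
#' `factor x factor` sub-pixels, the standard preprocessing before
#' sub-pixel centre-of-mass measurement (a fivefold upscale turns
#' 0.105 um pixels into 0.021 um pixels). Interpolation is bilinear by
#' default; `"nearest"` replication is available for oracle tests. Output
#' pixel centres map to input coordinates via
#' `x_in = (u + 0.5) / factor - 0.5` (0-based), clamped at the borders, so
#' geometry is preserved: a feature at input pixel coordinate `p` sits at
#' output coordinate `(p + 0.5) * factor - 0.5`.
#'
#' @param image numeric matrix (y, x).
#' @param factor integer >= 1.
#' @param method `"bilinear"` or `"nearest"`.
#' @return numeric matrix of size `factor * dim(image)`.
#' @export
upscale <- function(image, factor, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (length(factor) != 1L || factor < 1 || factor != round(factor)) {
    stop("factor must be a single integer >= 1")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  ny <- nrow(image); nx <- ncol(image)
  src <- function(n) {
    u <- seq_len(n * factor) - 1L
    pmin(pmax((u + 0.5) / factor - 0.5, 0), n - 1L)
  }
  yy <- src(ny); xx <- src(nx)
  if (method == "nearest") {
    return(image[round(yy) + 1L, round(xx) + 1L, drop = FALSE])
  }
  y0 <- pmin(floor(yy), ny - 2L); x0 <- pmin(floor(xx), nx - 2L)
  fy <- yy - y0; fx <- xx - x0
  a <- image[y0 + 1L, x0 + 1L, drop = FALSE]
  b <- image[y0 + 1L, x0 + 2L, drop = FALSE]
  cc <- image[y0 + 2L, x0 + 1L, drop = FALSE]
  d <- image[y0 + 2L, x0 + 2L, drop = FALSE]
  wy <- matrix(fy, length(yy), length(xx))
  wx <- matrix(fx, length(yy), length(xx), byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + cc * wy * (1 - wx) + d * wy * wx
}

#' Threshold rule for centre-of-mass measurement
#'
#' The measurement thresholds the window and takes the intensity-weighted
#' mean position of the surviving pixels. The default rule is "half-max":
#' background plus `fraction` of the background-subtracted window maximum,
#' with the background estimated as the mean of the dimmest
#' `background_quantile` of window pixels — deterministic, scale-free, and
#' robust for unimodal spots.
#'
#' @param fraction fraction of the background-subtracted peak, in (0, 1).
#' @param background_quantile lower quantile of window pixels averaged as
#'   the background estimate.
#' @param background optional fixed background level overriding the
#'   quantile estimate.
#' @return object of class `threshold_rule`.
#' @export
threshold_rule <- function(fraction = 0.5, background_quantile = 0.25,
                           background = NULL) {
  stopifnot(fraction > 0, fraction < 1,
            background_quantile > 0, background_quantile <= 1)
  structure(list(fraction = fraction,
                 background_quantile = background_quantile,
                 background = background),
            class = "threshold_rule")
}

.resolve_threshold <- function(image, rule) {
  bg <- rule$background
  if (is.null(bg)) {
    q <- stats::quantile(image, rule$background_quantile, names = FALSE)
    bg <- mean(image[image <= q])
  }
  list(background = bg, threshold = bg + rule$fraction * (max(image) - bg))
}

#' Intensity-weighted centroid of a thresholded window
#'
#' Computes the centre of mass of all pixels above the threshold, weighted
#' by their background-subtracted intensity — the "analyze particles"
#' centre-of-mass measurement. Coordinates are micrometres in the window's
#' own frame (origin at the centre of window pixel `(0, 0)`).
#'
#' @param image_window numeric matrix (y, x).
#' @param pixel_size_um pixel size of the window, um (pass the upscaled
#'   pixel size when the window has been upscaled).
#' @param rule a [threshold_rule()].
#' @param z_index 1-based z index recorded in the result (bookkeeping).
#' @return object of class `CentroidResult`: list with `position_um`
#'   (named `(x, y)`), `threshold_used`, `background_used`,
#'   `n_pixels_above`, `z_index`.
#' @export
compute_centroid <- function(image_window, pixel_size_um,
                             rule = threshold_rule(), z_index = 1L) {
  stopifnot(is.matrix(image_window), pixel_size_um > 0,
            inherits(rule, "threshold_rule"))
  th <- .resolve_threshold(image_window, rule)
  above <- image_window > th$threshold
  n_above <- sum(above)
  if (n_above == 0L) {
    if (max(image_window) <= th$background) {
      stop("empty signal: window contains nothing above background")
    }
    stop("no pixels above threshold (threshold rule too strict for this window)")
  }
  w <- ifelse(above, image_window - th$background, 0)
  w <- pmax(w, 0)
  tot <- sum(w)
  if (tot <= 0) stop("degenerate weights: nothing above background survives thresholding")
  rows <- seq_len(nrow(image_window)) - 1L
  cols <- seq_len(ncol(image_window)) - 1L
  cy <- sum(rowSums(w) * rows) / tot
  cx <- sum(colSums(w) * cols) / tot
  structure(
    list(position_um = c(x = cx * pixel_size_um, y = cy * pixel_size_um),
         threshold_used = th$threshold,
         background_used = th$background,
         n_pixels_above = as.integer(n_above),
         z_index = as.integer(z_index)),
    class = "CentroidResult")
}

.nearest_postbleach_frame <- function(series, t_query_s) {
  if (is.null(series$bleach_frame_index)) {
    stop("series has no bleach_frame_index; cannot locate post-bleach frames")
  }
  post <- which(seq_along(series$frame_times_s) > series$bleach_frame_index)
  if (length(post) == 0L) stop("series has no post-bleach frames")
  post[which.min(abs(series$frame_times_s[post] - t_query_s))]
}

# Localise one channel of one frame: crop the window, pick the most central
# z-slice (largest in-window sum), upscale, and take the thresholded
# centre of mass. Returns global um coordinates.
.localise_channel <- function(series, channel, frame, window, upscale_factor,
                              rule) {
  cropped <- crop_series(series, window)
  zsel <- central_slice(cropped$series, t = frame, channel = channel)
  plane <- get_plane(zsel$series, t = frame, channel = channel, z = 1L)
  up <- upscale(plane, upscale_factor)
  up_px <- series$pixel_size_um / upscale_factor
  cen <- compute_centroid(up, up_px, rule = rule, z_index = zsel$z)
  # map upscaled-window coordinates back to the parent frame:
  # u_um = (p_orig + 0.5) * f - 0.5 sub-pixels  =>  invert and add origin
  pos_in_window_px <- cen$position_um / up_px          # upscaled px, 0-based
  pos_orig_px <- (pos_in_window_px + 0.5) / upscale_factor - 0.5
  cen$position_um <- cropped$origin_um + pos_orig_px * series$pixel_size_um
  names(cen$position_um) <- c("x", "y")
  cen
}

#' Measure the corrected green-red offset of one centrosome
#'
#' Implements the two-colour offset measurement: at the post-bleach frame
#' nearest `t_query_s`, each channel's recovering signal is localised
#' independently (most central z-slice in the window, `upscale_factor`-fold
#' upscaling, thresholded centre of mass); the red position is corrected by
#' the bead registration model; and the displacement is expressed with the
#' red signal at the origin.
#'
#' @param series a 2-channel `ImageSeries` (green = channel 1,
#'   red = channel 2) with `bleach_frame_index` set.
#' @param window integer `c(y0, y1, x0, x1)` 1-based pixel bounds of the
#'   centrosome analysis window.
#' @param t_query_s requested post-bleach time, seconds; the nearest
#'   post-bleach frame is used and recorded.
#' @param model a `RegistrationModel` (use a zero-shift model to measure
#'   uncorrected offsets).
#' @param upscale_factor integer upscaling factor (default 5).
#' @param rule a [threshold_rule()].
#' @return object of class `OffsetMeasurement`: list with `green_centroid`,
#'   `red_centroid_corrected` (both `CentroidResult`, the red one after
#'   correction), `displacement_um` (green minus corrected red, i.e. green
#'   position with red at the origin), `distance_um`, `timepoint_s`,
#'   `frame`.
#' @export
measure_pair_offset <- function(series, window, t_query_s, model,
                                upscale_factor = 5L,
                                rule = threshold_rule()) {
  stopifnot(inherits(series, "ImageSeries"), n_channels(series) >= 2L,
            inherits(model, "RegistrationModel"))
  frame <- .nearest_postbleach_frame(series, t_query_s)
  green <- tryCatch(
    .localise_channel(series, 1L, frame, window, upscale_factor, rule),
    error = function(e) stop("green channel: ", conditionMessage(e)))
  red <- tryCatch(
    .localise_channel(series, 2L, frame, window, upscale_factor, rule),
    error = function(e) stop("red channel: ", conditionMessage(e)))
  red$position_um <- stats::setNames(apply_registration(red$position_um, model),
                                     c("x", "y"))
  disp <- green$position_um - red$position_um
  structure(
    list(green_centroid = green,
         red_centroid_corrected = red,
         displacement_um = disp,
         distance_um = sqrt(sum(disp^2)),
         timepoint_s = series$frame_times_s[frame],
         frame = frame),
    class = "OffsetMeasurement")
}

#' Summarise a set of offset measurements
#'
#' Produces the per-centrosome displacement table (red signal at the
#' origin, one dot per centrosome as in a relative-position scatter) and
#' summary statistics of the centre-to-centre distances.
#'
#' @param measurements list of `OffsetMeasurement` objects.
#' @return list with `mean_distance_um`, `median_distance_um`,
#'   `sd_distance_um`, `n`, and `table` — a data.frame with columns `id`,
#'   `dx_um`, `dy_um`, `distance_um`, `t_s`.
#' @export
aggregate_offsets <- function(measurements) {
  if (inherits(measurements, "OffsetMeasurement")) {
    measurements <- list(measurements)
  }
  if (length(measurements) == 0L) stop("no offset measurements to aggregate")
  stopifnot(all(vapply(measurements, inherits, logical(1), "OffsetMeasurement")))
  tab <- data.frame(
    id = seq_along(measurements),
    dx_um = vapply(measurements, function(m) m$displacement_um[["x"]], numeric(1)),
    dy_um = vapply(measurements, function(m) m$displacement_um[["y"]], numeric(1)),
    distance_um = vapply(measurements, function(m) m$distance_um, numeric(1)),
    t_s = vapply(measurements, function(m) m$timepoint_s, numeric(1))
  )
  list(mean_distance_um = mean(tab$distance_um),
       median_distance_um = stats::median(tab$distance_um),
       sd_distance_um = if (nrow(tab) > 1L) stats::sd(tab$distance_um) else NA_real_,
       n = nrow(tab),
       table = tab)
}
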