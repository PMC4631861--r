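#' Radial intensity profile about a centre
#'
#' Averages pixel intensity over concentric rings: ring `k` collects the
#' pixels whose centre-to-centre radius falls in
#' `[k * spacing, (k + 1) * spacing)`, and the profile reports the mean
#' intensity per ring against the radius `k * spacing` (ring 0 is the
#' central disc, labelled r = 0, so the mirrored display counts it once).
#' Defaults follow the
#' standard centrosome profiling recipe — 0.028 um rings spanning 3.02 um
#' (108 rings) — which assumes the image has been upscaled so pixels are
#' finer than the ring spacing. Rings containing no pixel (e.g. beyond the
#' image corner) are reported as `NA`, never zero.
#'
#' @param image numeric matrix (y, x).
#' @param center_um `(x, y)` profile centre, um, inside the image.
#' @param pixel_size_um pixel size, um.
#' @param spacing_um ring width, um.
#' @param extent_um total radial extent, um.
#' @return object of class `RadialProfile`: list with `radii_um` (ring
#'   centres), `mean_intensity`, `n_pixels` per ring, `spacing_um`, flags
#'   `background_subtracted`, `normalised`, and (after
#'   [finalize_profile()]) `mirrored_axis_um` / `mirrored_intensity`.
#' @export
radial_profile <- function(image, center_um, pixel_size_um,
                           spacing_um = 0.028, extent_um = 3.02) {
  stopifnot(is.matrix(image), length(center_um) == 2L,
            pixel_size_um > 0, spacing_um > 0, extent_um > spacing_um)
  ext <- (c(ncol(image), nrow(image)) - 1) * pixel_size_um
  if (any(center_um < 0) || center_um[1] > ext[1] || center_um[2] > ext[2]) {
    stop("profile centre outside the image")
  }
  n_rings <- ceiling(extent_um / spacing_um)
  x <- (seq_len(ncol(image)) - 1L) * pixel_size_um - center_um[1]
  y <- (seq_len(nrow(image)) - 1L) * pixel_size_um - center_um[2]
  r <- sqrt(outer(y^2, x^2, "+"))
  ring <- floor(r / spacing_um)                 # 0-based ring index
  sel <- ring < n_rings
  idx <- factor(ring[sel], levels = 0:(n_rings - 1L))
  sums <- tapply(image[sel], idx, sum)
  cnts <- tapply(rep(1, sum(sel)), idx, sum)
  cnts[is.na(cnts)] <- 0
  means <- as.numeric(sums) / ifelse(cnts > 0, as.numeric(cnts), NA)
  structure(
    list(radii_um = (0:(n_rings - 1L)) * spacing_um,
         mean_intensity = as.numeric(means),
         n_pixels = as.integer(cnts),
         spacing_um = spacing_um,
         background_subtracted = FALSE,
         normalised = FALSE),
    class = "RadialProfile")
}

#' Background-subtract, peak-normalise and mirror a radial profile
#'
#' Subtracts the average cytosolic background from every ring, rescales so
#' the peak ring intensity equals exactly 1, and reflects the one-sided
#' profile about r = 0 to produce the symmetric display profile (the
#' negative side is the mirror image of the positive side, not an
#' independent measurement).
#'
#' @param profile a `RadialProfile`.
#' @param cytosolic_background background level to subtract (>= 0), e.g.
#'   from [cytosolic_background()].
#' @return the finalized `RadialProfile` with `background_subtracted` and
#'   `normalised` set, plus `mirrored_axis_um` (signed radii) and
#'   `mirrored_intensity`.
#' @export
finalize_profile <- function(profile, cytosolic_background = 0) {
  stopifnot(inherits(profile, "RadialProfile"), cytosolic_background >= 0)
  v <- profile$mean_intensity - cytosolic_background
  peak <- max(v, na.rm = TRUE)
  if (!is.finite(peak) || peak <= 0) {
    stop("no peak to normalise: profile is empty after background subtraction")
  }
  v <- v / peak
  profile$mean_intensity <- v
  profile$background_subtracted <- TRUE
  profile$normalised <- TRUE
  # reflect about r = 0 with the central ring counted once
  profile$mirrored_axis_um <- c(-rev(profile$radii_um[-1]), profile$radii_um)
  profile$mirrored_intensity <- c(rev(v[-1]), v)
  profile
}

#' Estimate the average cytosolic background around a centrosome
#'
#' Mean intensity in an annulus around the centrosome centre, far enough
#' out to be clear of the PCM but still local. Pixels under `exclude_mask`
#' (e.g. other centrosomes) are ignored.
#'
#' @param image numeric matrix.
#' @param center_um `(x, y)` centre, um.
#' @param pixel_size_um pixel size, um.
#' @param r_inner_um,r_outer_um annulus radii, um.
#' @param exclude_mask optional logical matrix of pixels to ignore.
#' @return scalar mean background.
#' @export
cytosolic_background <- function(image, center_um, pixel_size_um,
                                 r_inner_um = 1.8, r_outer_um = 2.4,
                                 exclude_mask = NULL) {
  stopifnot(is.matrix(image), r_outer_um > r_inner_um, r_inner_um > 0)
  x <- (seq_len(ncol(image)) - 1L) * pixel_size_um - center_um[1]
  y <- (seq_len(nrow(image)) - 1L) * pixel_size_um - center_um[2]
  r <- sqrt(outer(y^2, x^2, "+"))
  sel <- r >= r_inner_um & r < r_outer_um
  if (!is.null(exclude_mask)) sel <- sel & !exclude_mask
  if (!any(sel)) stop("background annulus contains no usable pixels")
  mean(image[sel])
}

#' Average profiles per channel and offset the red axis
#'
#' Averages ring-by-ring across centrosomes within each channel (a sound
#' average needs a reasonable sample; fewer than `min_n` profiles per
#' channel is an error) and returns the paired display profile in which the
#' red profile's axis is shifted by the previously measured mean
#' green-red offset, so the two channels sit at their true relative
#' positions on a shared axis.
#'
#' @param green_profiles,red_profiles lists of finalized `RadialProfile`s
#'   on identical ring grids.
#' @param mean_offset_um scalar mean green-red centre distance, um; the
#'   red axis is shifted by this amount.
#' @param min_n minimum profiles per channel (default 10).
#' @return list with `axis_um` (green/shared mirrored axis), `green_mean`,
#'   `red_mean` (mean mirrored intensities), `red_axis_um` (the red
#'   channel's shifted axis), `n_green`, `n_red`, `mean_offset_um`.
#' @export
average_and_offset_profiles <- function(green_profiles, red_profiles,
                                        mean_offset_um, min_n = 10L) {
  as_list <- function(p) if (inherits(p, "RadialProfile")) list(p) else p
  green_profiles <- as_list(green_profiles); red_profiles <- as_list(red_profiles)
  if (length(green_profiles) < min_n || length(red_profiles) < min_n) {
    stop(sprintf("need at least %d profiles per channel (got %d green, %d red)",
                 min_n, length(green_profiles), length(red_profiles)))
  }
  ref <- green_profiles[[1]]
  check <- function(p) {
    if (length(p$radii_um) != length(ref$radii_um) ||
        any(abs(p$radii_um - ref$radii_um) > 1e-9)) {
      stop("mismatched ring grids: all profiles must share radii")
    }
    if (is.null(p$mirrored_intensity)) {
      stop("profiles must be finalized (mirrored) before averaging")
    }
  }
  invisible(lapply(c(green_profiles, red_profiles), check))
  avg <- function(ps) {
    rowMeans(do.call(cbind, lapply(ps, `[[`, "mirrored_intensity")))
  }
  list(axis_um = ref$mirrored_axis_um,
       green_mean = avg(green_profiles),
       red_mean = avg(red_profiles),
       red_axis_um = ref$mirrored_axis_um + mean_offset_um,
       n_green = length(green_profiles),
       n_red = length(red_profiles),
       mean_offset_um = mean_offset_um)
}

#' Reference-channel ROI for recovery measurement
#'
#' Masks every pixel of the reference image whose value exceeds the image
#' mean by more than `n_sd` standard deviations — the rule used to outline
#' the centriolar reference signal (typically a ~10 x 10 px, ~1 um square
#' region for realistic scenes). The statistic is computed on the image as
#' given; pass a maximum-intensity projection of the pre-bleach reference
#' frame for the standard behaviour.
#'
#' @param red_reference_image numeric matrix.
#' @param n_sd threshold in SDs above the mean (default 2).
#' @return logical matrix mask.
#' @export
recovery_roi <- function(red_reference_image, n_sd = 2) {
  stopifnot(is.matrix(red_reference_image), length(red_reference_image) > 0)
  mu <- mean(red_reference_image)
  s <- stats::sd(red_reference_image)
  mask <- red_reference_image > mu + n_sd * s
  if (!any(mask)) {
    stop("no reference signal: no pixel exceeds mean + ", n_sd, " SD")
  }
  mask
}

#' FRAP recovery curve from a masked ROI
#'
#' For every timepoint and channel, sums the (max-projected) intensity over
#' the ROI mask, subtracts the local cytoplasmic background (per-pixel mean
#' of the background region times the ROI size), and normalises by the mean
#' pre-bleach value of that channel, so pre-bleach values average 1.
#'
#' @param series a 2-channel `ImageSeries` with `bleach_frame_index` set.
#' @param mask logical ROI matrix matching the frame size.
#' @param background_region logical matrix of background pixels, or a
#'   per-channel numeric vector of per-pixel background levels.
#' @return object of class `RecoveryCurve`: list with `times_s`,
#'   `green_norm`, `red_norm`, `roi_n_pixels`, `pre_bleach_values`
#'   (per-channel mean raw pre-bleach ROI sums), `bleach_frame_index`.
#' @export
recovery_curve <- function(series, mask, background_region) {
  stopifnot(inherits(series, "ImageSeries"), n_channels(series) >= 2L,
            is.logical(mask))
  if (is.null(series$bleach_frame_index)) {
    stop("series has no bleach_frame_index")
  }
  pre <- seq_len(series$bleach_frame_index - 1L)
  if (length(pre) == 0L) stop("series has no pre-bleach frames")
  if (!any(mask)) stop("empty ROI mask")
  proj <- max_project(series)
  d <- dim(proj$pixels)
  if (!all(dim(mask) == d[4:5])) stop("mask dimensions do not match the frame")
  n_roi <- sum(mask)
  roi_sum <- function(t, ch) {
    plane <- matrix(proj$pixels[t, ch, 1, , ], d[4], d[5])
    s <- sum(plane[mask])
    bg <- if (is.logical(background_region)) {
      mean(plane[background_region])
    } else {
      background_region[ch]
    }
    s - bg * n_roi
  }
  raw <- vapply(seq_len(d[1]), function(t) {
    c(roi_sum(t, 1L), roi_sum(t, 2L))
  }, numeric(2))
  pre_mean <- rowMeans(raw[, pre, drop = FALSE])
  if (any(pre_mean <= 0)) {
    stop("pre-bleach mean <= 0: cannot normalise (check background region)")
  }
  structure(
    list(times_s = series$frame_times_s,
         green_norm = raw[1, ] / pre_mean[1],
         red_norm = raw[2, ] / pre_mean[2],
         roi_n_pixels = as.integer(n_roi),
         pre_bleach_values = stats::setNames(pre_mean, c("green", "red")),
         bleach_frame_index = series$bleach_frame_index),
    class = "RecoveryCurve")
}

#' Average recovery curves across centrosomes
#'
#' @param curves list of `RecoveryCurve`s on identical time grids.
#' @return a `RecoveryCurve` whose normalised values are the per-timepoint
#'   means across curves.
#' @export
average_recovery_curves <- function(curves) {
  if (inherits(curves, "RecoveryCurve")) return(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "RecoveryCurve")))
  ref <- curves[[1]]
  for (cv in curves) {
    if (length(cv$times_s) != length(ref$times_s) ||
        any(abs(cv$times_s - ref$times_s) > 1e-9)) {
      stop("mismatched time grids")
    }
  }
  ref$green_norm <- rowMeans(do.call(cbind, lapply(curves, `[[`, "green_norm")))
  ref$red_norm <- rowMeans(do.call(cbind, lapply(curves, `[[`, "red_norm")))
  ref$roi_n_pixels <- as.integer(round(mean(
    vapply(curves, `[[`, integer(1), "roi_n_pixels"))))
  ref
}
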