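# End-to-end simulation experiments: these wire the generator to the
# measurement chain exactly the way a real calibration + FRAP session would
# be analysed, and are what the parameter-recovery validations run.

#' Logical annulus mask around a centre
#'
#' @param dim_px integer `(ny, nx)`.
#' @param center_um `(x, y)` centre, um.
#' @param pixel_size_um pixel size, um.
#' @param r_inner_um,r_outer_um annulus radii, um.
#' @return logical matrix.
#' @export
annulus_mask <- function(dim_px, center_um, pixel_size_um,
                         r_inner_um = 1.8, r_outer_um = 2.4) {
  x <- (seq_len(dim_px[2]) - 1L) * pixel_size_um - center_um[1]
  y <- (seq_len(dim_px[1]) - 1L) * pixel_size_um - center_um[2]
  r <- sqrt(outer(y^2, x^2, "+"))
  r >= r_inner_um & r < r_outer_um
}

# Derive per-replicate sub-seeds from one master seed, kept within the
# 32-bit integer range R requires.
.sub_seeds <- function(seed, n) {
  .with_scene_rng(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate a full bead-field channel calibration
#'
#' Generates `n_images` two-channel bead fields sharing one systematic
#' red-minus-green shift, runs detection and mutual-nearest matching on
#' each, and pools all pairs into a single registration model — the
#' standard multi-image TetraSpeck calibration (defaults: 12 images
#' totalling 977 beads, shift magnitude 0.058 um, per-bead jitter
#' 0.03 um).
#'
#' @param true_shift_um `(dx, dy)` systematic shift, um.
#' @param n_images number of calibration images.
#' @param beads_per_image integer vector (recycled) of beads per image;
#'   the default spreads 977 beads over 12 images.
#' @param jitter_sd_um per-bead localisation jitter sd, um.
#' @param seed master seed.
#' @param image_shape_px field size (pixels).
#' @param noise logical: apply shot + read noise.
#' @return list with `model` (`RegistrationModel`), `pairs`,
#'   `true_shift_um`.
#' @export
simulate_bead_calibration <- function(true_shift_um = c(0.058, 0),
                                      n_images = 12L,
                                      beads_per_image = NULL,
                                      jitter_sd_um = 0.03,
                                      seed = 1L,
                                      image_shape_px = c(128L, 128L),
                                      noise = TRUE) {
  if (is.null(beads_per_image)) {
    base <- 977L %/% n_images
    extra <- 977L %% n_images
    beads_per_image <- rep(base, n_images) + c(rep(1L, extra),
                                               rep(0L, n_images - extra))
  } else {
    beads_per_image <- rep_len(as.integer(beads_per_image), n_images)
  }
  seeds <- .sub_seeds(seed, n_images)
  series_list <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    spec <- scene_spec(image_shape_px = image_shape_px, n_z = 1L,
                       shot_noise = noise,
                       read_noise_sd = if (noise) 2 else 0,
                       background_level = if (noise) 10 else 0,
                       rng_seed = seeds[i])
    pos <- .with_scene_rng(seeds[i] + 1L, place_beads(beads_per_image[i], spec))
    truth <- bead_field_truth(pos, true_shift_um = true_shift_um,
                              per_bead_jitter_sd_um = jitter_sd_um,
                              min_separation_um = 4 * spec$psf_sigma_um)
    series_list[[i]] <- generate_bead_field(spec, truth)$series
  }
  cal <- calibrate_channels(series_list)
  list(model = cal$model, pairs = cal$pairs, true_shift_um = true_shift_um)
}

# Default acquisition for a simulated centrosome FRAP series: two pre-bleach
# frames, bleach at t = 0, post-bleach frames through 90 s.
.frap_spec <- function(seed, camera_shift_um = c(0, 0),
                       frame_times_s = c(-20, -10, 0, 15, 30, 45, 60, 75, 90),
                       image_shape_px = c(48L, 48L), n_z = 5L) {
  scene_spec(image_shape_px = image_shape_px, n_z = n_z,
             frame_times_s = frame_times_s,
             bleach_frame_index = which(frame_times_s == 0),
             camera_shift_um = camera_shift_um,
             rng_seed = seed)
}

#' Simulate and measure a two-colour offset experiment
#'
#' Generates `n_series` centrosome FRAP series whose true green-red offset
#' has magnitude `offset_um` (random direction per replicate), applies the
#' supplied (or freshly simulated) bead registration model, measures each
#' offset at `t_query_s` with the full chain — central z-slice,
#' `upscale_factor`-fold upscaling, thresholded centre of mass, channel
#' correction — and aggregates.
#'
#' @param offset_um true offset magnitude, um.
#' @param n_series number of replicate centrosomes.
#' @param seed master seed.
#' @param model `RegistrationModel`; when `NULL` an identity (zero-shift)
#'   model is used together with zero camera shift.
#' @param camera_shift_um microscope misalignment applied to the red
#'   channel of every simulated series (should equal the truth the model
#'   was calibrated on).
#' @param t_query_s query time, s post-bleach.
#' @param upscale_factor upscaling factor for centroiding.
#' @return the [aggregate_offsets()] summary, plus elements
#'   `true_offset_um` and `measurements`.
#' @export
simulate_offset_experiment <- function(offset_um, n_series = 10L, seed = 1L,
                                       model = NULL,
                                       camera_shift_um = c(0, 0),
                                       t_query_s = 60, upscale_factor = 5L) {
  if (is.null(model)) {
    model <- structure(
      list(shift_um = c(x = 0, y = 0), shift_magnitude_um = 0,
           se_um = NA_real_, sd_um = NA_real_, n_beads = 0L, n_images = 0L),
      class = "RegistrationModel")
  }
  seeds <- .sub_seeds(seed, n_series)
  measurements <- vector("list", n_series)
  for (i in seq_len(n_series)) {
    spec <- .frap_spec(seeds[i], camera_shift_um = camera_shift_um)
    centre <- .field_extent_um(spec) / 2
    theta <- .with_scene_rng(seeds[i] + 1L, stats::runif(1, 0, 2 * pi))
    truth <- centrosome_truth(
      mother_pos_um = centre, pcm_center_um = centre,
      channel_offset_um = offset_um * c(cos(theta), sin(theta)))
    sim <- generate_frap_series(spec, truth)
    ctr_px <- round(centre / spec$pixel_size_um)  # (x, y), 0-based
    half <- 10L
    window <- c(ctr_px[2] + 1L - half, ctr_px[2] + 1L + half,
                ctr_px[1] + 1L - half, ctr_px[1] + 1L + half)
    measurements[[i]] <- measure_pair_offset(
      sim$series, window, t_query_s, model, upscale_factor = upscale_factor)
  }
  out <- aggregate_offsets(measurements)
  out$true_offset_um <- offset_um
  out$measurements <- measurements
  out
}

#' Simulate and measure FRAP recovery kinetics
#'
#' Generates `n_series` centrosome FRAP series (optionally with a delayed
#' red-channel recovery, emulating the regime where the centriolar protein
#' only returns after a cell-cycle transition), extracts each recovery
#' curve from the 2-SD reference ROI with annulus background subtraction,
#' and averages.
#'
#' @param n_series replicate count.
#' @param red_delay_s red-channel recovery delay, s post-bleach.
#' @param seed master seed.
#' @param frame_times_s acquisition times, s (bleach at t = 0 must be
#'   present).
#' @return list with `mean_curve` (a `RecoveryCurve`), `curves`,
#'   `red_delay_s`.
#' @export
simulate_recovery_experiment <- function(n_series = 10L, red_delay_s = 0,
                                         seed = 1L,
                                         frame_times_s = c(-30, -15, 0,
                                                           seq(15, 300, 15))) {
  seeds <- .sub_seeds(seed, n_series)
  curves <- vector("list", n_series)
  for (i in seq_len(n_series)) {
    spec <- .frap_spec(seeds[i], frame_times_s = frame_times_s,
                       image_shape_px = c(64L, 64L))
    centre <- .field_extent_um(spec) / 2
    truth <- centrosome_truth(
      mother_pos_um = centre, pcm_center_um = centre,
      channel_offset_um = c(0.21, 0), red_delay_s = red_delay_s)
    sim <- generate_frap_series(spec, truth)
    proj <- max_project(sim$series)
    pre_frame <- spec$bleach_frame_index - 1L
    mask <- recovery_roi(get_plane(proj, t = pre_frame, channel = 2L))
    bg <- annulus_mask(dim(mask), centre, spec$pixel_size_um)
    curves[[i]] <- recovery_curve(sim$series, mask, bg)
  }
  list(mean_curve = average_recovery_curves(curves), curves = curves,
       red_delay_s = red_delay_s)
}
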