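#' Acquisition / simulation scene parameters
#'
#' Bundles the acquisition geometry and camera model shared by all synthetic
#' scenes. Defaults reproduce a spinning-disk confocal setup typical of live
#' embryo centrosome imaging: 0.105 um pixels and 5 z-slices spaced 0.5 um,
#' whose maximum-intensity projection is what gets quantified.
#'
#' @param image_shape_px integer pair `(ny, nx)`.
#' @param pixel_size_um lateral pixel size, um/pixel (> 0).
#' @param n_z number of z-slices.
#' @param z_spacing_um axial spacing, um.
#' @param frame_times_s strictly increasing frame times, seconds.
#' @param bleach_frame_index 1-based index of the photobleach frame, or `NULL`.
#' @param psf_sigma_um lateral Gaussian PSF sigma, um. The PSF is an
#'   isotropic 2-D Gaussian per slice with Gaussian amplitude decay away
#'   from the focal plane (`psf_z_sigma_um`); no 3-D optics.
#' @param psf_z_sigma_um axial amplitude-decay sigma, um.
#' @param photons_per_emitter expected photons collected per point emitter
#'   at focus. The default gives single-bead localisation noise of a few
#'   nanometres, so that pooled bead-shift estimates resolve the ~0.005 um
#'   scale the calibration is expected to achieve.
#' @param background_level uniform background, photons/pixel.
#' @param read_noise_sd Gaussian read noise sigma, counts (gain = 1).
#' @param shot_noise apply Poisson noise to `signal + background`? Setting
#'   this `FALSE` together with `read_noise_sd = 0` gives exact noiseless
#'   renders for oracle tests.
#' @param camera_shift_um systematic red-minus-green channel misalignment
#'   `(dx, dy)` in um applied to every red-channel emitter; this is the
#'   microscope property that bead calibration estimates and removes.
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   scenes.
#' @return object of class `SceneSpec`.
#' @export
scene_spec <- function(image_shape_px = c(64L, 64L),
                       pixel_size_um = 0.105,
                       n_z = 5L,
                       z_spacing_um = 0.5,
                       frame_times_s = 0,
                       bleach_frame_index = NULL,
                       psf_sigma_um = 0.1,
                       psf_z_sigma_um = 0.6,
                       photons_per_emitter = 2000,
                       background_level = 10,
                       read_noise_sd = 2,
                       shot_noise = TRUE,
                       camera_shift_um = c(0, 0),
                       rng_seed = 1L) {
  stopifnot(
    length(image_shape_px) == 2L, all(image_shape_px >= 4),
    pixel_size_um > 0, n_z >= 1L, z_spacing_um > 0,
    psf_sigma_um > 0, psf_z_sigma_um > 0,
    photons_per_emitter > 0, background_level >= 0, read_noise_sd >= 0,
    length(camera_shift_um) == 2L, all(is.finite(camera_shift_um))
  )
  frame_times_s <- as.numeric(frame_times_s)
  if (length(frame_times_s) > 1L && any(diff(frame_times_s) <= 0)) {
    stop("frame_times_s must be strictly increasing")
  }
  if (!is.null(bleach_frame_index)) {
    bleach_frame_index <- as.integer(bleach_frame_index)
    if (bleach_frame_index < 1L || bleach_frame_index > length(frame_times_s)) {
      stop("bleach_frame_index outside the frame range")
    }
  }
  structure(
    list(image_shape_px = as.integer(image_shape_px),
         pixel_size_um = pixel_size_um, n_z = as.integer(n_z),
         z_spacing_um = z_spacing_um, frame_times_s = frame_times_s,
         bleach_frame_index = bleach_frame_index,
         psf_sigma_um = psf_sigma_um, psf_z_sigma_um = psf_z_sigma_um,
         photons_per_emitter = photons_per_emitter,
         background_level = background_level, read_noise_sd = read_noise_sd,
         shot_noise = isTRUE(shot_noise),
         camera_shift_um = as.numeric(camera_shift_um),
         rng_seed = as.integer(rng_seed)),
    class = "SceneSpec")
}

#' Ground truth for a fiducial bead field
#'
#' @param bead_positions_um n x 2 matrix (columns x, y) of true bead
#'   positions in um.
#' @param true_shift_um systematic red-minus-green displacement `(dx, dy)`,
#'   um, shared by every bead (the quantity calibration must recover).
#' @param per_bead_jitter_sd_um per-coordinate Gaussian sd of independent
#'   per-bead localisation jitter added to the red positions, um.
#' @param min_separation_um minimum allowed pairwise bead separation;
#'   positions closer than this are rejected so green/red matching is
#'   unambiguous. Default `4 * psf_sigma` should be enforced by the caller;
#'   here any positive value is accepted and checked.
#' @return object of class `BeadFieldTruth`.
#' @export
bead_field_truth <- function(bead_positions_um, true_shift_um = c(0, 0),
                             per_bead_jitter_sd_um = 0,
                             min_separation_um = 0.4) {
  bead_positions_um <- matrix(as.numeric(bead_positions_um), ncol = 2,
                              dimnames = list(NULL, c("x", "y")))
  stopifnot(nrow(bead_positions_um) >= 1L,
            length(true_shift_um) == 2L, all(is.finite(true_shift_um)),
            per_bead_jitter_sd_um >= 0, min_separation_um > 0)
  if (nrow(bead_positions_um) > 1L) {
    d <- stats::dist(bead_positions_um)
    if (min(d) < min_separation_um) {
      stop(sprintf("beads closer than the minimum separation (%.3f < %.3f um)",
                   min(d), min_separation_um))
    }
  }
  structure(
    list(bead_positions_um = bead_positions_um,
         true_shift_um = as.numeric(true_shift_um),
         per_bead_jitter_sd_um = per_bead_jitter_sd_um,
         min_separation_um = min_separation_um),
    class = "BeadFieldTruth")
}

#' Lay out well-separated bead positions on a jittered grid
#'
#' Deterministic given the RNG state; used by tests and the calibration
#' simulations to place `n` beads with guaranteed minimum separation inside
#' the field with a safety margin at the borders.
#'
#' @param n number of beads.
#' @param spec a `SceneSpec`.
#' @param margin_um border clearance, um.
#' @return n x 2 position matrix (um).
#' @export
place_beads <- function(n, spec, margin_um = 0.6) {
  ext <- (rev(spec$image_shape_px) - 1) * spec$pixel_size_um  # (x, y) extent
  usable <- ext - 2 * margin_um
  if (any(usable <= 0)) stop("margin leaves no usable field")
  k <- ceiling(sqrt(n))
  cell <- usable / k
  min_sep <- 4 * spec$psf_sigma_um
  if (min(cell) < 2 * min_sep) {
    stop(sprintf("cannot place %d beads with %.2f um separation in this field",
                 n, min_sep))
  }
  idx <- sample(k * k, n) - 1L
  gx <- idx %% k; gy <- idx %/% k
  # jitter within the central part of each cell so neighbours stay separated
  slack <- (cell - min_sep) / 2
  pos <- cbind(
    x = margin_um + (gx + 0.5) * cell[1] + stats::runif(n, -slack[1], slack[1]),
    y = margin_um + (gy + 0.5) * cell[2] + stats::runif(n, -slack[2], slack[2])
  )
  pos
}

#' Ground truth for a two-channel centrosome FRAP scene
#'
#' The scene holds a broad pericentriolar-material (PCM) distribution in the
#' green channel and one or two tight centriolar foci in the red channel.
#' After the photobleach both channels recover with saturating first-order
#' kinetics; the recovering green signal is centred on `pcm_center_um` and
#' the recovering red focus is displaced from it by `channel_offset_um`
#' (green position minus red position), which is the quantity the offset
#' pipeline must recover.
#'
#' @param mother_pos_um mother-centriole position `(x, y)`, um.
#' @param daughter_pos_um daughter position, or `NULL` for a single focus.
#' @param pcm_center_um centre of the PCM distribution; defaults to the
#'   mother position.
#' @param pcm_sigma_um Gaussian sigma of the PCM cloud (must exceed the PSF
#'   sigma: the PCM is a genuinely broad structure, not a point).
#' @param pcm_sigma_end_um optional final PCM sigma; when set, the
#'   recovering PCM width grows linearly from `pcm_sigma_um` to this value
#'   across the post-bleach window (signal recovers centrally then spreads).
#' @param channel_offset_um true green-minus-red displacement of the
#'   recovering signal centres, um.
#' @param recovery_rate_per_s length-2 `(green, red)` recovery rate
#'   constants, 1/s.
#' @param recovered_fraction length-2 `(green, red)` plateau fractions of
#'   the pre-bleach signal, each in [0, 1].
#' @param red_delay_s delay before the red channel starts recovering,
#'   seconds after the bleach (0 = immediate). Models the M-phase regime in
#'   which the centriolar protein only begins to return at the next S-phase.
#' @param pcm_photons total expected photons of the pre-bleach PCM cloud.
#' @param focus_photons total expected photons per centriolar focus.
#' @return object of class `CentrosomeTruth`.
#' @export
centrosome_truth <- function(mother_pos_um,
                             daughter_pos_um = NULL,
                             pcm_center_um = mother_pos_um,
                             pcm_sigma_um = 0.35,
                             pcm_sigma_end_um = NULL,
                             channel_offset_um = c(0.21, 0),
                             recovery_rate_per_s = c(green = 0.03, red = 0.03),
                             recovered_fraction = c(green = 0.8, red = 0.8),
                             red_delay_s = 0,
                             pcm_photons = 5e4,
                             focus_photons = 2e4) {
  stopifnot(length(mother_pos_um) == 2L, all(is.finite(mother_pos_um)),
            is.null(daughter_pos_um) || length(daughter_pos_um) == 2L,
            length(pcm_center_um) == 2L,
            pcm_sigma_um > 0,
            is.null(pcm_sigma_end_um) || pcm_sigma_end_um >= pcm_sigma_um,
            length(channel_offset_um) == 2L, all(is.finite(channel_offset_um)),
            length(recovery_rate_per_s) == 2L, all(recovery_rate_per_s > 0),
            length(recovered_fraction) == 2L,
            all(recovered_fraction >= 0), all(recovered_fraction <= 1),
            red_delay_s >= 0, pcm_photons > 0, focus_photons > 0)
  structure(
    list(mother_pos_um = as.numeric(mother_pos_um),
         daughter_pos_um = if (is.null(daughter_pos_um)) NULL else as.numeric(daughter_pos_um),
         pcm_center_um = as.numeric(pcm_center_um),
         pcm_sigma_um = pcm_sigma_um,
         pcm_sigma_end_um = pcm_sigma_end_um,
         channel_offset_um = as.numeric(channel_offset_um),
         recovery_rate_per_s = stats::setNames(as.numeric(recovery_rate_per_s),
                                               c("green", "red")),
         recovered_fraction = stats::setNames(as.numeric(recovered_fraction),
                                              c("green", "red")),
         red_delay_s = red_delay_s,
         pcm_photons = pcm_photons, focus_photons = focus_photons),
    class = "CentrosomeTruth")
}

# Run expr with a private RNG stream seeded from `seed`, restoring the
# caller's stream afterwards: generators are reproducible without trampling
# the session RNG.
.with_scene_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Add an integrated-Gaussian spot to a (ny, nx) matrix. Flux is the exact
# Gaussian mass falling in each pixel (difference of normal CDFs across the
# pixel edges), so total rendered photons are conserved to the truncation of
# the +/- 6 sigma patch regardless of sub-pixel position.
.render_spot <- function(img, x_um, y_um, photons, sigma_um, pixel_size_um) {
  ny <- nrow(img); nx <- ncol(img)
  half <- ceiling(6 * sigma_um / pixel_size_um)
  jc <- round(x_um / pixel_size_um); ic <- round(y_um / pixel_size_um)
  j0 <- max(0L, jc - half); j1 <- min(nx - 1L, jc + half)
  i0 <- max(0L, ic - half); i1 <- min(ny - 1L, ic + half)
  if (j0 > j1 || i0 > i1) return(img)
  jj <- j0:j1; ii <- i0:i1
  fx <- stats::pnorm(((jj + 0.5) * pixel_size_um - x_um) / sigma_um) -
        stats::pnorm(((jj - 0.5) * pixel_size_um - x_um) / sigma_um)
  fy <- stats::pnorm(((ii + 0.5) * pixel_size_um - y_um) / sigma_um) -
        stats::pnorm(((ii - 0.5) * pixel_size_um - y_um) / sigma_um)
  img[ii + 1L, jj + 1L] <- img[ii + 1L, jj + 1L] + photons * outer(fy, fx)
  img
}

# Gaussian amplitude decay of a point emitter away from the focal plane.
.z_weights <- function(spec) {
  z <- (seq_len(spec$n_z) - 1) * spec$z_spacing_um
  zf <- mean(range(z))
  exp(-(z - zf)^2 / (2 * spec$psf_z_sigma_um^2))
}

# Poisson shot noise on signal+background plus Gaussian read noise,
# clamped at zero (counts cannot be negative).
.apply_noise <- function(img, spec) {
  img <- img + spec$background_level
  if (spec$shot_noise) {
    img[] <- stats::rpois(length(img), lambda = img)
  }
  if (spec$read_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = spec$read_noise_sd)
  }
  pmax(img, 0)
}

.field_extent_um <- function(spec) (rev(spec$image_shape_px) - 1) * spec$pixel_size_um

#' Simulate a two-channel fiducial bead field
#'
#' Renders every bead as a PSF-blurred point source in both channels. Red
#' bead centres are the green centres plus the systematic
#' `truth$true_shift_um`, plus the scene's `camera_shift_um`, plus
#' independent per-bead Gaussian jitter. With jitter, shift, and noise all
#' zero the two channels are identical pixel for pixel.
#'
#' @param spec a `SceneSpec` (single timepoint).
#' @param truth a `BeadFieldTruth`.
#' @return list with `series` (a 2-channel `ImageSeries`, channels
#'   `green`, `red`) and `truth` — the input truth extended with
#'   `red_positions_um`, the realised (jittered) red bead centres.
#' @export
generate_bead_field <- function(spec, truth) {
  stopifnot(inherits(spec, "SceneSpec"), inherits(truth, "BeadFieldTruth"))
  ext <- .field_extent_um(spec)
  pos <- truth$bead_positions_um
  if (any(pos[, 1] < 0 | pos[, 1] > ext[1] | pos[, 2] < 0 | pos[, 2] > ext[2])) {
    stop("bead positions outside the field of view")
  }
  .with_scene_rng(spec$rng_seed, {
    n <- nrow(pos)
    jitter <- matrix(stats::rnorm(2 * n, sd = truth$per_bead_jitter_sd_um),
                     ncol = 2)
    red_pos <- sweep(pos, 2, -(truth$true_shift_um + spec$camera_shift_um)) +
      jitter
    wz <- .z_weights(spec)
    ny <- spec$image_shape_px[1]; nx <- spec$image_shape_px[2]
    px <- array(0, dim = c(1L, 2L, spec$n_z, ny, nx))
    for (z in seq_len(spec$n_z)) {
      g <- matrix(0, ny, nx); r <- matrix(0, ny, nx)
      for (b in seq_len(n)) {
        g <- .render_spot(g, pos[b, 1], pos[b, 2],
                          spec$photons_per_emitter * wz[z],
                          spec$psf_sigma_um, spec$pixel_size_um)
        r <- .render_spot(r, red_pos[b, 1], red_pos[b, 2],
                          spec$photons_per_emitter * wz[z],
                          spec$psf_sigma_um, spec$pixel_size_um)
      }
      px[1, 1, z, , ] <- .apply_noise(g, spec)
      px[1, 2, z, , ] <- .apply_noise(r, spec)
    }
    truth$red_positions_um <- red_pos
    list(series = image_series(px, spec$pixel_size_um, spec$z_spacing_um,
                               frame_times_s = spec$frame_times_s[1],
                               channel_names = c("green", "red")),
         truth = truth)
  })
}

# Closed-form recovery amplitude schedule: fraction of the pre-bleach
# signal present at time t_rel after the bleach (t_rel < 0 = pre-bleach).
.recovery_amplitude <- function(t_rel, rate, fraction, delay = 0) {
  ifelse(t_rel < 0, 1,
         fraction * (1 - exp(-rate * pmax(0, t_rel - delay))))
}

#' Simulate a two-channel centrosome FRAP series
#'
#' Pre-bleach frames show the steady state: a broad PCM cloud in the green
#' channel and one or two tight centriolar foci in the red channel. At the
#' bleach frame (`t_rel = 0`) both channels drop to pure background; in
#' later frames each channel recovers as
#' `I(t) = recovered_fraction * (1 - exp(-rate * (t - delay)))` of its
#' pre-bleach signal. The recovering green signal is centred on the PCM
#' centre; the recovering red signal is a single tight focus displaced from
#' it by `-channel_offset_um` (so green minus red equals the truth offset).
#' The scene's `camera_shift_um` is additionally applied to all red-channel
#' emitters, emulating microscope channel misalignment that downstream
#' registration must remove.
#'
#' @param spec a `SceneSpec` with `bleach_frame_index` set and frame times
#'   spanning pre- and post-bleach.
#' @param truth a `CentrosomeTruth`.
#' @return list with `series` (2-channel `ImageSeries`) and `truth`, the
#'   input extended with `recovering_red_pos_um` (the true post-bleach red
#'   focus position, before camera shift).
#' @export
generate_frap_series <- function(spec, truth) {
  stopifnot(inherits(spec, "SceneSpec"), inherits(truth, "CentrosomeTruth"))
  if (is.null(spec$bleach_frame_index)) {
    stop("spec$bleach_frame_index must be set for a FRAP series")
  }
  t_bleach <- spec$frame_times_s[spec$bleach_frame_index]
  if (!any(spec$frame_times_s < t_bleach) ||
      !any(spec$frame_times_s > t_bleach)) {
    stop("frame_times_s must span pre- and post-bleach frames")
  }
  ext <- .field_extent_um(spec)
  inside <- function(p) all(p >= 0) && p[1] <= ext[1] && p[2] <= ext[2]
  if (!inside(truth$mother_pos_um) || !inside(truth$pcm_center_um)) {
    stop("centrosome positions outside the field of view")
  }
  if (truth$pcm_sigma_um <= spec$psf_sigma_um) {
    stop("pcm_sigma_um must exceed psf_sigma_um: the PCM is a broad structure")
  }
  rec_red_pos <- truth$pcm_center_um - truth$channel_offset_um
  cam <- spec$camera_shift_um
  t_rel <- spec$frame_times_s - t_bleach
  t_end <- max(t_rel)
  wz <- .z_weights(spec)
  ny <- spec$image_shape_px[1]; nx <- spec$image_shape_px[2]
  nt <- length(spec$frame_times_s)

  .with_scene_rng(spec$rng_seed, {
    px <- array(0, dim = c(nt, 2L, spec$n_z, ny, nx))
    for (t in seq_len(nt)) {
      ag <- .recovery_amplitude(t_rel[t], truth$recovery_rate_per_s["green"],
                                truth$recovered_fraction["green"])
      ar <- .recovery_amplitude(t_rel[t], truth$recovery_rate_per_s["red"],
                                truth$recovered_fraction["red"],
                                truth$red_delay_s)
      # PCM width: steady pre-bleach, then optionally spreading outwards
      sig_pcm <- truth$pcm_sigma_um
      if (!is.null(truth$pcm_sigma_end_um) && t_rel[t] > 0 && t_end > 0) {
        sig_pcm <- truth$pcm_sigma_um +
          (truth$pcm_sigma_end_um - truth$pcm_sigma_um) * t_rel[t] / t_end
      }
      # effective lateral width convolves PCM extent with the PSF
      sig_g <- sqrt(sig_pcm^2 + spec$psf_sigma_um^2)
      for (z in seq_len(spec$n_z)) {
        g <- matrix(0, ny, nx); r <- matrix(0, ny, nx)
        if (ag > 0) {
          g <- .render_spot(g, truth$pcm_center_um[1], truth$pcm_center_um[2],
                            ag * truth$pcm_photons * wz[z], sig_g,
                            spec$pixel_size_um)
        }
        if (t_rel[t] < 0) {
          # steady state: mother (+ daughter) centriolar foci
          r <- .render_spot(r, truth$mother_pos_um[1] + cam[1],
                            truth$mother_pos_um[2] + cam[2],
                            truth$focus_photons * wz[z],
                            spec$psf_sigma_um, spec$pixel_size_um)
          if (!is.null(truth$daughter_pos_um)) {
            r <- .render_spot(r, truth$daughter_pos_um[1] + cam[1],
                              truth$daughter_pos_um[2] + cam[2],
                              truth$focus_photons * wz[z],
                              spec$psf_sigma_um, spec$pixel_size_um)
          }
        } else if (ar > 0) {
          r <- .render_spot(r, rec_red_pos[1] + cam[1], rec_red_pos[2] + cam[2],
                            ar * truth$focus_photons * wz[z],
                            spec$psf_sigma_um, spec$pixel_size_um)
        }
        px[t, 1, z, , ] <- .apply_noise(g, spec)
        px[t, 2, z, , ] <- .apply_noise(r, spec)
      }
    }
    truth$recovering_red_pos_um <- rec_red_pos
    list(series = image_series(px, spec$pixel_size_um, spec$z_spacing_um,
                               frame_times_s = spec$frame_times_s,
                               channel_names = c("green", "red"),
                               bleach_frame_index = spec$bleach_frame_index),
         truth = truth)
  })
}

#' Serialise / restore ground-truth records
#'
#' Truth records round-trip exactly (full double precision) through JSON.
#'
#' @param truth a `BeadFieldTruth` or `CentrosomeTruth`.
#' @param path JSON file path.
#' @return `path` invisibly (write); the truth object (read).
#' @export
write_truth <- function(truth, path) {
  kind <- class(truth)[1]
  stopifnot(kind %in% c("BeadFieldTruth", "CentrosomeTruth"))
  payload <- unclass(truth)
  payload$.kind <- kind
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- x$.kind
  x$.kind <- NULL
  for (f in c("bead_positions_um", "red_positions_um")) {
    if (!is.null(x[[f]])) {
      x[[f]] <- matrix(as.numeric(t(x[[f]])), ncol = 2, byrow = TRUE,
                       dimnames = list(NULL, c("x", "y")))
    }
  }
  for (f in c("recovery_rate_per_s", "recovered_fraction")) {
    if (!is.null(x[[f]])) {
      x[[f]] <- stats::setNames(as.numeric(x[[f]]), c("green", "red"))
    }
  }
  structure(x, class = kind)
}

#' Write a generated scene (series + truth) to disk
#'
#' Writes the TIFF stack with its JSON calibration sidecar plus a
#' `<path>.truth.json` ground-truth record.
#'
#' @param scene list with `series` and `truth` as returned by the
#'   generators.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  write_series(scene$series, path)
  write_truth(scene$truth, paste0(sub("\\.tiff?$", "", path), ".truth.json"))
  invisible(path)
}
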