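# Shared fixtures: everything is generated in code at test time.

# Noiseless small spec for exact oracle tests.
quiet_spec <- function(..., seed = 1L) {
  scene_spec(..., shot_noise = FALSE, read_noise_sd = 0, background_level = 0,
             rng_seed = seed)
}

zero_model <- function() {
  estimate_channel_shift(data.frame(dx_um = 0, dy_um = 0, dist_um = 0,
                                    gx_um = 0, gy_um = 0,
                                    rx_um = 0, ry_um = 0))
}

shift_model <- function(dx, dy) {
  estimate_channel_shift(data.frame(dx_um = dx, dy_um = dy,
                                    dist_um = sqrt(dx^2 + dy^2),
                                    gx_um = 0, gy_um = 0,
                                    rx_um = dx, ry_um = dy))
}

# A hand-built RadialProfile for arithmetic tests.
manual_profile <- function(values, spacing_um = 0.028) {
  structure(
    list(radii_um = (seq_along(values) - 1) * spacing_um,
         mean_intensity = as.numeric(values),
         n_pixels = rep(1L, length(values)),
         spacing_um = spacing_um,
         background_subtracted = FALSE, normalised = FALSE),
    class = "RadialProfile")
}

# Centre of the field of a spec, in um.
field_centre <- function(spec) (rev(spec$image_shape_px) - 1) * spec$pixel_size_um / 2
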