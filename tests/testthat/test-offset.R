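test_that("upscale geometry, identity and error cases", {
  img <- matrix(runif(30), 5, 6)
  expect_identical(upscale(img, 1), img)
  expect_error(upscale(img, 0), "factor")
  expect_error(upscale(img, 2.5), "factor")
  up <- upscale(img, 5)
  expect_identical(dim(up), c(25L, 30L))
  # a 10x10 window at 0.105 um/px becomes 50x50 at 0.021 um/px
  expect_identical(dim(upscale(matrix(0, 10, 10), 5)), c(50L, 50L))
  expect_equal(0.105 / 5, 0.021)
  # nearest-neighbour oracle: each input pixel replicated factor^2 times
  nn <- upscale(img, 3, method = "nearest")
  expect_equal(nn[seq(2, 15, 3), seq(2, 18, 3)], img)
})

test_that("bilinear upscaling preserves total intensity of a smooth image", {
  # oracle: direct summation; sum scales by factor^2 for a smooth field
  spec <- quiet_spec(image_shape_px = c(41, 41), n_z = 1)
  x <- (0:40) * spec$pixel_size_um
  img <- exp(-outer((x - 2.1)^2, (x - 2.1)^2, "+") / (2 * 0.4^2))
  up <- upscale(img, 5)
  expect_lt(abs(sum(up) / 25 - sum(img)) / sum(img), 0.01)
})

test_that("compute_centroid equals the weighted-mean arithmetic", {
  # two pixels, values 1 and 3 at x = 0 and 1, threshold 0: x = 0.75
  img <- matrix(c(1, 3), nrow = 1)
  cen <- compute_centroid(img, pixel_size_um = 1,
                          rule = threshold_rule(fraction = 0.1, background = 0))
  expect_equal(unname(cen$position_um["x"]), 0.75)
  expect_equal(unname(cen$position_um["y"]), 0)
  expect_equal(cen$n_pixels_above, 2L)
})

test_that("compute_centroid matches a brute-force double loop", {
  set.seed(51)
  img <- matrix(runif(20 * 17), 20, 17)
  img[8:12, 6:10] <- img[8:12, 6:10] + 5   # a blob
  rule <- threshold_rule(fraction = 0.5, background = 0)
  cen <- compute_centroid(img, pixel_size_um = 0.021, rule = rule)
  thr <- 0.5 * max(img)
  num_x <- 0; num_y <- 0; den <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (img[i, j] > thr) {
      num_x <- num_x + img[i, j] * (j - 1)
      num_y <- num_y + img[i, j] * (i - 1)
      den <- den + img[i, j]
    }
  }
  expect_equal(unname(cen$position_um["x"]), num_x / den * 0.021)
  expect_equal(unname(cen$position_um["y"]), num_y / den * 0.021)
})

test_that("centroid of a symmetric Gaussian spot is its centre", {
  spec <- quiet_spec(image_shape_px = c(25, 25), n_z = 1)
  ctr <- field_centre(spec) + c(0.04, -0.02)
  sim <- generate_bead_field(spec, bead_field_truth(matrix(ctr, 1, 2)))
  img <- upscale(get_plane(sim$series, 1, 1, 1), 5)
  up_px <- spec$pixel_size_um / 5
  for (frac in c(0.2, 0.5, 0.8)) {
    cen <- compute_centroid(img, up_px,
                            rule = threshold_rule(fraction = frac,
                                                  background = 0))
    # map upscaled coordinates back to the parent frame
    pos <- ((cen$position_um / up_px + 0.5) / 5 - 0.5) * spec$pixel_size_um
    expect_lt(max(abs(pos - ctr)), 0.25 * up_px + 1e-9)
  }
})

test_that("empty windows raise distinguishable errors", {
  expect_error(compute_centroid(matrix(2, 5, 5), 1,
                                rule = threshold_rule(background = 2)),
               "empty signal")
})

test_that("measured null offset stays at the calibrated noise floor", {
  res <- simulate_offset_experiment(0, n_series = 10, seed = 61L)
  expect_lt(res$mean_distance_um, 0.02)
})

test_that("registration correction changes the offset by exactly the shift", {
  sp <- scene_spec(image_shape_px = c(48, 48), n_z = 3,
                   frame_times_s = c(-10, 0, 30, 60),
                   bleach_frame_index = 2L, rng_seed = 71L)
  centre <- field_centre(sp)
  truth <- centrosome_truth(mother_pos_um = centre, pcm_center_um = centre,
                            channel_offset_um = c(0.15, 0.05))
  sim <- generate_frap_series(sp, truth)
  ctr_px <- round(centre / sp$pixel_size_um)
  window <- c(ctr_px[2] + 1 - 9, ctr_px[2] + 1 + 9,
              ctr_px[1] + 1 - 9, ctr_px[1] + 1 + 9)
  m_raw <- measure_pair_offset(sim$series, window, 60, zero_model())
  shift <- c(0.03, -0.02)
  m_cor <- measure_pair_offset(sim$series, window, 60,
                               shift_model(shift[1], shift[2]))
  # oracle: vector arithmetic; corrected = uncorrected + shift
  expect_equal(unname(m_cor$displacement_um - m_raw$displacement_um), shift,
               tolerance = 1e-10)
})

test_that("a channel without recovery signal is named in the error", {
  sp <- quiet_spec(image_shape_px = c(32, 32), n_z = 1,
                   frame_times_s = c(-10, 0, 30, 60))
  sp$bleach_frame_index <- 2L
  truth <- centrosome_truth(mother_pos_um = field_centre(sp),
                            recovered_fraction = c(green = 0.8, red = 0))
  sim <- generate_frap_series(sp, truth)
  window <- c(8, 24, 8, 24)
  expect_error(measure_pair_offset(sim$series, window, 60, zero_model()),
               "red channel")
})

test_that("aggregate_offsets summarises and rejects empty input", {
  sp <- scene_spec(image_shape_px = c(48, 48), n_z = 1,
                   frame_times_s = c(-10, 0, 60), bleach_frame_index = 2L,
                   rng_seed = 81L)
  centre <- field_centre(sp)
  truth <- centrosome_truth(mother_pos_um = centre, pcm_center_um = centre)
  sim <- generate_frap_series(sp, truth)
  ctr_px <- round(centre / sp$pixel_size_um)
  window <- c(ctr_px[2] - 8, ctr_px[2] + 10, ctr_px[1] - 8, ctr_px[1] + 10)
  m <- measure_pair_offset(sim$series, window, 60, zero_model())
  agg <- aggregate_offsets(list(m))
  expect_equal(agg$mean_distance_um, m$distance_um)
  expect_equal(agg$n, 1L)
  expect_named(agg$table, c("id", "dx_um", "dy_um", "distance_um", "t_s"))
  expect_error(aggregate_offsets(list()), "no offset measurements")
})

test_that("distances are invariant to a global scene translation", {
  base_centre <- c(2.4, 2.4)
  run_at <- function(centre, seed) {
    sp <- scene_spec(image_shape_px = c(64, 64), n_z = 1,
                     frame_times_s = c(-10, 0, 60), bleach_frame_index = 2L,
                     rng_seed = seed, shot_noise = FALSE, read_noise_sd = 0,
                     background_level = 0)
    truth <- centrosome_truth(mother_pos_um = centre, pcm_center_um = centre,
                              channel_offset_um = c(0.12, 0.09))
    sim <- generate_frap_series(sp, truth)
    ctr_px <- round(centre / sp$pixel_size_um)
    window <- c(ctr_px[2] + 1 - 9, ctr_px[2] + 1 + 9,
                ctr_px[1] + 1 - 9, ctr_px[1] + 1 + 9)
    measure_pair_offset(sim$series, window, 60, zero_model())$distance_um
  }
  d0 <- run_at(base_centre, 91L)
  # translate the whole scene by an arbitrary (non-integer-pixel) vector
  d1 <- run_at(base_centre + c(0.63, -0.41), 91L)
  expect_lt(abs(d1 - d0), 0.005)
})

test_that("mean measured distance increases monotonically with the truth", {
  truths <- c(0, 0.05, 0.10, 0.15, 0.20, 0.25)
  means <- vapply(seq_along(truths), function(i) {
    simulate_offset_experiment(truths[i], n_series = 10,
                               seed = 100L + i)$mean_distance_um
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("fivefold upscaling refines localisation precision", {
  set.seed(111)
  errs <- sapply(1:12, function(i) {
    sp <- scene_spec(image_shape_px = c(21, 21), n_z = 1, rng_seed = 200L + i,
                     photons_per_emitter = 3000)
    truth_xy <- field_centre(sp) + runif(2, -0.05, 0.05)
    sim <- generate_bead_field(sp, bead_field_truth(matrix(truth_xy, 1, 2)))
    img <- get_plane(sim$series, 1, 1, 1)
    vapply(c(1, 5), function(f) {
      up <- upscale(img, f)
      cen <- compute_centroid(up, sp$pixel_size_um / f)
      pos <- ((cen$position_um / (sp$pixel_size_um / f) + 0.5) / f - 0.5) *
        sp$pixel_size_um
      sqrt(sum((pos - truth_xy)^2))
    }, numeric(1))
  })
  rmse <- sqrt(rowMeans(errs^2))
  expect_lte(rmse[2], rmse[1])
})
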