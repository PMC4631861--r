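test_that("radial profile of a uniform field is flat", {
  img <- matrix(3.7, 61, 61)
  ctr <- c(30, 30) * 0.021
  p <- radial_profile(img, ctr, 0.021, spacing_um = 0.028, extent_um = 0.5)
  ok <- !is.na(p$mean_intensity)
  expect_true(all(abs(p$mean_intensity[ok] - 3.7) < 1e-12))
})

test_that("a single bright centre pixel dominates ring 0 only", {
  img <- matrix(0.1, 41, 41)
  img[21, 21] <- 100
  ctr <- c(20, 20) * 0.021
  p <- radial_profile(img, ctr, 0.021, spacing_um = 0.028, extent_um = 0.4)
  # ring 0 holds the bright pixel plus its 4 edge neighbours at r = 0.021
  expect_gt(p$mean_intensity[1], 10)
  expect_true(all(p$mean_intensity[-1] < 0.2, na.rm = TRUE))
})

test_that("profile of an isotropic Gaussian matches annulus integrals", {
  # oracle: dense numeric integration of exp(-r^2 / 2 sigma^2) over each
  # ring annulus; pixel-centre binning must agree within 2%
  px <- 0.021; n <- 301; sigma <- 0.35
  ctr <- c((n - 1) / 2, (n - 1) / 2) * px
  x <- (0:(n - 1)) * px - ctr[1]
  img <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  p <- radial_profile(img, ctr, px)
  oracle <- vapply(seq_along(p$radii_um), function(k) {
    r0 <- (k - 1) * p$spacing_um; r1 <- k * p$spacing_um
    rr <- seq(r0, r1, length.out = 200)
    f <- exp(-rr^2 / (2 * sigma^2)) * rr
    2 * sum((f[-1] + f[-200]) / 2 * diff(rr)) / (r1^2 - r0^2)
  }, numeric(1))
  sel <- oracle > 0.02          # rings with appreciable signal
  expect_lt(max(abs(p$mean_intensity[sel] - oracle[sel]) / oracle[sel]), 0.02)
  # defaults give the documented ring count and spacing
  expect_equal(length(p$radii_um), 108L)
  expect_equal(diff(p$radii_um)[1], 0.028)
})

test_that("rings beyond the image are NA, never zero", {
  img <- matrix(1, 21, 21)
  p <- radial_profile(img, c(0.21, 0.21), 0.021,
                      spacing_um = 0.028, extent_um = 3.02)
  expect_true(anyNA(p$mean_intensity))
  expect_false(any(p$mean_intensity == 0 & p$n_pixels == 0, na.rm = TRUE))
  expect_error(radial_profile(img, c(-1, 0), 0.021), "outside")
})

test_that("radial profile is rotation-invariant to within discretisation", {
  px <- 0.021; n <- 201; sigma <- 0.3
  ctr <- c((n - 1) / 2, (n - 1) / 2) * px
  x <- (0:(n - 1)) * px - ctr[1]
  # anisotropy-free scene: Gaussian + offset; rotate 90 deg about centre
  img <- 5 + exp(-outer(x^2, x^2, "+") / (2 * sigma^2)) * 10
  rot <- t(img)[n:1, ]
  p1 <- radial_profile(img, ctr, px, extent_um = 2)
  p2 <- radial_profile(rot, ctr, px, extent_um = 2)
  ok <- !is.na(p1$mean_intensity)
  expect_lt(max(abs(p1$mean_intensity[ok] - p2$mean_intensity[ok]) /
                p1$mean_intensity[ok]), 0.02)
})

test_that("finalize_profile subtracts, normalises and mirrors", {
  p <- finalize_profile(manual_profile(c(4, 2, 1)), cytosolic_background = 1)
  expect_equal(p$mean_intensity, c(1, 1 / 3, 0))
  expect_equal(p$mirrored_intensity, c(0, 1 / 3, 1, 1 / 3, 0))
  expect_equal(p$mirrored_axis_um,
               c(-rev(p$radii_um[-1]), p$radii_um))
  expect_true(p$background_subtracted && p$normalised)
})

test_that("finalize_profile is idempotent on normalised input and exact", {
  p0 <- manual_profile(c(0.2, 1, 0.4))
  p1 <- finalize_profile(p0, 0)
  expect_equal(p1$mean_intensity, p0$mean_intensity)
  # oracle: recompute the maximum; it must be exactly 1
  set.seed(121)
  for (i in 1:5) {
    p <- finalize_profile(manual_profile(runif(20, 0.1, 7)), 0.05)
    expect_identical(max(p$mean_intensity), 1)
    expect_equal(p$mirrored_intensity, rev(p$mirrored_intensity))
  }
  expect_error(finalize_profile(manual_profile(c(1, 1)), 1), "no peak")
})

test_that("average_and_offset_profiles shifts the red axis by the offset", {
  prof <- finalize_profile(manual_profile(exp(-((1:40) - 10)^2 / 30)), 0)
  greens <- rep(list(prof), 10)
  reds <- rep(list(prof), 10)
  # identical profiles, offset zero: output equals the input, unshifted
  out0 <- average_and_offset_profiles(greens, reds, 0)
  expect_equal(out0$green_mean, prof$mirrored_intensity)
  expect_equal(out0$red_mean, prof$mirrored_intensity)
  expect_equal(out0$red_axis_um, out0$axis_um)

  out <- average_and_offset_profiles(greens, reds, 0.21)
  g_peak <- out$axis_um[which.max(out$green_mean)]
  r_peak <- out$red_axis_um[which.max(out$red_mean)]
  expect_equal(r_peak - g_peak, 0.21)

  # fewer than 10 centrosomes per channel is not a valid average
  expect_error(average_and_offset_profiles(greens[1:5], reds, 0.21),
               "at least 10")
  bad <- finalize_profile(manual_profile(c(1, 2, 3), spacing_um = 0.05), 0)
  expect_error(average_and_offset_profiles(c(greens[-1], list(bad)), reds, 0),
               "ring grids")
})

test_that("recovery_roi applies the mean + 2 SD rule", {
  expect_error(recovery_roi(matrix(5, 10, 10)), "no reference signal")

  img <- matrix(0, 20, 20); img[7, 13] <- 100
  mask <- recovery_roi(img)
  expect_equal(sum(mask), 1L)
  expect_true(mask[7, 13])

  # Gaussian spot on flat background: oracle = explicit comparison loop
  px <- 0.105; n <- 41
  x <- (0:(n - 1)) * px - 2.1
  spot <- 10 + 500 * exp(-outer(x^2, x^2, "+") / (2 * 0.3^2))
  mask <- recovery_roi(spot)
  thr <- mean(spot) + 2 * sd(spot)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    expect_identical(mask[i, j], spot[i, j] > thr)
  }
  expect_gt(sum(mask), 0)
})

test_that("recovery curves normalise to 1 pre-bleach and track bleaching", {
  # constant series with zero background: curve identically 1
  px <- array(7, dim = c(4, 2, 1, 8, 8))
  s <- image_series(px, 0.105, frame_times_s = c(-10, 0, 10, 20),
                    bleach_frame_index = 2L)
  mask <- matrix(FALSE, 8, 8); mask[3:5, 3:5] <- TRUE
  cv <- recovery_curve(s, mask, background_region = c(0, 0))
  expect_equal(cv$green_norm, rep(1, 4))
  expect_equal(cv$red_norm, rep(1, 4))
  expect_equal(cv$roi_n_pixels, 9L)

  # bleached to pure background, no recovery: post-bleach values ~ 0
  px2 <- array(2, dim = c(4, 2, 1, 8, 8))
  px2[1, , , 3:5, 3:5] <- 50
  s2 <- image_series(px2, 0.105, frame_times_s = c(-10, 0, 10, 20),
                     bleach_frame_index = 2L)
  bgmask <- matrix(FALSE, 8, 8); bgmask[, 7:8] <- TRUE
  cv2 <- recovery_curve(s2, mask, background_region = bgmask)
  expect_equal(cv2$green_norm[1], 1)
  expect_equal(cv2$green_norm[2:4], rep(0, 3))

  expect_error(recovery_curve(s2, matrix(FALSE, 8, 8), bgmask), "empty ROI")
})

test_that("recovery curve is invariant to a shared constant offset", {
  set.seed(131)
  base <- array(runif(5 * 2 * 1 * 10 * 10, 1, 4), dim = c(5, 2, 1, 10, 10))
  base[1:2, , , 4:6, 4:6] <- base[1:2, , , 4:6, 4:6] + 30
  mk <- function(extra) {
    image_series(base + extra, 0.105, frame_times_s = c(-20, -10, 0, 10, 20),
                 bleach_frame_index = 3L)
  }
  mask <- matrix(FALSE, 10, 10); mask[4:6, 4:6] <- TRUE
  bgmask <- matrix(FALSE, 10, 10); bgmask[, 9:10] <- TRUE
  cv0 <- recovery_curve(mk(0), mask, bgmask)
  cv5 <- recovery_curve(mk(5), mask, bgmask)
  expect_equal(cv5$green_norm, cv0$green_norm, tolerance = 1e-6)
  expect_equal(cv5$red_norm, cv0$red_norm, tolerance = 1e-6)
})

test_that("delayed red recovery reproduces the two-phase kinetics", {
  res <- simulate_recovery_experiment(n_series = 1, red_delay_s = 90,
                                      seed = 141L,
                                      frame_times_s = c(-30, -15, 0,
                                                        seq(15, 180, 15)))
  cv <- res$mean_curve
  post <- cv$times_s > 0
  # green rises from the first post-bleach frame
  expect_gt(cv$green_norm[which(post)[1]], 0.1)
  # red flat below the noise floor until the programmed transition
  before <- cv$times_s > 0 & cv$times_s <= 90
  expect_true(all(cv$red_norm[before] <= 0.1))
  # then rises: the sudden change in recovery dynamics
  after <- cv$times_s > 105
  expect_true(all(cv$red_norm[after] > 0.1))
  expect_gt(cv$red_norm[length(cv$red_norm)], cv$red_norm[sum(before) + 3])
})

test_that("average_recovery_curves averages per timepoint", {
  res <- simulate_recovery_experiment(n_series = 3, seed = 151L,
                                      frame_times_s = c(-20, -10, 0, 20, 40))
  m <- res$mean_curve
  manual <- rowMeans(sapply(res$curves, `[[`, "green_norm"))
  expect_equal(m$green_norm, manual)
  expect_error(average_recovery_curves(list(res$curves[[1]],
    structure(list(times_s = c(0, 1), green_norm = c(1, 1),
                   red_norm = c(1, 1), roi_n_pixels = 1L),
              class = "RecoveryCurve"))), "time grids")
})
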