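test_that("cycle detection finds sinusoid peaks and verifies closure", {
  tt <- seq(0, 10, by = 0.01)
  v <- 50 + 40 * sin(2 * pi * tt)          # 10 full periods
  f <- detect_cycles(intensity_trace(tt, v), min_prominence = 10)
  expect_length(f$peak_times, 10L)
  expect_length(f$arrest_intervals, 0L)
  expect_equal(f$cycle_periods, rep(1, 9), tolerance = 0.02)
  expect_true(all(f$closure_ok_per_cycle))
  # flat trace: no peaks, whole-span arrest, warning
  expect_warning(f0 <- detect_cycles(intensity_trace(tt, rep(3, length(tt)))),
                 "constant")
  expect_length(f0$peak_times, 0L)
  expect_equal(f0$arrest_intervals[[1]], c(0, 10))
})

test_that("a silent gap between peaks is reported as one arrest", {
  tt <- seq(0, 12, by = 0.01)
  v <- 50 + 40 * pmax(sin(2 * pi * tt), 0)
  v[tt > 4 & tt < 7] <- 50                 # three silent periods
  f <- detect_cycles(intensity_trace(tt, v), min_prominence = 10)
  expect_length(f$arrest_intervals, 1L)
  # oracle: scan peak times for the one gap exceeding twice the median
  gaps <- diff(f$peak_times)
  k <- which(gaps > 2 * median(gaps))
  expect_length(k, 1L)
  iv <- f$arrest_intervals[[1]]
  expect_lt(iv[1] - f$peak_times[k], median(gaps) + 1e-9)
  expect_equal(iv[2], f$peak_times[k + 1])
  expect_gt(interval_jaccard(iv, c(4.25, 7.25)), 0.8)
})

test_that("closure verification fails when the trace never returns to baseline", {
  tt <- seq(0, 6, by = 0.01)
  v <- 100 + 30 * sin(2 * pi * tt)         # oscillates high above minimum
  v[1:10] <- 0                             # true baseline sits at zero
  f <- detect_cycles(intensity_trace(tt, v), min_prominence = 10,
                     baseline_quantile = 0.01)
  expect_false(any(f$closure_ok_per_cycle))
})

test_that("flood-fill segmentation matches definition and BFS oracle", {
  img <- matrix(0, 40, 40)
  for (r in 1:40) for (c_ in 1:40)
    if ((r - 20)^2 + (c_ - 20)^2 <= 100) img[r, c_] <- 200
  seg <- segment_packet(img, c(20, 20), tolerance = 10)
  expect_equal(seg$area_px, sum(img == 200))
  expect_equal(seg$mean_intensity, 200)
  # tolerance 0 keeps only pixels exactly equal to the seed value
  img2 <- img
  img2[20, 21] <- 199
  seg0 <- segment_packet(img2, c(20, 20), tolerance = 0)
  expect_true(all(img2[seg0$pixels] == 200))
  expect_equal(seg0$area_px, sum(img2 == 200))
  # random blob vs the scalar-queue oracle, both connectivities
  set.seed(31)
  noisy <- matrix(sample(0:255, 30 * 30, TRUE), 30, 30)
  for (conn in c(4L, 8L)) {
    got <- segment_packet(noisy, c(15, 15), tolerance = 60,
                          connectivity = conn)
    px <- got$pixels[order(got$pixels[, 1], got$pixels[, 2]), ,
                     drop = FALSE]
    oracle <- flood_fill_oracle(noisy, c(15L, 15L), 60, conn)
    expect_equal(unname(px), unname(oracle))
  }
  # seed flagged as background
  expect_warning(bg <- segment_packet(img, c(1, 1), tolerance = 10,
                                      background_max = 50),
                 "background")
  expect_equal(bg$area_px, 1L)
  expect_error(segment_packet(img, c(0, 5), 1), "outside")
})

test_that("packet intensity series summarises per-cycle packets", {
  fr <- array(0, c(5, 30, 30))
  for (i in 1:5) fr[i, 10:20, 10:20] <- 120
  vs <- video_stack(fr, 0.01, 5)
  seeds <- data.frame(frame = 1:5, row = 15, col = 15)
  res <- packet_intensity_series(vs, seeds, tolerance = 10)
  expect_equal(res$mean_intensities, rep(120, 5))
  expect_equal(res$summary_mean, 120)
  expect_equal(res$n_excluded, 0L)
  # a seed landing on empty background is excluded from the summary
  fr[3, , ] <- 0
  vs2 <- video_stack(fr, 0.01, 5)
  expect_warning(
    res2 <- packet_intensity_series(vs2, seeds, tolerance = 10,
                                    background_max = 5),
    "background")
  expect_equal(res2$n_excluded, 1L)
  expect_equal(res2$summary_mean, 120)
  # attenuated packets report proportionally lower intensity
  fr[3, 10:20, 10:20] <- 60
  res3 <- packet_intensity_series(video_stack(fr, 0.01, 5), seeds, 10)
  expect_lt(res3$mean_intensities[3], res3$mean_intensities[1])
})

test_that("two-ROI velocimetry recovers delay-defined velocities", {
  tt <- seq(0, 5, by = 0.01)
  bump <- function(t0) 100 * exp(-(tt - t0)^2 / (2 * 0.03^2))
  post <- intensity_trace(tt, bump(1) + bump(2) + bump(3))
  ant <- intensity_trace(tt, bump(1.1) + bump(2.1) + bump(3.1))
  ve <- estimate_velocity(post, ant, distance = 0.5, n_cycles = 3)
  expect_equal(ve$velocity, 5, tolerance = 1e-6)      # 0.5 mm / 0.1 s
  expect_equal(ve$transit_times, rep(0.1, 3), tolerance = 1e-6)
  # one-frame delay at 100 fps over 0.05 mm is also 5 mm/s
  ant1 <- intensity_trace(tt, bump(1.01) + bump(2.01) + bump(3.01))
  ve1 <- estimate_velocity(post, ant1, distance = 0.05, n_cycles = 3)
  expect_equal(ve1$velocity, 5, tolerance = 1e-6)
  # anterior trace missing a matching peak errors, listing the orphan
  ant2 <- intensity_trace(tt, bump(1.1) + bump(2.1))
  expect_error(estimate_velocity(post, ant2, 0.5, n_cycles = 3),
               "unmatched")
  expect_error(estimate_velocity(post, ant, 0), "positive")
})

test_that("velocity estimator is unbiased on noise-free synthetic videos", {
  # error bounded by frame quantisation: dt * v^2 / (distance + dt * v)
  # is the worst-case relative bound; sub-frame refinement does better
  for (v in c(2, 8)) {
    p <- scene_params(duration = 4, packet_velocity = v, noise_sd = 0,
                      background_drift_per_s = 0)
    g <- generate_heart_video(p, channels = "dye")
    bs <- subtract_background(g$video)
    trP <- extract_trace(bs, roi_spec(17, 57, 15, 15))
    trA <- extract_trace(bs, roi_spec(17, 150, 15, 15))
    ve <- estimate_velocity(trP, trA, distance = (157 - 64) * 5 / 1000,
                            n_cycles = 3, refine_peaks = TRUE)
    expect_equal(ve$velocity, v, tolerance = 0.05)
  }
})
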