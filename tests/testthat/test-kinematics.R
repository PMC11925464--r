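lobe_stack <- function(gaps_px, h = 40, w = 30, px = 1, dt = 0.005,
                       axis = (h + 1) / 2, cols = 13:17) {
  a <- array(0, c(length(gaps_px), h, w))
  for (i in seq_along(gaps_px)) {
    half_g <- max(gaps_px[i] / 2, 0.5)
    top_last <- floor(axis - half_g)
    bot_first <- max(ceiling(axis + half_g), top_last + 2)
    a[i, 5:top_last, cols] <- 200
    a[i, bot_first:(h - 4), cols] <- 200
  }
  video_stack(a, dt, px, channel_names = "valve")
}

test_that("gap measurement is the perpendicular boundary distance", {
  # two rectangles separated by 10 empty rows at 1 um/px: gap 10 um
  a <- array(0, c(1, 40, 30))
  a[1, 5:14, 10:20] <- 200
  a[1, 25:34, 10:20] <- 200
  vs <- video_stack(a, 0.01, 1, channel_names = "valve")
  gt <- gap_trace(vs)
  expect_equal(gt$gap, 10)
  # touching lobes (fused into one component) read gap 0
  b <- array(0, c(1, 40, 30))
  b[1, 5:19, 10:20] <- 200
  b[1, 20:34, 10:20] <- 200
  expect_equal(gap_trace(video_stack(b, 0.01, 1,
                                     channel_names = "valve"))$gap, 0)
  # one empty row between the lobes reads one pixel of gap
  b2 <- array(0, c(1, 40, 30))
  b2[1, 5:19, 10:20] <- 200
  b2[1, 21:34, 10:20] <- 200
  expect_equal(gap_trace(video_stack(b2, 0.01, 1,
                                     channel_names = "valve"))$gap, 1)
  # pixel size scales the physical gap
  expect_equal(gap_trace(video_stack(a, 0.01, 2.5,
                                     channel_names = "valve"))$gap, 25)
})

test_that("gap matches an exhaustive perpendicular pair-distance oracle", {
  set.seed(41)
  for (rep in 1:5) {
    a <- array(0, c(1, 36, 36))
    # two random-ish blobs above and below the midline
    r1 <- sample(6:12, 1); r2 <- sample(24:30, 1)
    a[1, 4:r1, 10:24] <- 200
    a[1, r2:32, 10:24] <- 200
    a[1, 4:(r1 - 2), 8:26] <- 200           # ragged shoulders
    a[1, (r2 + 2):32, 8:26] <- 200
    vs <- video_stack(a, 0.01, 1, channel_names = "valve")
    got <- gap_trace(vs, angle_tol_deg = 5)$gap
    # oracle: all boundary-pixel pairs, perpendicular within 5 degrees
    m <- a[1, , ] > 100
    lab <- EBImage::bwlabel(m)
    bpix <- function(id) {
      out <- NULL
      for (r in 1:36) for (c_ in 1:36) {
        if (lab[r, c_] != id) next
        nb <- c(if (r > 1) lab[r - 1, c_] else 0,
                if (r < 36) lab[r + 1, c_] else 0,
                if (c_ > 1) lab[r, c_ - 1] else 0,
                if (c_ < 36) lab[r, c_ + 1] else 0)
        if (any(nb != id)) out <- rbind(out, c(r, c_))
      }
      out
    }
    b1 <- bpix(1); b2 <- bpix(2)
    best <- Inf
    for (i in seq_len(nrow(b1))) for (j in seq_len(nrow(b2))) {
      dr <- b2[j, 1] - b1[i, 1]; dc <- b2[j, 2] - b1[i, 2]
      ang <- atan2(-dr, dc) * 180 / pi
      if (abs(((ang - 90 + 90) %% 180) - 90) > 5) next
      best <- min(best, sqrt(dr^2 + dc^2))
    }
    expect_equal(got, max(best - 1, 0))
  }
})

test_that("frames without two components interpolate when isolated", {
  vs <- lobe_stack(c(6, 6, 6, 6, 6))
  vs$frames[3, 2:3, 25:28] <- 200            # stray speck: 3 components
  gt <- gap_trace(vs)
  expect_equal(gt$invalid_frames, 3L)
  expect_equal(gt$gap[3], mean(gt$gap[c(2, 4)]))
  vs$frames[4, , ] <- vs$frames[3, , ]       # now a run of two: error
  expect_error(gap_trace(vs), "cannot be interpolated")
})

test_that("peak opening distance averages per-event maxima", {
  # raised-cosine gap peaking at 20 um, 2 beats/s sampled at 200 fps
  tt <- seq(0, 3.995, by = 0.005)
  gap <- 20 * 0.5 * (1 - cos(2 * pi * 2 * tt))
  tr <- valve_gap_trace(tt, gap, pixel_size = 1)
  expect_equal(peak_open_distance(tr, n_beats = 5), 20, tolerance = 0.01)
  # halving the opening halves the peak
  tr2 <- valve_gap_trace(tt, gap / 2, pixel_size = 1)
  expect_equal(peak_open_distance(tr2, n_beats = 5), 10, tolerance = 0.01)
  # permanently closed valve has no opening events
  tr0 <- valve_gap_trace(tt, rep(0, length(tt)), pixel_size = 1)
  expect_error(peak_open_distance(tr0, n_beats = 5), "0 opening")
  # intensity rescaling of the label channel does not change the gap
  vs <- lobe_stack(rep(c(2, 8), 5))
  g1 <- gap_trace(vs)$gap
  vs$frames <- vs$frames * 0.6
  expect_equal(gap_trace(vs, threshold = 60)$gap, g1)
})

test_that("opening durations span closed state to closed state", {
  # square wave: open 0.2 s, closed 0.3 s -> close-to-close 0.5 s
  dt <- 0.005
  tt <- seq(0, 5 - dt, by = dt)
  phase <- tt %% 0.5
  gap <- ifelse(phase < 0.2, 10, 0)
  ev <- opening_durations(valve_gap_trace(tt, gap, pixel_size = 1),
                          closure_threshold = 1, n_beats = 8)
  expect_equal(ev$status, "ok")
  expect_equal(ev$events$duration, rep(0.5, nrow(ev$events)),
               tolerance = 1e-9)
  expect_equal(ev$mean_duration, 0.5, tolerance = 1e-9)
  # valve that never closes: explicit cannot-estimate status
  ev2 <- opening_durations(valve_gap_trace(tt, gap + 5, pixel_size = 1),
                           closure_threshold = 1)
  expect_equal(ev2$status, "cannot_estimate")
  expect_equal(nrow(ev2$events), 0L)
  expect_true(is.na(ev2$mean_duration))
})

test_that("generator kinematics are recovered within raster precision", {
  p <- scene_params(duration = 5, noise_sd = 0)
  g <- generate_heart_video(p)
  gt <- gap_trace(g$video)
  expect_lt(max(abs(gt$gap - g$truth$valve_gap)), p$pixel_size + 1e-9)
  # close-to-close duration is one beat period
  ev <- opening_durations(gt, n_beats = 8)
  expect_equal(ev$mean_duration, 1 / p$beat_rate,
               tolerance = 1 / p$frame_rate)
  # peak opening tracks the commanded opening fraction
  expect_equal(peak_open_distance(gt, n_beats = 5),
               p$valve_opening_fraction * p$tube_width,
               tolerance = p$pixel_size)
  p2 <- scene_params(duration = 5, noise_sd = 0,
                     valve_opening_fraction = 0.5)
  g2 <- generate_heart_video(p2)
  expect_equal(peak_open_distance(gap_trace(g2$video), n_beats = 5),
               0.5 * p2$tube_width, tolerance = p2$pixel_size)
})
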