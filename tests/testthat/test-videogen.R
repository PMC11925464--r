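test_that("scene generation is deterministic given parameters and seed", {
  p <- scene_params(duration = 2, image_size = c(32L, 96L), seed = 42L,
                    valve_position_col = 32)
  g1 <- generate_heart_video(p)
  g2 <- generate_heart_video(p)
  expect_identical(g1$video$frames, g2$video$frames)
  expect_identical(g1$truth$beat_times, g2$truth$beat_times)
  pp <- particle_scene_params(duration = 0.5, seed = 7L)
  q1 <- generate_particle_video(pp, 3)
  q2 <- generate_particle_video(pp, 3)
  expect_identical(q1$video$frames, q2$video$frames)
})

test_that("scene parameter validation rejects degenerate inputs", {
  expect_error(scene_params(frame_rate = 0), "frame_rate")
  expect_error(scene_params(pixel_size = -1), "pixel_size")
  expect_error(scene_params(valve_opening_fraction = 1.2), "0, 1")
  expect_error(scene_params(arrest_intervals = list(c(5, 4))), "arrest")
  expect_error(scene_params(duration = 10,
                            arrest_intervals = list(c(2, 12))), "arrest")
  expect_error(scene_params(duration = 10,
                            arrest_intervals = list(c(1, 4), c(3, 6))),
               "overlap")
})

test_that("a fully arrested zero-velocity scene is static after drift removal", {
  p <- scene_params(duration = 1, image_size = c(32L, 96L), noise_sd = 0,
                    packet_velocity = 0, background_drift_per_s = 2,
                    arrest_intervals = list(c(0, 1)),
                    valve_position_col = 32)
  g <- generate_heart_video(p, channels = "dye")
  tt <- frame_times(g$video)
  for (i in seq_len(n_frames(g$video))) {
    dedrifted <- g$video$frames[i, , ] - p$background_drift_per_s * tt[i]
    expect_equal(dedrifted, g$video$frames[1, , ], tolerance = 1e-12)
  }
  expect_length(g$truth$beat_times, 0)
  expect_equal(nrow(g$truth$packet_centroids), 0)
})

test_that("beat bookkeeping: one packet per beat outside arrests", {
  p <- scene_params(duration = 5, beat_rate = 2, image_size = c(32L, 96L),
                    valve_position_col = 32, noise_sd = 0)
  g <- generate_heart_video(p, channels = "dye")
  expect_length(g$truth$beat_times, 10L)
  pa <- scene_params(duration = 10, beat_rate = 2,
                     image_size = c(32L, 96L), valve_position_col = 32,
                     noise_sd = 0, arrest_intervals = list(c(3, 6)))
  ga <- generate_heart_video(pa, channels = "dye")
  in_arrest <- ga$truth$beat_times >= 3 & ga$truth$beat_times < 6
  expect_false(any(in_arrest))
  expect_length(ga$truth$beat_times, 20L - 6L)
  expect_equal(sort(unique(ga$truth$packet_centroids$packet)),
               seq_along(ga$truth$beat_times))
})

test_that("packet centroids advance at the commanded velocity", {
  # 5 mm/s at 100 fps and 5 um/px is exactly 10 px per frame
  p <- scene_params(duration = 3, packet_velocity = 5, noise_sd = 0,
                    image_size = c(32L, 192L), valve_position_col = 16)
  g <- generate_heart_video(p, channels = "dye")
  expected_step <- p$packet_velocity * 1000 / (p$pixel_size * p$frame_rate)
  for (s in split(g$truth$packet_centroids, g$truth$packet_centroids$packet)) {
    if (nrow(s) < 2L) next
    expect_equal(diff(s$col), rep(expected_step, nrow(s) - 1L),
                 tolerance = 1e-9)
  }
})

test_that("particle scenes obey continuity and record matching truth", {
  pp <- particle_scene_params(duration = 1, seed = 3L)
  for (vof in c(1, 0.5)) {
    g <- generate_particle_video(
      particle_scene_params(duration = 1, seed = 3L,
                            valve_opening_fraction = vof), 4)
    for (tr in g$truth$particle_tracks) {
      flux <- tr$speed * gap_profile_um(g$truth$params, tr$col)
      expect_lt(diff(range(flux)) / mean(flux), 0.01)
    }
    speeds <- unlist(lapply(g$truth$particle_tracks, `[[`, "speed"))
    v0 <- pp$packet_velocity * 1000
    if (vof == 1) {
      expect_lt(diff(range(speeds)) / mean(speeds), 1e-9)
    } else {
      expect_gt(max(speeds), 1.85 * v0)   # peak at the constriction
      expect_lt(max(speeds), 2.001 * v0)  # bounded by the continuity ratio
    }
  }
})

test_that("particle density above the collision-free capacity errors", {
  pp <- particle_scene_params(duration = 0.1)
  expect_error(generate_particle_video(pp, 500), "capacity")
})

test_that("a single noise-free particle is the brightest pixel near truth", {
  pp <- particle_scene_params(duration = 0.5, noise_sd = 0)
  g <- generate_particle_video(pp, 1)
  truth <- do.call(rbind, g$truth$particle_tracks)
  for (i in seq(1L, n_frames(g$video), by = 7L)) {
    fr <- g$video$frames[i, , , 1L]
    am <- which(fr == max(fr), arr.ind = TRUE)[1L, ]
    tp <- truth[truth$frame == i, ]
    expect_lt(max(abs(c(am[1L] - tp$row, am[2L] - tp$col))), 1 + 1e-9)
  }
})

test_that("fiber textures have the commanded orientation structure", {
  # pure horizontal stripes: constant along each row
  ft0 <- generate_fiber_texture(0, coherence = 1, size = 128)
  expect_equal(max(apply(ft0$image, 1L, function(r) diff(range(r)))), 0)
  # pure noise: angular spectrum flat within sampling error
  ftn <- generate_fiber_texture(0, coherence = 0, size = 256, seed = 5)
  dh <- directionality_histogram(ftn$image)
  expect_lt(max(dh$amplitudes), 2 * mean(dh$amplitudes))
  # 45-degree stripes: FFT argmax oracle finds the spectral angle
  ft45 <- generate_fiber_texture(pi / 4, coherence = 1, size = 128)
  img <- ft45$image - mean(ft45$image)
  P <- Mod(stats::fft(img))^2
  fr <- (seq_len(128) - 1) / 128; fr[fr > 0.5] <- fr[fr > 0.5] - 1
  FR <- matrix(fr, 128, 128); FC <- matrix(fr, 128, 128, byrow = TRUE)
  P[1, 1] <- 0
  am <- which(P == max(P), arr.ind = TRUE)[1L, ]
  ang <- atan2(FC[am[1L], am[2L]], FR[am[1L], am[2L]]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  expect_lt(abs(ang - 45), 2)
  expect_error(generate_fiber_texture(0, coherence = 2, size = 64),
               "coherence")
})

test_that("crawl sequences follow the path and expose true shape", {
  cp <- crawl_scene_params(duration = 8, image_size = c(300L, 300L))
  # closed square path returns to its start: zero net displacement
  sq <- rbind(c(100, 100), c(100, 200), c(200, 200), c(200, 100),
              c(100, 100))
  g <- generate_crawl_sequence(cp, sq, bend_schedule = 0)
  tc <- g$truth$centroids
  # zero up to the supersampled-raster integration residual
  expect_lt(sqrt((tc$row[nrow(tc)] - tc$row[1L])^2 +
                   (tc$col[nrow(tc)] - tc$col[1L])^2), 0.2)
  # rendered mask centroid tracks the true centroid to sub-pixel accuracy
  ct <- centroid_track(g$video)
  err <- sqrt((ct$points$row - tc$row)^2 + (ct$points$col - tc$col)^2)
  expect_lt(max(err), 0.5)
  # straight, unbent larva: truth-ellipse roundness is the axis ratio
  shp <- g$truth$larva_shape_series
  ellipse_area <- pi * shp$major_um * shp$minor_um / 4
  roundness <- 4 * ellipse_area / (pi * shp$major_um^2)
  expect_equal(roundness, shp$minor_um / shp$major_um, tolerance = 1e-12)
})

test_that("a silhouette leaving the frame stops the generator", {
  cp <- crawl_scene_params(duration = 2, image_size = c(200L, 200L))
  run <- rbind(c(100, 100), c(100, 195))
  expect_error(generate_crawl_sequence(cp, run, bend_schedule = 0),
               "leaves the frame")
  expect_error(generate_crawl_sequence(cp, rbind(c(100, 250)), 0),
               "inside the image")
})
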