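blob_frame <- function(pts, h = 64, w = 96, amp = 200, sigma = 1.5,
                       base = 5) {
  fr <- matrix(base, h, w)
  for (i in seq_len(nrow(pts)))
    fr <- valveflow:::add_gaussian_blob(fr, pts[i, 1], pts[i, 2], amp, sigma)
  fr
}

test_that("spot detection is sub-pixel accurate and counts spots", {
  fr <- blob_frame(rbind(c(50.0, 80.0)))
  d <- detect_spots(fr, 1.5, 10)
  expect_equal(nrow(d), 1L)
  expect_lt(max(abs(c(d$row - 50, d$col - 80))), 0.25)
  # off-grid centre still within 0.25 px
  fr2 <- blob_frame(rbind(c(30.4, 40.7)))
  d2 <- detect_spots(fr2, 1.5, 10)
  expect_lt(max(abs(c(d2$row - 30.4, d2$col - 40.7))), 0.25)
  # blank frame: nothing
  expect_equal(nrow(detect_spots(matrix(5, 64, 96), 1.5, 10)), 0L)
  # two spots 10 sigma apart: exactly two detections
  fr3 <- blob_frame(rbind(c(20, 30), c(20, 45)))
  expect_equal(nrow(detect_spots(fr3, 1.5, 10)), 2L)
})

test_that("linking follows single and parallel particles without swaps", {
  # one particle moving 2 px/frame
  det <- lapply(0:19, function(i) data.frame(row = 10, col = 5 + 2 * i))
  tk <- link_tracks(det, max_disp = 5)
  expect_length(tk, 1L)
  expect_equal(nrow(tk[[1]]$points), 20L)
  # two parallel particles far beyond max_disp: two tracks, no swaps
  det2 <- lapply(0:19, function(i)
    data.frame(row = c(10, 40), col = 5 + 2 * i))
  tk2 <- link_tracks(det2, max_disp = 5)
  expect_length(tk2, 2L)
  expect_true(all(tk2[[1]]$points$row == 10))
  expect_true(all(tk2[[2]]$points$row == 40))
  # a gap of one missed frame is bridged when max_gap allows
  det3 <- det
  det3[[10]] <- data.frame(row = numeric(0), col = numeric(0))
  expect_length(link_tracks(det3, max_disp = 5, max_gap = 0), 2L)
  expect_length(link_tracks(det3, max_disp = 5, max_gap = 1), 1L)
})

test_that("greedy linking matches the exhaustive assignment oracle", {
  set.seed(51)
  for (rep in 1:10) {
    # non-crossing walkers: rows separated well beyond the step scale, so
    # the cost matrix is non-degenerate and greedy matches the optimum
    n <- 5L
    a <- cbind(seq(10, 58, by = 12) + runif(n, -1, 1), runif(n, 10, 80))
    step <- cbind(runif(n, -2, 2), runif(n, -2, 2))
    b <- a + step
    det <- list(data.frame(row = a[, 1], col = a[, 2]),
                data.frame(row = b[, 1], col = b[, 2]))
    tk <- link_tracks(det, max_disp = 6)
    links <- vapply(tk, function(t) nrow(t$points), integer(1L))
    expect_true(all(links == 2L))
    # greedy result against minimum-cost perfect matching
    cost <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      sqrt(sum((a[i, ] - b[j, ])^2))))
    oracle <- min_cost_assignment(cost)$assignment
    got <- integer(n)
    for (t in tk) {
      i <- which(abs(a[, 1] - t$points$row[1]) < 1e-9)
      j <- which(abs(b[, 1] - t$points$row[2]) < 1e-9)
      got[i] <- j
    }
    expect_equal(got, oracle)
  }
})

test_that("track metrics match their geometric definitions", {
  # straight 10-step line, 1 um steps at 1 s intervals
  p <- data.frame(t = 0:10, row = 0:10, col = rep(0, 11))
  m <- compute_track_metrics(p, pixel_size = 1)
  expect_equal(m$total_distance, 10)
  expect_equal(m$displacement, 10)
  expect_equal(m$confinement_ratio, 1)
  expect_equal(m$mean_speed, 1)
  expect_equal(m$peak_speed, 1)
  # closed square loop: zero displacement and confinement
  sq <- data.frame(t = 0:8,
                   row = c(0, 0, 0, 1, 2, 2, 2, 1, 0),
                   col = c(0, 1, 2, 2, 2, 1, 0, 0, 0))
  ms <- compute_track_metrics(sq, pixel_size = 2)
  expect_equal(ms$displacement, 0)
  expect_equal(ms$confinement_ratio, 0)
  expect_equal(ms$total_distance, 8 * 2)
  # random walk against a step-sum oracle
  set.seed(52)
  rw <- data.frame(t = cumsum(runif(30, 0.5, 1.5)),
                   row = cumsum(rnorm(30)), col = cumsum(rnorm(30)))
  mr <- compute_track_metrics(rw, pixel_size = 2.5)
  tot <- 0; pk <- 0
  for (i in 2:30) {
    s <- 2.5 * sqrt((rw$row[i] - rw$row[i - 1])^2 +
                      (rw$col[i] - rw$col[i - 1])^2)
    tot <- tot + s
    pk <- max(pk, s / (rw$t[i] - rw$t[i - 1]))
  }
  expect_equal(mr$total_distance, tot)
  expect_equal(mr$peak_speed, pk)
  expect_gte(mr$confinement_ratio, 0)
  expect_lte(mr$confinement_ratio, 1)
  expect_error(compute_track_metrics(data.frame(t = c(0, 0), row = 1:2,
                                                col = 1:2), 1),
               "timestamps")
})

test_that("confinement ratio is 1 only for collinear monotone motion", {
  set.seed(53)
  for (rep in 1:20) {
    p <- data.frame(t = 0:10, row = cumsum(runif(11)),
                    col = cumsum(runif(11)))
    m <- compute_track_metrics(p, 1)
    expect_gte(m$confinement_ratio, 0)
    expect_lte(m$confinement_ratio, 1 + 1e-12)
  }
  line <- data.frame(t = 0:5, row = seq(0, 10, 2), col = seq(0, 5, 1))
  expect_equal(compute_track_metrics(line, 1)$confinement_ratio, 1,
               tolerance = 1e-12)
})

test_that("region gating takes the maximum step speed inside the region", {
  p <- data.frame(t = 0:4, row = rep(10, 5), col = c(0, 2, 6, 12, 14))
  region <- matrix(FALSE, 20, 20)
  region[, 8:12] <- TRUE                    # covers the fast middle step
  g <- gate_speeds_by_region(list(p), region, pixel_size = 1)
  expect_equal(g$peak_speeds$peak_speed, 6)  # step 6 px, midpoint col 9
  # whole-frame region equals the track's peak speed
  all_region <- matrix(TRUE, 20, 20)
  expect_equal(gate_speeds_by_region(list(p), all_region, 1)$peak_speeds$peak_speed,
               compute_track_metrics(p, 1)$peak_speed)
  # a track that never enters the region is excluded and counted
  far <- data.frame(t = 0:2, row = rep(1, 3), col = c(1, 2, 3))
  region2 <- matrix(FALSE, 20, 20); region2[15:20, ] <- TRUE
  g2 <- gate_speeds_by_region(list(p, far), region2, 1)
  expect_equal(g2$n_excluded, 2L)
  expect_error(gate_speeds_by_region(list(p), matrix(FALSE, 5, 5), 1),
               "empty")
})

test_that("the full pipeline recovers planted particle motion", {
  pp <- particle_scene_params(duration = 1.5, seed = 9L, noise_sd = 0)
  g <- generate_particle_video(pp, 4)
  det <- detect_spots_stack(g$video, 1.5, 10, channel = "particles")
  tk <- link_tracks(det, max_disp = 8,
                    frame_interval = g$video$frame_interval)
  truth <- g$truth$particle_tracks
  # match every linked point to the nearest truth point in its frame
  truth_all <- do.call(rbind, truth)
  n_pts <- 0L; n_good <- 0L
  for (t in tk) {
    for (i in seq_len(nrow(t$points))) {
      cand <- truth_all[truth_all$frame == t$points$frame[i], ]
      d <- sqrt((cand$row - t$points$row[i])^2 +
                  (cand$col - t$points$col[i])^2)
      n_pts <- n_pts + 1L
      if (min(d) < 1) n_good <- n_good + 1L
    }
  }
  expect_gte(n_good / n_pts, 0.95)
  # recovered step speeds within 10% of the local truth speed
  errs <- c()
  for (t in tk) {
    p <- t$points
    if (nrow(p) < 6L) next
    for (i in 2:nrow(p)) {
      sp <- sqrt((p$row[i] - p$row[i - 1])^2 +
                   (p$col[i] - p$col[i - 1])^2) *
        pp$pixel_size / (p$t[i] - p$t[i - 1])
      mid <- (p$col[i] + p$col[i - 1]) / 2
      true_sp <- speed_profile_mm_s(pp, mid) * 1000
      errs <- c(errs, abs(sp / true_sp - 1))
    }
  }
  expect_lt(stats::quantile(errs, 0.99), 0.1)
})

test_that("larva centroid tracks feed the crawling metrics", {
  cp <- crawl_scene_params(duration = 6, image_size = c(260L, 260L))
  path <- rbind(c(130, 70), c(130, 190))
  g <- generate_crawl_sequence(cp, path, bend_schedule = 0)
  ct <- centroid_track(g$video)
  m <- compute_track_metrics(ct, cp$pixel_size)
  true_len <- 120 * cp$pixel_size
  expect_equal(m$displacement, true_len, tolerance = 0.02 * true_len)
  expect_gt(m$confinement_ratio, 0.95)
})
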