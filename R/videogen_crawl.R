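# Minimum distance from points (r, c) to segment (r1,c1)-(r2,c2), vectorised.
dist_to_segment <- function(r, c, r1, c1, r2, c2) {
  dr <- r2 - r1; dc <- c2 - c1
  len2 <- dr * dr + dc * dc
  if (len2 == 0) return(sqrt((r - r1)^2 + (c - c1)^2))
  u <- pmin(pmax(((r - r1) * dr + (c - c1) * dc) / len2, 0), 1)
  sqrt((r - r1 - u * dr)^2 + (c - c1 - u * dc)^2)
}

# Evaluate the bent-capsule silhouette on a supersampled grid around joint
# (jr, jc); returns logical matrix plus the grid coordinates.
capsule_grid <- function(jr, jc, heading, bend, half_len, half_wid, ss,
                         clip = NULL) {
  a_ang <- heading + bend / 2
  p_ang <- heading + pi - bend / 2
  ar <- jr + half_len * sin(a_ang); ac <- jc + half_len * cos(a_ang)
  pr <- jr + half_len * sin(p_ang); pc <- jc + half_len * cos(p_ang)
  pad <- half_wid + 1
  rlo <- min(jr, ar, pr) - pad; rhi <- max(jr, ar, pr) + pad
  clo <- min(jc, ac, pc) - pad; chi <- max(jc, ac, pc) + pad
  rs <- seq(rlo, rhi, by = 1 / ss)
  cs <- seq(clo, chi, by = 1 / ss)
  g <- expand.grid(r = rs, c = cs)
  d <- pmin(dist_to_segment(g$r, g$c, jr, jc, ar, ac),
            dist_to_segment(g$r, g$c, jr, jc, pr, pc))
  inside <- d <= half_wid
  list(r = g$r[inside], c = g$c[inside],
       ends = c(ar, ac, pr, pc))
}

#' Generate a synthetic crawling-larva silhouette sequence
#'
#' Renders the binary silhouette video the crawling assay analyses: a
#' capsule-shaped larva (body length `larva_length_um`, width
#' `larva_width_um`) whose centroid follows a waypoint path at constant
#' speed, and whose body bends at mid-length by the scheduled angle (0 =
#' straight forward crawl; larger angles emulate turning, which raises the
#' silhouette's roundness). Heading follows the local path tangent.
#'
#' The shape is positioned so that its true (continuous) centroid lies on
#' the interpolated path point of each frame; the ground truth records that
#' centroid together with the area and moment-ellipse axes of the
#' silhouette, evaluated on a supersampled grid independent of the rendered
#' pixel raster.
#'
#' A silhouette touching the image border stops the generator with an error
#' -- the live assay likewise discards larvae that reach the dish edge.
#'
#' @param params A [scene_params()]; see [crawl_scene_params()].
#' @param path_spec Numeric matrix/data frame of waypoints, columns
#'   `(row, col)` in px, all inside the image.
#' @param bend_schedule Bend angle in radians per frame (recycled).
#' @param larva_length_um,larva_width_um Body dimensions in um.
#'   Defaults 4500 and 800 (third-instar larva).
#' @return A list with `video` (binary mask [video_stack()], values
#'   0/255) and `truth` (class `ground_truth`) with `centroids`
#'   `(frame, t, row, col)` and `larva_shape_series`
#'   `(frame, area_um2, major_um, minor_um, orientation)`.
#' @export
generate_crawl_sequence <- function(params, path_spec, bend_schedule = 0,
                                    larva_length_um = 4500,
                                    larva_width_um = 800) {
  stopifnot(inherits(params, "scene_params"))
  wp <- as.matrix(path_spec)
  if (ncol(wp) != 2L || nrow(wp) < 1L)
    stop("`path_spec` must be a matrix of (row, col) waypoints",
         call. = FALSE)
  h <- params$image_size[1L]; w <- params$image_size[2L]
  if (any(wp[, 1L] < 1 | wp[, 1L] > h | wp[, 2L] < 1 | wp[, 2L] > w))
    stop("waypoints must lie inside the image bounds", call. = FALSE)
  nf <- max(1L, floor(params$duration * params$frame_rate))
  dt <- 1 / params$frame_rate
  px <- params$pixel_size
  bend <- rep_len(bend_schedule, nf)

  # constant-speed interpolation along the waypoint polyline
  if (nrow(wp) == 1L) {
    pos <- matrix(rep(wp[1L, ], each = nf), ncol = 2L)
  } else {
    seg <- sqrt(rowSums(diff(wp)^2))
    s_cum <- c(0, cumsum(seg))
    s_frame <- seq(0, s_cum[length(s_cum)], length.out = nf)
    pos <- cbind(stats::approx(s_cum, wp[, 1L], xout = s_frame,
                               ties = "ordered")$y,
                 stats::approx(s_cum, wp[, 2L], xout = s_frame,
                               ties = "ordered")$y)
  }
  # heading from the path tangent; hold the last heading when stationary
  heading <- numeric(nf)
  hprev <- 0
  for (i in seq_len(nf)) {
    j <- min(i + 1L, nf)
    dr <- pos[j, 1L] - pos[max(i - 1L, 1L), 1L]
    dc <- pos[j, 2L] - pos[max(i - 1L, 1L), 2L]
    if (abs(dr) + abs(dc) > 1e-9) hprev <- atan2(dr, dc)
    heading[i] <- hprev
  }

  half_len <- larva_length_um / px / 2
  half_wid <- larva_width_um / px / 2
  ss <- 4L
  frames <- array(0, dim = c(nf, h, w))
  cent <- matrix(0, nf, 2L)
  shp <- matrix(0, nf, 4L)

  for (i in seq_len(nf)) {
    # first pass: continuous centroid offset of the bent shape
    g0 <- capsule_grid(0, 0, heading[i], bend[i], half_len, half_wid, ss)
    off_r <- mean(g0$r); off_c <- mean(g0$c)
    jr <- pos[i, 1L] - off_r; jc <- pos[i, 2L] - off_c
    g <- capsule_grid(jr, jc, heading[i], bend[i], half_len, half_wid, ss)
    if (min(g$r) < 0.5 || max(g$r) > h + 0.5 ||
        min(g$c) < 0.5 || max(g$c) > w + 0.5)
      stop(sprintf(paste0("silhouette leaves the frame at frame %d ",
                          "(t = %.2f s); shorten the path or enlarge the ",
                          "image (larvae reaching the dish edge are ",
                          "discarded)"), i, (i - 1) * dt), call. = FALSE)
    # ground truth from the supersampled grid
    n_sup <- length(g$r)
    area_um2 <- n_sup / ss^2 * px^2
    mr <- mean(g$r); mc <- mean(g$c)
    mrr <- mean((g$r - mr)^2); mcc <- mean((g$c - mc)^2)
    mrc <- mean((g$r - mr) * (g$c - mc))
    eg <- eigen(matrix(c(mrr, mrc, mrc, mcc), 2L, 2L), symmetric = TRUE)
    major_um <- 4 * sqrt(eg$values[1L]) * px
    minor_um <- 4 * sqrt(max(eg$values[2L], 0)) * px
    orient <- fold_axial(atan2(-eg$vectors[1L, 1L], eg$vectors[2L, 1L]))
    cent[i, ] <- c(mr, mc)
    shp[i, ] <- c(area_um2, major_um, minor_um, orient)
    # rendered binary mask: pixel centres inside the capsule
    rr <- max(1L, floor(min(g$r))):min(h, ceiling(max(g$r)))
    cc <- max(1L, floor(min(g$c))):min(w, ceiling(max(g$c)))
    gg <- expand.grid(r = rr, c = cc)
    e <- g$ends
    d <- pmin(dist_to_segment(gg$r, gg$c, jr, jc, e[1L], e[2L]),
              dist_to_segment(gg$r, gg$c, jr, jc, e[3L], e[4L]))
    m <- matrix(0, h, w)
    m[cbind(gg$r[d <= half_wid], gg$c[d <= half_wid])] <- 255
    frames[i, , ] <- m
  }

  video <- video_stack(frames, frame_interval = dt, pixel_size = px,
                       channel_names = "mask")
  truth <- structure(
    list(centroids = data.frame(frame = seq_len(nf),
                                t = (seq_len(nf) - 1) * dt,
                                row = cent[, 1L], col = cent[, 2L]),
         larva_shape_series = data.frame(frame = seq_len(nf),
                                         area_um2 = shp[, 1L],
                                         major_um = shp[, 2L],
                                         minor_um = shp[, 3L],
                                         orientation = shp[, 4L]),
         params = params),
    class = "ground_truth")
  list(video = video, truth = truth)
}

#' Generate an oriented fiber texture with known orientation
#'
#' Produces the test input for Fourier directionality analysis: a sinusoidal
#' stripe pattern at orientation `theta` mixed with isotropic Gaussian noise
#' in proportion `coherence` (1 = pure stripes, 0 = pure noise), rescaled to
#' 8-bit. Orientation follows the package convention: 0 = horizontal
#' structures (constant along rows), positive angles rotate
#' counter-clockwise with the row axis pointing down, axial modulo 180
#' degrees.
#'
#' @param theta True fiber orientation in radians.
#' @param coherence Stripe fraction in \[0, 1\].
#' @param size Image side length in px (single integer).
#' @param seed RNG seed for the noise component.
#' @param frequency Stripe spatial frequency in cycles/px. Default 0.15.
#' @return A list with `image` (numeric `size x size` matrix in \[0, 255\])
#'   and `theta` (the true orientation, radians).
#' @export
generate_fiber_texture <- function(theta, coherence, size, seed = 1L,
                                   frequency = 0.15) {
  if (!is.numeric(coherence) || coherence < 0 || coherence > 1)
    stop("`coherence` must be in [0, 1]", call. = FALSE)
  size <- as.integer(size)
  if (size < 8L) stop("`size` must be >= 8 px", call. = FALSE)
  r <- matrix(seq_len(size), size, size)
  c_ <- matrix(seq_len(size), size, size, byrow = TRUE)
  stripes <- sin(2 * pi * frequency * (r * cos(theta) + c_ * sin(theta)))
  img <- with_scene_seed(seed, {
    noise <- matrix(stats::rnorm(size * size, sd = sqrt(0.5)), size, size)
    coherence * stripes + (1 - coherence) * noise
  })
  rng <- range(img)
  if (rng[1L] == rng[2L]) {
    img8 <- matrix(128, size, size)
  } else {
    img8 <- (img - rng[1L]) / (rng[2L] - rng[1L]) * 255
  }
  list(image = img8, theta = theta)
}
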