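#' Luminal gap and advection speed profiles along the tube
#'
#' The static flow geometry of particle scenes. The luminal gap is the
#' full `tube_width` far from the valve and narrows to
#' `valve_opening_fraction * tube_width` at the valve plane with a
#' Gaussian axial profile of scale `valve_sigma_um` (a malformed valve's
#' narrowed lumen is a persistent obstruction). Advection speed follows
#' 1-D continuity, `speed * gap = const`, so
#' `speed(col) = packet_velocity * tube_width / gap(col)`, peaking at the
#' constriction.
#'
#' @param params A [scene_params()].
#' @param col_px Column positions in px (vectorised).
#' @return `gap_profile_um()`: gap in um; `speed_profile_mm_s()`: speed in
#'   mm/s.
#' @export
gap_profile_um <- function(params, col_px) {
  x_um <- (col_px - params$valve_position_col) * params$pixel_size
  params$tube_width *
    (1 - (1 - params$valve_opening_fraction) *
       exp(-x_um^2 / (2 * params$valve_sigma_um^2)))
}

#' @rdname gap_profile_um
#' @export
speed_profile_mm_s <- function(params, col_px) {
  params$packet_velocity * params$tube_width / gap_profile_um(params, col_px)
}

#' Generate a synthetic two-channel particle streaming video
#'
#' Renders the particle-velocimetry assay: fluorescent tracer particles
#' advected anteriorly through the heart tube past the valve constriction.
#' Channel `"particles"` shows the particles as Gaussian spots; channel
#' `"valve"` is a static label over the region the valve cells span
#' (emulating a valve-cell GFP reporter, from which the gating region is
#' derived in analysis).
#'
#' Particle speed obeys 1-D continuity through the constriction: the local
#' luminal gap narrows to `valve_opening_fraction * tube_width` at the valve
#' plane with Gaussian axial profile `valve_sigma_um`, and speed scales as
#' `tube_width / gap`, so speed peaks at the valve -- at twice the upstream
#' speed for a half-closed lumen. Each particle keeps its own row (laminar
#' streamlines) and re-enters at the posterior margin after leaving the
#' field anteriorly, starting a new ground-truth track.
#'
#' Particles are seeded on distinct rows separated by at least
#' `4 * spot_sigma` pixels so rendered spots never overlap and tracks never
#' cross; requesting more particles than that packing allows is an error.
#'
#' @param params A [scene_params()]; see [particle_scene_params()] for the
#'   assay's preset conditions.
#' @param n_particles Number of particles (>= 1).
#' @param spot_sigma Rendered spot Gaussian sigma in px. Default 1.5.
#' @param spot_amplitude Peak spot intensity (8-bit). Default 200.
#' @return A list with `video` (two-channel [video_stack()]) and `truth`
#'   (class `ground_truth`) holding `particle_tracks`: a list of data
#'   frames `(t, frame, row, col, speed)` with `speed` the true local
#'   advection speed in um/s at each point, plus the valve-region mask
#'   (`valve_region`, logical matrix) and the scene `params`.
#' @export
generate_particle_video <- function(params, n_particles,
                                    spot_sigma = 1.5,
                                    spot_amplitude = 200) {
  stopifnot(inherits(params, "scene_params"))
  if (!is.numeric(n_particles) || length(n_particles) != 1L ||
      n_particles < 1 || n_particles != round(n_particles))
    stop("`n_particles` must be a positive integer", call. = FALSE)
  n_particles <- as.integer(n_particles)
  h <- params$image_size[1L]; w <- params$image_size[2L]
  nf <- max(1L, floor(params$duration * params$frame_rate))
  dt <- 1 / params$frame_rate
  px <- params$pixel_size

  half_w_px <- params$tube_width / px / 2
  row_lo <- params$tube_axis_row - half_w_px + 2
  row_hi <- params$tube_axis_row + half_w_px - 2
  min_sep <- 4 * spot_sigma
  capacity <- floor((row_hi - row_lo) / min_sep) + 1L
  if (n_particles > capacity)
    stop(sprintf(paste0("n_particles = %d exceeds the collision-free ",
                        "capacity of %d for this tube (%g px of luminal ",
                        "height at a minimum row separation of %g px)"),
                 n_particles, capacity, row_hi - row_lo, min_sep),
         call. = FALSE)

  col_lo <- 8; col_hi <- w - 8
  valve_half_cols <- 2 * params$valve_sigma_um / px
  region <- matrix(FALSE, h, w)
  tube_rows <- which(seq_len(h) >= params$tube_axis_row - half_w_px &
                       seq_len(h) <= params$tube_axis_row + half_w_px)
  region_cols <- which(abs(seq_len(w) - params$valve_position_col) <=
                         valve_half_cols)
  region[tube_rows, region_cols] <- TRUE

  rows0 <- seq(row_lo, row_hi, length.out = n_particles)
  tracks <- list()

  pvid <- array(0, dim = c(nf, h, w))
  vvid <- array(0, dim = c(nf, h, w))
  vlabel <- matrix(0, h, w)
  vlabel[region] <- 180

  with_scene_seed(params$seed, {
    cols <- seq(col_lo, col_hi, length.out = n_particles + 2L)[
      seq_len(n_particles) + 1L] + stats::runif(n_particles, -5, 5)
    cur_track <- seq_len(n_particles)
    next_id <- n_particles + 1L
    pts <- vector("list", n_particles)
    for (i in seq_len(nf)) {
      t <- (i - 1) * dt
      sp_um_s <- speed_profile_mm_s(params, cols) * 1000
      frame <- matrix(params$background_level, h, w)
      for (k in seq_len(n_particles)) {
        frame <- add_gaussian_blob(frame, rows0[k], cols[k],
                                   spot_amplitude, spot_sigma)
        pts[[k]] <- rbind(pts[[k]],
                          c(t = t, frame = i, row = rows0[k],
                            col = cols[k], speed = sp_um_s[k]))
      }
      if (params$noise_sd > 0)
        frame <- frame + matrix(stats::rnorm(h * w, sd = params$noise_sd),
                                h, w)
      pvid[i, , ] <- pmin(pmax(frame, 0), 255)
      vf <- vlabel
      if (params$noise_sd > 0)
        vf <- vf + matrix(stats::rnorm(h * w, sd = params$noise_sd), h, w)
      vvid[i, , ] <- pmin(pmax(vf, 0), 255)
      # advect; recycle particles leaving the anterior margin
      cols <- cols + sp_um_s * dt / px
      for (k in which(cols > col_hi)) {
        tracks[[cur_track[k]]] <- as.data.frame(pts[[k]])
        pts[k] <- list(NULL)
        cols[k] <- col_lo + stats::runif(1L, 0, 4)
        cur_track[k] <- next_id
        next_id <- next_id + 1L
      }
    }
    for (k in seq_len(n_particles))
      if (!is.null(pts[[k]]))
        tracks[[cur_track[k]]] <- as.data.frame(pts[[k]])
  })
  tracks <- tracks[!vapply(tracks, is.null, logical(1L))]

  frames <- array(0, dim = c(nf, h, w, 2L))
  frames[, , , 1L] <- pvid; frames[, , , 2L] <- vvid
  video <- video_stack(frames, frame_interval = dt, pixel_size = px,
                       channel_names = c("particles", "valve"))
  truth <- structure(
    list(particle_tracks = tracks,
         valve_region = region,
         params = params),
    class = "ground_truth")
  list(video = video, truth = truth)
}
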