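#' Scene parameters for the synthetic video generator
#'
#' Bundles every physical and imaging parameter of a synthetic scene. The
#' defaults describe the dye-angiography recording conditions: 30 s dorsal
#' view at ~100 frames/s of a prepupa whose heart pumps discrete hemolymph
#' packets anteriorly through the aorta at roughly 5.2 mm/s, beating at
#' about 2 Hz, with a pair of intracardiac valve cells gating the aortic
#' inlet. Because the original recordings carry no stated optical
#' calibration, `pixel_size` here is a generator choice (5 um/px gives a
#' 240 x 960 um field covering the aorta), not a measured value; analyses of
#' real data must always be given their own calibration.
#'
#' `valve_opening_fraction` is the key biological dial: 1 means the valve
#' opens to the full tube lumen each systole (wildtype-like); values below 1
#' emulate malformed valves whose peak luminal opening is reduced.
#' `valve_min_gap_fraction` raises the diastolic floor of the gap, emulating
#' valves that can no longer seal the lumen at all.
#'
#' @param frame_rate Frames per second (> 0). Default 100.
#' @param duration Recording length in seconds. Default 30.
#' @param image_size Integer `(rows, cols)`. Default `c(48, 192)`.
#' @param pixel_size um per pixel (> 0). Default 5.
#' @param tube_axis_row Row of the tube centreline (may be fractional;
#'   default centred).
#' @param tube_width Luminal width of the heart tube in um. Default 40.
#' @param beat_rate Heartbeats per second. Default 2.
#' @param packet_velocity Anterograde packet/particle velocity in mm/s.
#'   Default 5.2.
#' @param valve_opening_fraction Peak luminal opening as a fraction of
#'   `tube_width`, in \[0, 1\]. Default 1.
#' @param valve_min_gap_fraction Diastolic gap floor as a fraction of
#'   `tube_width`, in \[0, `valve_opening_fraction`\]. Default 0 (valve
#'   seals completely).
#' @param valve_position_col Column of the valve plane. Default 48.
#' @param valve_sigma_um Axial extent (Gaussian sigma, um) of the valve
#'   constriction used in particle scenes. Default 25.
#' @param arrest_intervals List of `c(start, end)` pairs in seconds during
#'   which the heart does not beat. Default none.
#' @param noise_sd Additive Gaussian pixel noise, 8-bit units. Default 5.
#' @param background_drift_per_s Linear background intensity drift in 8-bit
#'   units per second, emulating the slow darkening of the cuticle over a
#'   recording. Default 1.
#' @param background_level Baseline background intensity. Default 20.
#' @param packet_sigma_um Gaussian radius of a rendered dye packet, um.
#'   Default 15.
#' @param packet_amplitude Peak 8-bit intensity of an unattenuated packet.
#'   Default 120.
#' @param seed Integer RNG seed; identical parameters and seed give
#'   bit-identical scenes. Default 1.
#'
#' @return An object of class `scene_params`.
#' @seealso [generate_heart_video()], [generate_particle_video()],
#'   [particle_scene_params()], [crawl_scene_params()]
#' @export
scene_params <- function(frame_rate = 100,
                         duration = 30,
                         image_size = c(48L, 192L),
                         pixel_size = 5,
                         tube_axis_row = (image_size[1L] + 1) / 2,
                         tube_width = 40,
                         beat_rate = 2,
                         packet_velocity = 5.2,
                         valve_opening_fraction = 1,
                         valve_min_gap_fraction = 0,
                         valve_position_col = 48,
                         valve_sigma_um = 25,
                         arrest_intervals = list(),
                         noise_sd = 5,
                         background_drift_per_s = 1,
                         background_level = 20,
                         packet_sigma_um = 15,
                         packet_amplitude = 120,
                         seed = 1L) {
  num1 <- function(x, nm, lo = -Inf, strict = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (strict && x <= lo) || (!strict && x < lo))
      stop("`", nm, "` must be a finite number ",
           if (strict) paste(">", lo) else paste(">=", lo), call. = FALSE)
    as.numeric(x)
  }
  frame_rate <- num1(frame_rate, "frame_rate", 0, strict = TRUE)
  duration <- num1(duration, "duration", 0, strict = TRUE)
  pixel_size <- num1(pixel_size, "pixel_size", 0, strict = TRUE)
  tube_width <- num1(tube_width, "tube_width", 0, strict = TRUE)
  beat_rate <- num1(beat_rate, "beat_rate", 0, strict = TRUE)
  packet_velocity <- num1(packet_velocity, "packet_velocity", 0)
  vof <- num1(valve_opening_fraction, "valve_opening_fraction", 0)
  if (vof > 1) stop("`valve_opening_fraction` must be in [0, 1]",
                    call. = FALSE)
  vmin <- num1(valve_min_gap_fraction, "valve_min_gap_fraction", 0)
  if (vmin > vof)
    stop("`valve_min_gap_fraction` cannot exceed `valve_opening_fraction`",
         call. = FALSE)
  noise_sd <- num1(noise_sd, "noise_sd", 0)
  if (length(image_size) != 2L || any(image_size < 8))
    stop("`image_size` must be (rows, cols), each >= 8", call. = FALSE)
  image_size <- as.integer(image_size)
  if (!is.list(arrest_intervals))
    stop("`arrest_intervals` must be a list of c(start, end) pairs",
         call. = FALSE)
  for (iv in arrest_intervals) {
    if (length(iv) != 2L || iv[1L] >= iv[2L] ||
        iv[1L] < 0 || iv[2L] > duration)
      stop("each arrest interval must be c(start, end) with ",
           "0 <= start < end <= duration", call. = FALSE)
  }
  if (length(arrest_intervals) > 1L) {
    o <- order(vapply(arrest_intervals, `[`, numeric(1L), 1L))
    arrest_intervals <- arrest_intervals[o]
    for (k in seq_len(length(arrest_intervals) - 1L))
      if (arrest_intervals[[k]][2L] > arrest_intervals[[k + 1L]][1L])
        stop("arrest intervals must not overlap", call. = FALSE)
  }
  structure(
    list(frame_rate = frame_rate, duration = duration,
         image_size = image_size, pixel_size = pixel_size,
         tube_axis_row = as.numeric(tube_axis_row),
         tube_width = tube_width, beat_rate = beat_rate,
         packet_velocity = packet_velocity,
         valve_opening_fraction = vof,
         valve_min_gap_fraction = vmin,
         valve_position_col = as.numeric(valve_position_col),
         valve_sigma_um = as.numeric(valve_sigma_um),
         arrest_intervals = arrest_intervals,
         noise_sd = noise_sd,
         background_drift_per_s = as.numeric(background_drift_per_s),
         background_level = as.numeric(background_level),
         packet_sigma_um = as.numeric(packet_sigma_um),
         packet_amplitude = as.numeric(packet_amplitude),
         seed = as.integer(seed)),
    class = "scene_params")
}

#' Scene parameters preset for particle velocimetry scenes
#'
#' Same container as [scene_params()], preset to the particle-streaming
#' recording conditions: 10 s two-channel confocal video at 200 frames/s of
#' 1.2 um fluorescent particles advected through the heart tube past the
#' valve constriction. The finer default calibration (2 um/px) reflects the
#' higher magnification of that assay; the default upstream speed of 2 mm/s
#' keeps per-frame particle steps a few pixels so that frame-to-frame
#' linking is well posed at 200 fps.
#'
#' @param ... Overrides passed to [scene_params()].
#' @return A `scene_params` object.
#' @export
particle_scene_params <- function(...) {
  defaults <- list(frame_rate = 200, duration = 10,
                   image_size = c(64L, 256L), pixel_size = 2,
                   tube_width = 80, packet_velocity = 2,
                   valve_position_col = 128, valve_sigma_um = 25,
                   noise_sd = 3, background_drift_per_s = 0,
                   background_level = 10)
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_params, args)
}

#' Scene parameters preset for larval crawling scenes
#'
#' Preset to the crawling-assay conditions: a 60 s overhead recording of a
#' single larva on a petri dish, analysed at 10 frames/s. The coarse
#' calibration (50 um/px) puts a ~4.5 mm third-instar larva at ~90 px body
#' length in a 2 x 2 cm field.
#'
#' @param ... Overrides passed to [scene_params()].
#' @return A `scene_params` object.
#' @export
crawl_scene_params <- function(...) {
  defaults <- list(frame_rate = 10, duration = 60,
                   image_size = c(400L, 400L), pixel_size = 50,
                   noise_sd = 0, background_drift_per_s = 0,
                   background_level = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_params, args)
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf("<scene_params> %g s @ %g fps, %d x %d px (%g um/px)\n",
              x$duration, x$frame_rate, x$image_size[1L], x$image_size[2L],
              x$pixel_size))
  cat(sprintf("  tube width %g um @ row %g; valve @ col %g, opening fraction %g (floor %g)\n",
              x$tube_width, x$tube_axis_row, x$valve_position_col,
              x$valve_opening_fraction, x$valve_min_gap_fraction))
  cat(sprintf("  beat rate %g /s, packet velocity %g mm/s, noise sd %g, seed %d\n",
              x$beat_rate, x$packet_velocity, x$noise_sd, x$seed))
  if (length(x$arrest_intervals))
    cat("  arrests:", paste(vapply(x$arrest_intervals, function(iv)
      sprintf("[%g, %g]", iv[1L], iv[2L]), character(1L)), collapse = " "),
      "\n")
  invisible(x)
}

# Run `expr` under a seeded RNG without disturbing the caller's RNG state.
with_scene_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

in_any_interval <- function(t, intervals) {
  for (iv in intervals) if (t >= iv[1L] && t < iv[2L]) return(TRUE)
  FALSE
}

# Instantaneous luminal gap (um) of the valve: raised-cosine beat waveform
# between the diastolic floor and the systolic peak opening; closed (at the
# floor) during arrests. Systolic peaks fall at t = (k + 1/2) / beat_rate.
valve_gap_at <- function(params, t) {
  lo <- params$valve_min_gap_fraction
  hi <- params$valve_opening_fraction
  phase <- 0.5 * (1 - cos(2 * pi * params$beat_rate * t))
  g <- params$tube_width * (lo + (hi - lo) * phase)
  arrested <- vapply(t, in_any_interval, logical(1L),
                     intervals = params$arrest_intervals)
  g[arrested] <- params$tube_width * lo
  g
}

# Add a Gaussian blob (amplitude `amp`, sigma `sig` px) centred at
# continuous position (r0, c0) into matrix `img`, touching only a local
# patch. Returns the modified matrix.
add_gaussian_blob <- function(img, r0, c0, amp, sig) {
  h <- nrow(img); w <- ncol(img)
  ext <- ceiling(4 * sig)
  rr <- max(1L, floor(r0 - ext)):min(h, ceiling(r0 + ext))
  cc <- max(1L, floor(c0 - ext)):min(w, ceiling(c0 + ext))
  if (length(rr) == 0L || length(cc) == 0L) return(img)
  gr <- exp(-(rr - r0)^2 / (2 * sig^2))
  gc <- exp(-(cc - c0)^2 / (2 * sig^2))
  img[rr, cc] <- img[rr, cc] + amp * outer(gr, gc)
  img
}

#' Generate a synthetic dye-angiography heart video with ground truth
#'
#' Renders the scene the dye-angiography setup records: a horizontal heart
#' tube seen from above, with the intracardiac valve at
#' `valve_position_col`. Once per heartbeat -- at the systolic peak of the
#' valve waveform, except during arrest intervals -- a discrete dye packet
#' is ejected through the valve and advected anteriorly (toward higher
#' column index) at `packet_velocity`. Hemolymph is transported in such
#' individual units per beat, not as a continuous current, and that is
#' exactly what the renderer draws: one Gaussian packet per beat.
#'
#' The valve attenuates each packet: its rendered amplitude is scaled by the
#' luminal gap fraction at ejection time, so a scene with
#' `valve_opening_fraction = 0.2` ejects packets carrying 20% of the
#' wildtype dye load. Packets that reach the anterior margin deposit their
#' dye there, building up the anterior accumulation the angiography assay
#' reads out. Gaussian pixel noise and a linear background drift (cuticle
#' darkening) are added last, and intensities are clipped to \[0, 255\].
#'
#' An optional second channel renders the two opposing valve lobes as a
#' bright label (emulating a valve-cell reporter), whose per-frame gap
#' follows the same raised-cosine waveform recorded in the ground truth.
#'
#' @param params A [scene_params()].
#' @param channels Character subset of `c("dye", "valve")`; default both.
#' @return A list with elements `video` (a [video_stack()]) and `truth`
#'   (class `ground_truth`: `beat_times` of beats that occurred,
#'   `packet_centroids` data frame `(packet, frame, t, row, col)`,
#'   `valve_gap` in um per frame, `arrest_intervals`, and the originating
#'   `params`).
#' @export
generate_heart_video <- function(params, channels = c("dye", "valve")) {
  stopifnot(inherits(params, "scene_params"))
  channels <- match.arg(channels, c("dye", "valve"), several.ok = TRUE)
  h <- params$image_size[1L]; w <- params$image_size[2L]
  nf <- max(1L, floor(params$duration * params$frame_rate))
  dt <- 1 / params$frame_rate
  times <- (seq_len(nf) - 1) * dt
  px <- params$pixel_size

  # beats occur at systolic peaks of the valve waveform, skipping arrests
  sched <- (seq_len(floor(params$duration * params$beat_rate)) - 0.5) /
    params$beat_rate
  occurred <- !vapply(sched, in_any_interval, logical(1L),
                      intervals = params$arrest_intervals)
  beat_times <- sched[occurred]

  gap_um <- valve_gap_at(params, times)
  v_px_s <- params$packet_velocity * 1000 / px    # px per second
  sig_px <- params$packet_sigma_um / px
  deposit_col <- w - 6                             # anterior deposition line
  accum_cols <- (w - 15L):w                        # anterior deposition zone
  deposit_per_packet <- 2.5

  # per-packet attenuation: gap fraction at ejection (systolic peak)
  amp_frac <- valve_gap_at(params, beat_times) / params$tube_width

  dye <- array(0, dim = c(nf, h, w))
  valve_ch <- if ("valve" %in% channels) array(0, dim = c(nf, h, w)) else NULL
  cent <- vector("list", length(beat_times))

  lobe_rows <- function(g_um) {
    # two opposing lobes reaching from outside the lumen (3 px of cell body
    # beyond the tube wall, so a fully retracted lobe stays visible) down to
    # the luminal gap. At least one empty pixel row is kept between the
    # lobes so they remain two components even at gap 0; the measured
    # boundary-to-boundary gap is then 1 px at closure, inside the raster
    # quantisation bound.
    half_w <- params$tube_width / px / 2
    half_g <- max(g_um / px / 2, 0.5)
    ax <- params$tube_axis_row
    top_last <- floor(ax - half_g)
    bot_first <- max(ceiling(ax + half_g), top_last + 2L)
    rows <- seq_len(h)
    top <- rows >= ax - half_w - 3 & rows <= top_last
    bot <- rows <= ax + half_w + 3 & rows >= bot_first
    list(top = rows[top], bottom = rows[bot])
  }
  valve_cols <- max(1L, round(params$valve_position_col - 2)):
    min(w, round(params$valve_position_col + 2))

  with_scene_seed(params$seed, {
    accum_level <- 0
    active_amp <- numeric(0)   # per active packet: amplitude
    active_t0 <- numeric(0)    # ejection time
    active_id <- integer(0)
    next_beat <- 1L
    for (i in seq_len(nf)) {
      t <- times[i]
      # eject packets whose beat time has arrived
      while (next_beat <= length(beat_times) && beat_times[next_beat] <= t) {
        active_amp <- c(active_amp,
                        params$packet_amplitude * amp_frac[next_beat])
        active_t0 <- c(active_t0, beat_times[next_beat])
        active_id <- c(active_id, next_beat)
        next_beat <- next_beat + 1L
      }
      frame <- matrix(params$background_level +
                        params$background_drift_per_s * t, h, w)
      frame[, accum_cols] <- frame[, accum_cols] + accum_level
      if (length(active_amp)) {
        cols_now <- params$valve_position_col + v_px_s * (t - active_t0)
        arrived <- cols_now >= deposit_col
        for (k in which(arrived))
          accum_level <- accum_level +
            deposit_per_packet * active_amp[k] / params$packet_amplitude
        for (k in which(!arrived)) {
          frame <- add_gaussian_blob(frame, params$tube_axis_row,
                                     cols_now[k], active_amp[k], sig_px)
          cent[[active_id[k]]] <- rbind(
            cent[[active_id[k]]],
            c(packet = active_id[k], frame = i, t = t,
              row = params$tube_axis_row, col = cols_now[k]))
        }
        keep <- !arrived
        active_amp <- active_amp[keep]
        active_t0 <- active_t0[keep]
        active_id <- active_id[keep]
      }
      if (params$noise_sd > 0)
        frame <- frame + matrix(stats::rnorm(h * w, sd = params$noise_sd),
                                h, w)
      dye[i, , ] <- pmin(pmax(frame, 0), 255)
      if (!is.null(valve_ch)) {
        vf <- matrix(0, h, w)
        lr <- lobe_rows(gap_um[i])
        if (length(lr$top)) vf[lr$top, valve_cols] <- 200
        if (length(lr$bottom)) vf[lr$bottom, valve_cols] <- 200
        if (params$noise_sd > 0)
          vf <- vf + matrix(stats::rnorm(h * w, sd = params$noise_sd), h, w)
        valve_ch[i, , ] <- pmin(pmax(vf, 0), 255)
      }
    }
  })

  frames <- if (is.null(valve_ch) || !("dye" %in% channels)) {
    if (is.null(valve_ch)) dye else valve_ch
  } else {
    a <- array(0, dim = c(nf, h, w, 2L))
    a[, , , 1L] <- dye; a[, , , 2L] <- valve_ch
    a
  }
  video <- video_stack(frames, frame_interval = dt, pixel_size = px,
                       channel_names = channels)
  centroids <- do.call(rbind, cent[!vapply(cent, is.null, logical(1L))])
  centroids <- as.data.frame(
    if (is.null(centroids))
      matrix(numeric(0), 0, 5,
             dimnames = list(NULL, c("packet", "frame", "t", "row", "col")))
    else centroids)
  truth <- structure(
    list(beat_times = beat_times,
         packet_centroids = centroids,
         valve_gap = gap_um,
         arrest_intervals = params$arrest_intervals,
         params = params),
    class = "ground_truth")
  list(video = video, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  for (nm in setdiff(names(x), "params")) {
    v <- x[[nm]]
    if (is.data.frame(v))
      cat(sprintf("  %s: data.frame %d x %d\n", nm, nrow(v), ncol(v)))
    else if (is.list(v)) cat(sprintf("  %s: %d interval(s)\n", nm, length(v)))
    else cat(sprintf("  %s: %s of length %d\n", nm, class(v)[1L], length(v)))
  }
  invisible(x)
}
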