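# Scale-normalised Laplacian-of-Gaussian kernel (negated, so bright blobs
# of matching scale give a positive response peak).
log_kernel <- function(sigma) {
  ext <- ceiling(3 * sigma)
  x <- -ext:ext
  r2 <- outer(x^2, x^2, "+")
  g <- exp(-r2 / (2 * sigma^2))
  k <- -sigma^2 * (r2 / sigma^4 - 2 / sigma^2) * g / (2 * pi * sigma^2)
  k - mean(k)   # zero-sum: flat background gives zero response
}

#' Detect particle spots in a frame
#'
#' Laplacian-of-Gaussian blob detection, the automated counterpart of
#' clicking particles by hand: the frame is filtered with a
#' scale-normalised LoG kernel at the expected spot scale, local maxima of
#' the response above `threshold` are kept, and positions are refined to
#' sub-pixel precision by a per-axis quadratic fit around the maximum.
#'
#' @param frame Numeric matrix (single channel).
#' @param spot_sigma Expected spot Gaussian sigma in px. Default 1.5.
#' @param threshold Minimum LoG response; for a Gaussian spot of matching
#'   sigma the peak response is roughly a quarter of the spot amplitude.
#'   Default 10.
#' @return Data frame with columns `row`, `col` (sub-pixel) and
#'   `response`; zero rows when nothing is found.
#' @export
detect_spots <- function(frame, spot_sigma = 1.5, threshold = 10) {
  stopifnot(is.matrix(frame))
  k <- log_kernel(spot_sigma)
  resp <- EBImage::filter2(frame, k, boundary = "replicate")
  h <- nrow(resp); w <- ncol(resp)
  if (h < 3L || w < 3L)
    return(data.frame(row = numeric(0), col = numeric(0),
                      response = numeric(0)))
  ctr <- resp[2:(h - 1L), 2:(w - 1L)]
  is_max <- ctr > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max &
      ctr >= resp[(2:(h - 1L)) + dr, (2:(w - 1L)) + dc]
  }
  pos <- which(is_max, arr.ind = TRUE)
  if (nrow(pos) == 0L)
    return(data.frame(row = numeric(0), col = numeric(0),
                      response = numeric(0)))
  rows <- pos[, 1L] + 1L; cols <- pos[, 2L] + 1L
  sub_r <- sub_c <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    r <- rows[i]; c_ <- cols[i]
    sub_r[i] <- r + parabolic_offset(resp[, c_], r)
    sub_c[i] <- c_ + parabolic_offset(resp[r, ], c_)
  }
  out <- data.frame(row = sub_r, col = sub_c,
                    response = resp[cbind(rows, cols)])
  out[order(-out$response), , drop = FALSE]
}

#' Detect spots in every frame of a stack
#'
#' @param stack A [video_stack()]; `channel` selects the particle channel.
#' @param channel Channel index or name (default first).
#' @inheritParams detect_spots
#' @return List of per-frame detection data frames.
#' @export
detect_spots_stack <- function(stack, spot_sigma = 1.5, threshold = 10,
                               channel = 1L) {
  stopifnot(inherits(stack, "video_stack"))
  s <- get_channel(stack, channel)
  lapply(seq_len(n_frames(s)), function(i)
    detect_spots(s$frames[i, , ], spot_sigma, threshold))
}

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking: for each new frame, all
#' candidate links between active track ends and new detections within the
#' displacement budget are ranked by distance and accepted smallest-first
#' (so every accepted link is the mutual nearest neighbour among the
#' remaining candidates). Ties are broken by lowest row, then column. A
#' track end may survive up to `max_gap` missed frames, with the
#' displacement budget scaled by the number of frames bridged. Unmatched
#' detections start new tracks.
#'
#' @param detections List of per-frame data frames with columns `row`,
#'   `col` (as from [detect_spots_stack()]).
#' @param max_disp Maximum displacement per frame, px (> 0).
#' @param max_gap Frames a track may skip. Default 0.
#' @param frame_interval Seconds per frame used for the `t` column.
#'   Default 1.
#' @return List of objects of class `track`, each with `id` and `points`
#'   (data frame `t`, `frame`, `row`, `col`).
#' @export
link_tracks <- function(detections, max_disp, max_gap = 0L,
                        frame_interval = 1) {
  if (!is.numeric(max_disp) || max_disp <= 0)
    stop("`max_disp` must be positive", call. = FALSE)
  active <- list()   # each: list(id, last_frame, r, c, points)
  done <- list()
  next_id <- 1L
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    det <- if (is.null(det)) data.frame(row = numeric(0), col = numeric(0))
           else as.data.frame(det)
    # retire stale tracks
    if (length(active)) {
      stale <- vapply(active, function(a) f - a$last_frame > max_gap + 1L,
                      logical(1L))
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    n_det <- nrow(det)
    used_det <- logical(n_det)
    used_act <- logical(length(active))
    if (length(active) && n_det) {
      cand <- NULL
      for (a in seq_along(active)) {
        gap_f <- f - active[[a]]$last_frame
        d <- sqrt((det$row - active[[a]]$r)^2 +
                    (det$col - active[[a]]$c)^2)
        ok <- which(d <= max_disp * gap_f)
        if (length(ok))
          cand <- rbind(cand, cbind(a = a, j = ok, d = d[ok]))
      }
      if (!is.null(cand)) {
        ord <- order(cand[, "d"], det$row[cand[, "j"]],
                     det$col[cand[, "j"]])
        for (k in ord) {
          a <- cand[k, "a"]; j <- cand[k, "j"]
          if (used_act[a] || used_det[j]) next
          used_act[a] <- TRUE; used_det[j] <- TRUE
          active[[a]]$points <- rbind(
            active[[a]]$points,
            data.frame(t = (f - 1) * frame_interval, frame = f,
                       row = det$row[j], col = det$col[j]))
          active[[a]]$last_frame <- f
          active[[a]]$r <- det$row[j]; active[[a]]$c <- det$col[j]
        }
      }
    }
    for (j in which(!used_det)) {
      active[[length(active) + 1L]] <- list(
        id = next_id, last_frame = f, r = det$row[j], c = det$col[j],
        points = data.frame(t = (f - 1) * frame_interval, frame = f,
                            row = det$row[j], col = det$col[j]))
      next_id <- next_id + 1L
    }
  }
  done <- c(done, active)
  tracks <- lapply(done, function(a)
    structure(list(id = a$id, points = a$points), class = "track"))
  tracks[order(vapply(tracks, function(tr) tr$id, integer(1L)))]
}

#' @export
print.track <- function(x, ...) {
  p <- x$points
  cat(sprintf("<track %s> %d point(s), t %.4g..%.4g s\n",
              x$id, nrow(p), p$t[1L], p$t[nrow(p)]))
  invisible(x)
}

as_track_points <- function(track) {
  p <- if (inherits(track, "track")) track$points else as.data.frame(track)
  if (!all(c("t", "row", "col") %in% names(p)))
    stop("track needs columns t, row, col", call. = FALSE)
  p
}

#' Track metrics: distance, displacement, confinement, speeds
#'
#' The crawling/streaming readouts of a single track: total path length
#' (sum of step lengths), net displacement (first to last point),
#' confinement ratio (displacement / total distance: 1 for straight
#' monotone motion, toward 0 for looping or confined motion), mean speed
#' (total distance over elapsed time) and peak single-step speed.
#'
#' @param track A `track` object or data frame with `t`, `row`, `col`.
#' @param pixel_size um/px.
#' @return Object of class `track_metrics`: `total_distance`,
#'   `displacement`, `confinement_ratio`, `mean_speed`, `peak_speed`
#'   (um and um/s), `n_points`.
#' @export
compute_track_metrics <- function(track, pixel_size) {
  p <- as_track_points(track)
  if (nrow(p) < 2L) stop("track needs >= 2 points", call. = FALSE)
  if (any(diff(p$t) <= 0))
    stop("duplicate or non-increasing timestamps in track", call. = FALSE)
  steps <- sqrt(diff(p$row)^2 + diff(p$col)^2) * pixel_size
  total <- sum(steps)
  disp <- sqrt((p$row[nrow(p)] - p$row[1L])^2 +
                 (p$col[nrow(p)] - p$col[1L])^2) * pixel_size
  structure(list(
    total_distance = total, displacement = disp,
    confinement_ratio = if (total > 0) disp / total else NA_real_,
    mean_speed = total / (p$t[nrow(p)] - p$t[1L]),
    peak_speed = max(steps / diff(p$t)),
    n_points = nrow(p)),
    class = "track_metrics")
}

#' @export
print.track_metrics <- function(x, ...) {
  cat(sprintf(paste0("<track_metrics> total %.4g um, displacement %.4g um, ",
                     "confinement %.3g\n  mean speed %.4g um/s, ",
                     "peak %.4g um/s (%d points)\n"),
              x$total_distance, x$displacement, x$confinement_ratio,
              x$mean_speed, x$peak_speed, x$n_points))
  invisible(x)
}

point_in_region <- function(region, r, c_) {
  if (inherits(region, "roi_spec")) {
    r >= region$row0 & r <= region$row0 + region$height - 1L &
      c_ >= region$col0 & c_ <= region$col0 + region$width - 1L
  } else {
    ri <- pmin(pmax(round(r), 1L), nrow(region))
    ci <- pmin(pmax(round(c_), 1L), ncol(region))
    region[cbind(ri, ci)]
  }
}

#' Peak track speed inside a region
#'
#' For every track, the maximum single-step speed whose step midpoint lies
#' inside the gating region (typically the valve region derived from a
#' valve-cell reporter channel). Tracks that never enter the region are
#' excluded and counted. The highest single speeds concentrate in the
#' valve region, and rise further when the lumen there is narrowed.
#'
#' @param tracks List of `track` objects (or data frames).
#' @param region Logical matrix mask on the image grid, or an
#'   [roi_spec()].
#' @param pixel_size um/px.
#' @return List with `peak_speeds` (data frame `id`, `peak_speed` in um/s)
#'   and `n_excluded` (tracks that never entered the region).
#' @export
gate_speeds_by_region <- function(tracks, region, pixel_size) {
  if (is.matrix(region) && !any(region))
    stop("gating region is empty", call. = FALSE)
  ids <- numeric(0); sp <- numeric(0); excl <- 0L
  for (k in seq_along(tracks)) {
    p <- as_track_points(tracks[[k]])
    if (nrow(p) < 2L) { excl <- excl + 1L; next }
    mid_r <- (p$row[-1L] + p$row[-nrow(p)]) / 2
    mid_c <- (p$col[-1L] + p$col[-nrow(p)]) / 2
    inside <- point_in_region(region, mid_r, mid_c)
    if (!any(inside)) { excl <- excl + 1L; next }
    steps <- sqrt(diff(p$row)^2 + diff(p$col)^2) * pixel_size
    speeds <- steps / diff(p$t)
    id <- if (inherits(tracks[[k]], "track")) tracks[[k]]$id else k
    ids <- c(ids, id); sp <- c(sp, max(speeds[inside]))
  }
  list(peak_speeds = data.frame(id = ids, peak_speed = sp),
       n_excluded = excl)
}

#' Centroid track of a silhouette mask video
#'
#' Per-frame intensity centroid of the thresholded mask, turned into a
#' `track` so the crawling readouts reuse the particle-track machinery.
#'
#' @param stack A single-channel binary-mask [video_stack()].
#' @param threshold Mask threshold (8-bit). Default 128.
#' @return A `track` object.
#' @export
centroid_track <- function(stack, threshold = 128) {
  stopifnot(inherits(stack, "video_stack"))
  nf <- n_frames(stack)
  tt <- frame_times(stack)
  rows <- cols <- numeric(nf)
  for (i in seq_len(nf)) {
    m <- stack$frames[i, , ] > threshold
    if (!any(m)) stop("empty mask at frame ", i, call. = FALSE)
    idx <- which(m, arr.ind = TRUE)
    rows[i] <- mean(idx[, 1L]); cols[i] <- mean(idx[, 2L])
  }
  structure(list(id = 1L,
                 points = data.frame(t = tt, frame = seq_len(nf),
                                     row = rows, col = cols)),
            class = "track")
}
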