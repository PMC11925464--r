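# Boundary pixels of a labelled component: pixels with a 4-neighbour
# outside the component (or on the image edge).
component_boundary <- function(lab, id) {
  m <- lab == id
  h <- nrow(m); w <- ncol(m)
  up <- rbind(TRUE, !m[-h, , drop = FALSE])
  down <- rbind(!m[-1L, , drop = FALSE], TRUE)
  left <- cbind(TRUE, !m[, -w, drop = FALSE])
  right <- cbind(!m[, -1L, drop = FALSE], TRUE)
  which(m & (up | down | left | right), arr.ind = TRUE)
}

# Minimum boundary-to-boundary pair distance (px) restricted to pairs whose
# direction lies within `tol_deg` of `perp_deg` (axial angles, screen
# convention: counter-clockwise positive from the column axis).
min_perp_distance <- function(b1, b2, perp_deg, tol_deg) {
  dr <- outer(b2[, 1L], b1[, 1L], "-")
  dc <- outer(b2[, 2L], b1[, 2L], "-")
  ang <- atan2(-dr, dc) * 180 / pi
  dd <- abs(((ang - perp_deg + 90) %% 180) - 90)
  d <- sqrt(dr^2 + dc^2)
  d[dd > tol_deg] <- Inf
  min(d)
}

#' Per-frame valve luminal gap from a valve-label channel
#'
#' Measures, for every frame, the minimum luminal distance between the two
#' opposing valve-cell components, taken perpendicular to the tube axis (a
#' 90-degree measurement relative to the flow direction, with a small
#' angular tolerance to absorb mask pixelation). The valve channel is
#' thresholded; exactly two connected components are expected per frame.
#' The distance runs from cytoplasmic border to cytoplasmic border: it
#' counts the empty pixels between the two components, so two components
#' separated by a single empty row read 1 px. A frame whose lobes touch and
#' fuse into one component reads gap 0 (a sealed lumen). Frames with zero
#' or more than two components are flagged invalid and linearly
#' interpolated when isolated; runs of invalid frames (or invalid
#' first/last frames) raise an error.
#'
#' @param stack A [video_stack()]; `channel` selects the valve label.
#' @param tube_axis_deg Tube axis angle in degrees (0 = flow along
#'   columns). Default 0.
#' @param threshold Label threshold (8-bit). Default 100.
#' @param angle_tol_deg Angular tolerance around the perpendicular.
#'   Default 5.
#' @param min_component_px Components smaller than this are ignored (noise
#'   specks). Default 4.
#' @param channel Channel index or name. Default `"valve"` if present,
#'   else 1.
#' @return Object of class `valve_gap_trace`: `times` (s), `gap` (um),
#'   `axis_angle_deg`, `pixel_size`, `invalid_frames` (indices that were
#'   interpolated).
#' @export
gap_trace <- function(stack, tube_axis_deg = 0, threshold = 100,
                      angle_tol_deg = 5, min_component_px = 4L,
                      channel = NULL) {
  stopifnot(inherits(stack, "video_stack"))
  if (is.null(channel))
    channel <- if ("valve" %in% stack$channel_names) "valve" else 1L
  vs <- get_channel(stack, channel)
  nf <- n_frames(vs)
  perp <- tube_axis_deg + 90
  gap_px <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    m <- vs$frames[i, , ] > threshold
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0L])
    ids <- which(sizes >= min_component_px)
    if (length(ids) == 1L) {
      gap_px[i] <- 0            # lobes touching and fused: sealed lumen
    } else if (length(ids) == 2L) {
      b1 <- component_boundary(lab, ids[1L])
      b2 <- component_boundary(lab, ids[2L])
      d <- min_perp_distance(b1, b2, perp, angle_tol_deg)
      if (is.finite(d)) gap_px[i] <- max(d - 1, 0)
    }
  }
  invalid <- which(is.na(gap_px))
  if (length(invalid)) {
    runs <- split(invalid, cumsum(c(1L, diff(invalid) != 1L)))
    bad <- vapply(runs, length, integer(1L)) > 1L |
      vapply(runs, function(r) r[1L] == 1L || r[length(r)] == nf,
             logical(1L))
    if (any(bad))
      stop("frames without exactly two valve components cannot be ",
           "interpolated (frames ",
           paste(utils::head(invalid, 10L), collapse = ", "),
           if (length(invalid) > 10L) ", ..." else "", ")", call. = FALSE)
    for (i in invalid)
      gap_px[i] <- (gap_px[i - 1L] + gap_px[i + 1L]) / 2
  }
  structure(list(times = frame_times(vs),
                 gap = gap_px * vs$pixel_size,
                 axis_angle_deg = tube_axis_deg,
                 pixel_size = vs$pixel_size,
                 invalid_frames = invalid),
            class = "valve_gap_trace")
}

#' Construct a valve gap trace directly
#'
#' @param times Seconds, strictly increasing.
#' @param gap Gap in um, same length.
#' @param pixel_size um/px used to derive the default closure threshold.
#' @param axis_angle_deg Tube axis angle (metadata).
#' @return A `valve_gap_trace`.
#' @export
valve_gap_trace <- function(times, gap, pixel_size = 1,
                            axis_angle_deg = 0) {
  if (length(times) != length(gap))
    stop("`times` and `gap` must have equal length", call. = FALSE)
  if (any(gap < 0)) stop("gap must be >= 0", call. = FALSE)
  structure(list(times = as.numeric(times), gap = as.numeric(gap),
                 axis_angle_deg = axis_angle_deg,
                 pixel_size = pixel_size, invalid_frames = integer(0)),
            class = "valve_gap_trace")
}

#' @export
print.valve_gap_trace <- function(x, ...) {
  cat(sprintf("<valve_gap_trace> %d frames; gap %.3g..%.3g um; axis %g deg\n",
              length(x$times), min(x$gap), max(x$gap), x$axis_angle_deg))
  if (length(x$invalid_frames))
    cat("  interpolated frames:", length(x$invalid_frames), "\n")
  invisible(x)
}

# Maximal runs of open frames (gap > threshold); returns a data frame of
# run start/end indices.
open_runs <- function(open) {
  r <- rle(open)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Mean peak luminal opening distance
#'
#' The fully-open-state readout: for each of the first `n_beats` opening
#' events (runs of gap above the closure threshold), take the maximum gap,
#' and average. Malformed valves reach a smaller peak opening even when
#' their rhythm is unchanged.
#'
#' @param trace A [gap_trace()] result or [valve_gap_trace()].
#' @param n_beats Opening events to average. Default 5.
#' @param closure_threshold Gap (um) at or below which the valve counts as
#'   closed; default one pixel equivalent (`pixel_size` um).
#' @return Mean peak gap in um.
#' @export
peak_open_distance <- function(trace, n_beats = 5L,
                               closure_threshold = NULL) {
  stopifnot(inherits(trace, "valve_gap_trace"))
  if (is.null(closure_threshold)) closure_threshold <- trace$pixel_size
  runs <- open_runs(trace$gap > closure_threshold)
  if (nrow(runs) < n_beats)
    stop(sprintf("only %d opening event(s) found, %d requested",
                 nrow(runs), n_beats), call. = FALSE)
  peaks <- vapply(seq_len(n_beats), function(k)
    max(trace$gap[runs$start[k]:runs$end[k]]), numeric(1L))
  mean(peaks)
}

#' Valve opening durations (closed state to closed state)
#'
#' Measures the time between two closed valve states: each event runs from
#' the first open frame of an opening until the valve next begins to open
#' again, i.e. it spans the opening, the peak-open phase, and the complete
#' following closure. Events need a closed state on both sides; the first
#' opening is skipped if the trace starts open, and the last opening is
#' dropped if no further opening follows. The peak gap and its time are
#' reported per event.
#'
#' A valve that never reaches the closed state (gap always above the
#' threshold -- valves unable to seal the lumen) yields no events and the
#' explicit status `"cannot_estimate"` rather than a number.
#'
#' @param trace A [gap_trace()] result or [valve_gap_trace()].
#' @param closure_threshold Gap (um) at or below which the valve is
#'   closed; default one pixel equivalent.
#' @param n_beats Events to average for `mean_duration`. Default 10.
#' @return Object of class `opening_events`: `events` data frame
#'   (`open_start`, `open_end`, `duration`, `peak_gap`, `peak_time`),
#'   `mean_duration` (s, over the first `n_beats` events), and `status`
#'   (`"ok"` or `"cannot_estimate"`).
#' @export
opening_durations <- function(trace, closure_threshold = NULL,
                              n_beats = 10L) {
  stopifnot(inherits(trace, "valve_gap_trace"))
  if (is.null(closure_threshold)) closure_threshold <- trace$pixel_size
  open <- trace$gap > closure_threshold
  if (all(open)) {
    return(structure(list(events = data.frame(open_start = numeric(0),
                                              open_end = numeric(0),
                                              duration = numeric(0),
                                              peak_gap = numeric(0),
                                              peak_time = numeric(0)),
                          mean_duration = NA_real_,
                          status = "cannot_estimate"),
                     class = "opening_events"))
  }
  runs <- open_runs(open)
  ev <- list()
  for (k in seq_len(nrow(runs))) {
    if (runs$start[k] == 1L) next                  # no closure before
    if (k == nrow(runs)) break                     # no re-opening after
    o_start <- trace$times[runs$start[k]]
    o_end <- trace$times[runs$start[k + 1L]]       # next opening begins
    seg <- runs$start[k]:runs$end[k]
    pk <- which.max(trace$gap[seg])
    ev[[length(ev) + 1L]] <- data.frame(
      open_start = o_start, open_end = o_end, duration = o_end - o_start,
      peak_gap = trace$gap[seg][pk], peak_time = trace$times[seg][pk])
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(open_start = numeric(0), open_end = numeric(0),
               duration = numeric(0), peak_gap = numeric(0),
               peak_time = numeric(0))
  n_use <- min(n_beats, nrow(events))
  if (n_use < n_beats)
    warning(sprintf("only %d complete opening event(s), %d requested",
                    nrow(events), n_beats))
  structure(list(events = events,
                 mean_duration = if (n_use)
                   mean(events$duration[seq_len(n_use)]) else NA_real_,
                 status = "ok"),
            class = "opening_events")
}

#' @export
print.opening_events <- function(x, ...) {
  if (x$status == "cannot_estimate") {
    cat("<opening_events> valve never closes: opening time cannot be estimated\n")
  } else {
    cat(sprintf("<opening_events> %d event(s); mean close-to-close duration %.4g s\n",
                nrow(x$events), x$mean_duration))
  }
  invisible(x)
}
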