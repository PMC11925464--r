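#' Subtract the first frame as background
#'
#' Dye angiography quantifies signal that appears after injection, so the
#' first video frame serves as the background estimate: every frame has the
#' first frame subtracted pixel-wise, and negative differences are clipped
#' to zero (the tracer can only add signal to the anterior region; negative
#' residuals are noise). The first output frame is consequently all zeros.
#'
#' @param stack A [video_stack()] with at least 2 frames (single channel).
#' @return A `video_stack` of clipped differences.
#' @export
subtract_background <- function(stack) {
  stopifnot(inherits(stack, "video_stack"))
  if (length(dim(stack$frames)) != 3L)
    stop("subtract_background expects a single-channel stack; ",
         "use get_channel() first", call. = FALSE)
  nf <- n_frames(stack)
  if (nf < 2L)
    stop("background subtraction needs at least 2 frames", call. = FALSE)
  f0 <- stack$frames[1L, , ]
  out <- stack
  for (i in seq_len(nf))
    out$frames[i, , ] <- pmax(stack$frames[i, , ] - f0, 0)
  out
}

#' Mean-intensity time trace of an ROI
#'
#' The Z-axis profile of a rectangular ROI: the arithmetic mean intensity
#' over the ROI pixels for every frame, with times taken from the stack's
#' frame interval. This trace is the substrate of the accumulation index,
#' the peri-valve oscillogram, and two-ROI velocimetry.
#'
#' @param stack A single-channel [video_stack()].
#' @param roi An [roi_spec()] inside the frame bounds.
#' @return An object of class `intensity_trace`: list with `times` (s),
#'   `values` (mean 8-bit intensity), and `roi`.
#' @export
extract_trace <- function(stack, roi) {
  stopifnot(inherits(stack, "video_stack"), inherits(roi, "roi_spec"))
  if (length(dim(stack$frames)) != 3L)
    stop("extract_trace expects a single-channel stack; ",
         "use get_channel() first", call. = FALSE)
  d <- dim(stack$frames)
  check_roi_in_bounds(roi, d[2L], d[3L])
  sub <- stack$frames[, roi_rows(roi), roi_cols(roi), drop = FALSE]
  vals <- apply(sub, 1L, mean)
  structure(list(times = frame_times(stack), values = vals, roi = roi),
            class = "intensity_trace")
}

#' Construct an intensity trace directly
#'
#' Mainly for tests and for traces imported from other tools.
#'
#' @param times Strictly increasing times in seconds.
#' @param values Intensities, same length as `times`.
#' @param roi Optional [roi_spec()] provenance.
#' @return An `intensity_trace`.
#' @export
intensity_trace <- function(times, values, roi = NULL) {
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length", call. = FALSE)
  if (length(times) >= 2L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 roi = roi),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %d samples over %.4g s; mean %.3g, range [%.3g, %.3g]\n",
              length(x$times), diff(range(x$times)), mean(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Anterior dye accumulation index
#'
#' The cardiac-performance readout of dye angiography: how much tracer the
#' heart has moved into the anterior region by the end of the recording.
#' The index is the mean background-subtracted ROI intensity within a
#' terminal time window -- by default the final second of the recording.
#' Averaging over a window rather than taking the literal last frame keeps
#' the endpoint robust to single-frame noise while still reflecting the
#' 30 s endpoint of the assay.
#'
#' @param trace An [intensity_trace()] from a background-subtracted stack.
#' @param window `c(start, end)` in seconds; default the final 1 s of the
#'   trace.
#' @return An object of class `accumulation_result`: list with
#'   `accumulation_index`, `trace`, and `window`.
#' @export
accumulation_index <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  span <- range(trace$times)
  if (is.null(window)) window <- c(max(span[1L], span[2L] - 1), span[2L])
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("`window` must be c(start, end) with start < end", call. = FALSE)
  if (window[1L] < span[1L] - 1e-9 || window[2L] > span[2L] + 1e-9)
    stop(sprintf("window [%g, %g] lies outside the trace span [%g, %g]",
                 window[1L], window[2L], span[1L], span[2L]), call. = FALSE)
  sel <- trace$times >= window[1L] - 1e-9 & trace$times <= window[2L] + 1e-9
  if (!any(sel)) stop("window contains no samples", call. = FALSE)
  structure(list(accumulation_index = mean(trace$values[sel]),
                 trace = trace, window = as.numeric(window)),
            class = "accumulation_result")
}

#' @export
print.accumulation_result <- function(x, ...) {
  cat(sprintf("<accumulation_result> index %.4g (mean intensity over [%g, %g] s)\n",
              x$accumulation_index, x$window[1L], x$window[2L]))
  invisible(x)
}

# Monotone-luminance colormap: black -> red -> yellow -> white. Each ramp
# stage only ever increases R, then G, then B, so display luminance is a
# strictly increasing function of input intensity.
hot_colormap <- grDevices::colorRamp(c("black", "red", "yellow", "white"))

#' Colour-coded background-subtracted intensity map
#'
#' Presentational view of where dye sits at time `t`: the
#' background-subtracted frame nearest to `t`, mapped through a monotone
#' black-red-yellow-white colormap over the 8-bit range so that brighter
#' dye is rendered with strictly higher luminance.
#'
#' @param stack A single-channel [video_stack()] (raw; background is
#'   subtracted internally).
#' @param t Time in seconds, within the recording.
#' @return Numeric array `[row, col, 3]` of RGB values in \[0, 1\].
#' @export
intensity_map <- function(stack, t) {
  stopifnot(inherits(stack, "video_stack"))
  tt <- frame_times(stack)
  if (t < tt[1L] - 1e-9 || t > tt[length(tt)] + 1e-9)
    stop(sprintf("t = %g s is outside the recording [0, %g] s",
                 t, tt[length(tt)]), call. = FALSE)
  sub <- subtract_background(stack)
  i <- which.min(abs(tt - t))
  frame <- sub$frames[i, , ]
  rgb <- hot_colormap(pmin(pmax(frame, 0), 255) / 255) / 255
  array(rgb, dim = c(nrow(frame), ncol(frame), 3L))
}
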