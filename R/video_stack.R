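#' Video stack container
#'
#' `video_stack()` is the universal raw-input container of the package: a
#' time-ordered set of frames with the two calibration values every
#' quantitative operation needs, the frame interval (s) and the pixel size
#' (um/pixel). Neither calibration has a default anywhere in the package --
#' recordings come from different microscope/camera combinations and the
#' calibration must be supplied with the data.
#'
#' Frames are stored as a numeric array indexed `[frame, row, col]` for
#' single-channel stacks or `[frame, row, col, channel]` for multi-channel
#' stacks. Intensities are 8-bit units (0--255) throughout the pipeline;
#' [to_grayscale_8bit()] converts other bit depths. Rows and columns are
#' 1-based, and the anatomical convention is posterior to anterior along
#' increasing column index.
#'
#' @param frames Numeric array, `[frame, row, col]` or
#'   `[frame, row, col, channel]`. All values must be finite.
#' @param frame_interval Time between consecutive frames, in seconds (> 0).
#' @param pixel_size Physical size of one pixel, in micrometres (> 0).
#' @param channel_names Optional character vector naming the channels
#'   (length must equal the 4th dimension; single-channel stacks may omit it).
#'
#' @return An object of class `video_stack`.
#' @seealso [read_video()], [write_video()], [frame_times()], [get_frame()]
#' @export
video_stack <- function(frames, frame_interval, pixel_size,
                        channel_names = NULL) {
  if (!is.array(frames) || !(length(dim(frames)) %in% c(3L, 4L)))
    stop("`frames` must be a 3-D [frame, row, col] or 4-D ",
         "[frame, row, col, channel] array", call. = FALSE)
  if (!is.numeric(frames) || anyNA(frames) || any(!is.finite(frames)))
    stop("frame intensities must be finite numbers", call. = FALSE)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be a single positive number (seconds)",
         call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/pixel)",
         call. = FALSE)
  nch <- if (length(dim(frames)) == 4L) dim(frames)[4L] else 1L
  if (is.null(channel_names)) {
    channel_names <- if (nch == 1L) "gray" else paste0("ch", seq_len(nch))
  }
  if (length(channel_names) != nch)
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  structure(
    list(frames = frames,
         frame_interval = as.numeric(frame_interval),
         pixel_size = as.numeric(pixel_size),
         channel_names = as.character(channel_names)),
    class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_stack> %d frame(s), %d x %d px, %d channel(s) [%s]\n",
              d[1L], d[2L], d[3L],
              length(x$channel_names),
              paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  frame interval %.6g s (%.4g fps), pixel size %.4g um/px, duration %.4g s\n",
              x$frame_interval, 1 / x$frame_interval, x$pixel_size,
              d[1L] * x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [video_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "video_stack"))
  dim(stack$frames)[1L]
}

#' Acquisition times of the frames
#'
#' Frame `i` is timestamped `(i - 1) * frame_interval`, i.e. recording starts
#' at t = 0 s with the first frame.
#'
#' @param stack A [video_stack()].
#' @return Numeric vector of times in seconds, one per frame.
#' @export
frame_times <- function(stack) {
  stopifnot(inherits(stack, "video_stack"))
  (seq_len(n_frames(stack)) - 1) * stack$frame_interval
}

#' Extract a single frame as a matrix
#'
#' @param stack A [video_stack()].
#' @param i Frame index (1-based).
#' @param channel Channel index or name (default first channel).
#' @return Numeric matrix `[row, col]`.
#' @export
get_frame <- function(stack, i, channel = 1L) {
  stopifnot(inherits(stack, "video_stack"))
  nf <- n_frames(stack)
  if (!(is.numeric(i) && length(i) == 1L && i >= 1 && i <= nf))
    stop("frame index out of range [1, ", nf, "]", call. = FALSE)
  ch <- resolve_channel(stack, channel)
  if (length(dim(stack$frames)) == 4L) {
    stack$frames[i, , , ch]
  } else {
    stack$frames[i, , ]
  }
}

#' Select one channel of a multi-channel stack
#'
#' @param stack A [video_stack()].
#' @param channel Channel index or name.
#' @return A single-channel `video_stack`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "video_stack"))
  ch <- resolve_channel(stack, channel)
  fr <- if (length(dim(stack$frames)) == 4L) stack$frames[, , , ch] else stack$frames
  video_stack(fr, stack$frame_interval, stack$pixel_size,
              channel_names = stack$channel_names[ch])
}

resolve_channel <- function(stack, channel) {
  nch <- length(stack$channel_names)
  if (is.character(channel)) {
    ch <- match(channel, stack$channel_names)
    if (is.na(ch)) stop("unknown channel '", channel, "'; available: ",
                        paste(stack$channel_names, collapse = ", "),
                        call. = FALSE)
  } else {
    ch <- as.integer(channel)
    if (is.na(ch) || ch < 1L || ch > nch)
      stop("channel index out of range [1, ", nch, "]", call. = FALSE)
  }
  ch
}

#' Rectangular region of interest
#'
#' An ROI is an axis-aligned rectangle of pixels, given by its top-left
#' corner (1-based row/column of the first pixel) and its extent. The ROI
#' covers rows `row0 ... row0 + height - 1` and columns
#' `col0 ... col0 + width - 1`, so a 15 x 15 ROI contains exactly 225 pixels
#' -- the ROI size used for both the anterior accumulation readout and the
#' two aorta velocimetry windows.
#'
#' @param row0,col0 Top-left pixel of the rectangle (1-based, >= 1).
#' @param height,width Extent in pixels (>= 1).
#' @param name Optional label.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(row0, col0, height, width, name = "roi") {
  vals <- c(row0 = row0, col0 = col0, height = height, width = width)
  if (!all(is.finite(vals)) || any(vals != round(vals)))
    stop("ROI fields must be integers", call. = FALSE)
  if (row0 < 1 || col0 < 1) stop("ROI origin must be >= 1", call. = FALSE)
  if (height < 1 || width < 1) stop("ROI extent must be >= 1", call. = FALSE)
  structure(list(name = as.character(name), row0 = as.integer(row0),
                 col0 = as.integer(col0), height = as.integer(height),
                 width = as.integer(width)),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> '%s': rows %d..%d, cols %d..%d (%d px)\n",
              x$name, x$row0, x$row0 + x$height - 1L,
              x$col0, x$col0 + x$width - 1L, x$height * x$width))
  invisible(x)
}

roi_rows <- function(roi) roi$row0:(roi$row0 + roi$height - 1L)
roi_cols <- function(roi) roi$col0:(roi$col0 + roi$width - 1L)

check_roi_in_bounds <- function(roi, nrow_img, ncol_img, what = "frame") {
  if (roi$row0 + roi$height - 1L > nrow_img ||
      roi$col0 + roi$width - 1L > ncol_img)
    stop(sprintf("ROI '%s' (rows %d..%d, cols %d..%d) exceeds %s bounds %d x %d",
                 roi$name, roi$row0, roi$row0 + roi$height - 1L,
                 roi$col0, roi$col0 + roi$width - 1L, what,
                 nrow_img, ncol_img), call. = FALSE)
  invisible(TRUE)
}
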