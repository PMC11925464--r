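#' Read a video stack from a multi-page TIFF
#'
#' Reads a multi-page TIFF into a [video_stack()]. Calibration (frame
#' interval and pixel size) is never guessed from file metadata -- it must be
#' passed explicitly, typically from the same YAML config that carries the
#' ROIs ([load_roi_config()]).
#'
#' RGB pages are converted to a single luminance channel with the ITU-R
#' BT.601 weights (0.299 R + 0.587 G + 0.114 B). Multi-channel stacks
#' written by [write_video()] with `layout = "interleaved"` are recovered by
#' passing the channel count in `n_channels`: pages are taken as
#' frame-major, channel-minor.
#'
#' @param path Path to a TIFF file.
#' @param frame_interval Seconds between frames.
#' @param pixel_size Micrometres per pixel.
#' @param n_channels Number of interleaved channels the page sequence
#'   encodes (default 1).
#' @param channel_names Optional channel labels.
#' @return A [video_stack()].
#' @export
read_video <- function(path, frame_interval, pixel_size, n_channels = 1L,
                       channel_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("could not read TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("empty TIFF: ", path, call. = FALSE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) rgb_to_luminance(p) else p
  })
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("inconsistent frame shapes across TIFF pages in ", path,
         call. = FALSE)
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L || length(pages) %% n_channels != 0L)
    stop("page count (", length(pages),
         ") is not a multiple of n_channels (", n_channels, ")",
         call. = FALSE)
  nf <- length(pages) %/% n_channels
  h <- dims[1L, 1L]; w <- dims[2L, 1L]
  if (n_channels == 1L) {
    frames <- array(0, dim = c(nf, h, w))
    for (i in seq_len(nf)) frames[i, , ] <- pages[[i]]
  } else {
    frames <- array(0, dim = c(nf, h, w, n_channels))
    k <- 1L
    for (i in seq_len(nf)) for (ch in seq_len(n_channels)) {
      frames[i, , , ch] <- pages[[k]]; k <- k + 1L
    }
  }
  video_stack(frames, frame_interval, pixel_size,
              channel_names = channel_names)
}

rgb_to_luminance <- function(page) {
  w <- c(0.299, 0.587, 0.114)
  nch <- dim(page)[3L]
  if (nch < 3L) return(page[, , 1L])
  page[, , 1L] * w[1L] + page[, , 2L] * w[2L] + page[, , 3L] * w[3L]
}

#' Write a video stack to multi-page TIFF
#'
#' Intensities are written as 8-bit samples; values are clamped to
#' \[0, 255\] and rounded. Multi-channel stacks are written either as one
#' file with frame-major/channel-minor interleaved pages
#' (`layout = "interleaved"`) or as one file per channel
#' (`layout = "per_channel"`, file names get a `_<channel>` suffix).
#'
#' @param stack A [video_stack()].
#' @param path Output TIFF path.
#' @param layout `"interleaved"` or `"per_channel"`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_video <- function(stack, path, layout = c("interleaved", "per_channel")) {
  stopifnot(inherits(stack, "video_stack"))
  layout <- match.arg(layout)
  to_page <- function(m) pmin(pmax(round(m), 0), 255) / 255
  d <- dim(stack$frames)
  if (length(d) == 3L || layout == "interleaved") {
    pages <- list()
    k <- 1L
    for (i in seq_len(d[1L])) {
      if (length(d) == 3L) {
        pages[[k]] <- to_page(stack$frames[i, , ]); k <- k + 1L
      } else {
        for (ch in seq_len(d[4L])) {
          pages[[k]] <- to_page(stack$frames[i, , , ch]); k <- k + 1L
        }
      }
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    invisible(path)
  } else {
    paths <- character(0)
    for (ch in seq_len(d[4L])) {
      pages <- lapply(seq_len(d[1L]),
                      function(i) to_page(stack$frames[i, , , ch]))
      p <- sub("(\\.tiff?)?$", paste0("_", stack$channel_names[ch], "\\1"),
               path)
      if (identical(p, path))
        p <- paste0(path, "_", stack$channel_names[ch], ".tif")
      tiff::writeTIFF(pages, p, bits.per.sample = 8L)
      paths <- c(paths, p)
    }
    invisible(paths)
  }
}

#' Convert a stack to 8-bit grayscale
#'
#' Linearly rescales the global minimum--maximum of the whole stack to
#' \[0, 255\] and rounds half-up, mirroring the 8-bit conversion applied to
#' the raw recordings. The rescale is global, not per-frame: per-frame
#' normalisation would erase the slow intensity trends (dye accumulation,
#' cuticle darkening) the downstream analyses quantify.
#'
#' A stack whose values are already integers inside \[0, 255\] is returned
#' unchanged. A constant stack has no usable range and is returned as all
#' zeros with a warning.
#'
#' @param stack A [video_stack()].
#' @return A `video_stack` with intensities in \[0, 255\].
#' @export
to_grayscale_8bit <- function(stack) {
  stopifnot(inherits(stack, "video_stack"))
  v <- stack$frames
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    warning("constant-intensity stack: degenerate range, returning zeros")
    stack$frames[] <- 0
    return(stack)
  }
  if (rng[1L] >= 0 && rng[2L] <= 255 && all(v == round(v))) return(stack)
  stack$frames[] <- floor((v - rng[1L]) / (rng[2L] - rng[1L]) * 255 + 0.5)
  stack
}

#' Load ROIs and calibration from a YAML config
#'
#' The config carries the information the original protocol recorded as
#' manual click positions and microscope settings: pixel size, frame
#' interval, and a list of rectangular ROIs. Example:
#'
#' ```yaml
#' pixel_size: 5.0        # um/pixel
#' frame_interval: 0.01   # s
#' rois:
#'   - {name: anterior, row0: 17, col0: 177, height: 15, width: 15}
#'   - {name: aorta_post, row0: 17, col0: 60, height: 15, width: 15}
#' ```
#'
#' ROIs are validated structurally here; bounds against a concrete image are
#' checked by the operation that applies them (every extraction errors on an
#' out-of-bounds ROI, naming it). Overlapping ROIs are legal -- the two
#' velocimetry windows and the accumulation window may share pixels -- but
#' draw a warning so accidental duplicates are noticed.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `rois` (list of [roi_spec()]),
#'   `pixel_size`, and `frame_interval` (either may be `NULL` if absent).
#' @export
load_roi_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  rois <- list()
  for (r in cfg$rois) {
    roi <- tryCatch(
      roi_spec(row0 = r$row0, col0 = r$col0, height = r$height,
               width = r$width,
               name = if (is.null(r$name)) "roi" else r$name),
      error = function(e)
        stop("invalid ROI '", if (is.null(r$name)) "<unnamed>" else r$name,
             "' in ", path, ": ", conditionMessage(e), call. = FALSE))
    rois[[length(rois) + 1L]] <- roi
  }
  if (length(rois) >= 2L) {
    for (i in seq_len(length(rois) - 1L)) for (j in (i + 1L):length(rois)) {
      a <- rois[[i]]; b <- rois[[j]]
      if (a$row0 <= b$row0 + b$height - 1L && b$row0 <= a$row0 + a$height - 1L &&
          a$col0 <= b$col0 + b$width - 1L && b$col0 <= a$col0 + a$width - 1L)
        warning("ROIs '", a$name, "' and '", b$name, "' overlap")
    }
  }
  list(rois = rois,
       pixel_size = cfg$pixel_size,
       frame_interval = cfg$frame_interval)
}
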