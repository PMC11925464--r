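# Local maxima of a numeric vector with topographic prominence.
# Plateau maxima report their centre sample. Prominence of a peak is its
# height above the higher of the two minima separating it from the nearest
# higher ground on each side (trace ends count as higher ground).
find_peaks_prominence <- function(v) {
  n <- length(v)
  if (n < 3L) return(data.frame(index = integer(0), value = numeric(0),
                                prominence = numeric(0)))
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) {
        idx <- c(idx, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  prom <- vapply(idx, function(p) {
    lmin <- v[p]; k <- p
    while (k > 1L && v[k - 1L] <= v[p]) { k <- k - 1L; lmin <- min(lmin, v[k]) }
    rmin <- v[p]; k <- p
    while (k < n && v[k + 1L] <= v[p]) { k <- k + 1L; rmin <- min(rmin, v[k]) }
    v[p] - max(lmin, rmin)
  }, numeric(1L))
  data.frame(index = idx, value = v[idx], prominence = prom)
}

# Parabolic sub-sample refinement of a peak position; returns fractional
# index offset in [-0.5, 0.5].
parabolic_offset <- function(v, i) {
  if (i <= 1L || i >= length(v)) return(0)
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (denom >= 0) return(0)
  max(min(0.5 * (v[i - 1L] - v[i + 1L]) / denom, 0.5), -0.5)
}

#' Oscillogram analysis of a peri-valve intensity trace
#'
#' Decomposes the ROI oscillogram into pump cycles. Each heartbeat drives a
#' dye packet past the ROI: intensity rises to a peak and -- if the valve
#' seals the lumen afterwards -- falls back to baseline before the next
#' beat. The function finds peaks by topographic prominence, estimates the
#' baseline as a low quantile of the trace, marks each cycle's closure as
#' verified when the trace returns to within `closure_tol` of baseline
#' between consecutive peaks, and declares a cardiac arrest wherever the
#' gap between consecutive peaks (or between a trace end and its nearest
#' peak) exceeds `arrest_factor` times the median cycle period. A detected
#' arrest starts one median period after the last peak before the silence
#' -- where the next beat was due -- and ends at the next peak.
#'
#' @param trace An [intensity_trace()] (>= 3 samples).
#' @param min_prominence Minimum peak prominence in intensity units;
#'   default 20% of the range from baseline to trace maximum.
#' @param baseline_quantile Quantile of the trace taken as baseline.
#'   Default 0.1.
#' @param closure_tol Distance from baseline (intensity units) within which
#'   a cycle counts as having closed; default 20% of the median peak height
#'   above baseline. Both baseline and tolerance are per-trace quantities:
#'   background intensity differs between animals and must be estimated per
#'   recording.
#' @param arrest_factor Inter-peak gap, in units of the median cycle
#'   period, beyond which silence counts as arrest. Default 2.
#' @param refine_peaks If `TRUE`, peak times are refined to sub-frame
#'   precision by parabolic interpolation around the peak sample; default
#'   `FALSE` (one-frame resolution).
#' @return An object of class `oscillogram_features`: `peak_times`,
#'   `peak_values`, `peak_indices`, `baseline`, `cycle_periods`,
#'   `arrest_intervals` (list of `c(start, end)`), `closure_ok_per_cycle`.
#' @export
detect_cycles <- function(trace, min_prominence = NULL,
                          baseline_quantile = 0.1, closure_tol = NULL,
                          arrest_factor = 2, refine_peaks = FALSE) {
  stopifnot(inherits(trace, "intensity_trace"))
  v <- trace$values; tt <- trace$times
  if (length(v) < 3L)
    stop("oscillogram analysis needs at least 3 samples", call. = FALSE)
  baseline <- as.numeric(stats::quantile(v, baseline_quantile, names = FALSE))
  span <- c(tt[1L], tt[length(tt)])
  empty <- function(msg) {
    warning(msg, call. = FALSE)
    structure(list(peak_times = numeric(0), peak_values = numeric(0),
                   peak_indices = integer(0), baseline = baseline,
                   cycle_periods = numeric(0),
                   arrest_intervals = list(span),
                   closure_ok_per_cycle = logical(0)),
              class = "oscillogram_features")
  }
  if (max(v) == min(v))
    return(empty("constant trace: no pump cycles detectable"))
  if (is.null(min_prominence))
    min_prominence <- 0.2 * (max(v) - baseline)
  pk <- find_peaks_prominence(v)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (nrow(pk) == 0L)
    return(empty("no peaks above the prominence threshold"))
  peak_idx <- pk$index
  peak_t <- tt[peak_idx]
  if (refine_peaks && length(tt) >= 2L) {
    dt <- stats::median(diff(tt))
    peak_t <- peak_t + vapply(peak_idx, function(i) parabolic_offset(v, i),
                              numeric(1L)) * dt
  }
  periods <- diff(peak_t)
  med_p <- if (length(periods)) stats::median(periods) else diff(span)
  if (is.null(closure_tol))
    closure_tol <- 0.2 * max(stats::median(pk$value) - baseline, 0)
  closure_ok <- logical(0)
  if (length(peak_idx) >= 2L) {
    closure_ok <- vapply(seq_len(length(peak_idx) - 1L), function(k) {
      min(v[peak_idx[k]:peak_idx[k + 1L]]) <= baseline + closure_tol
    }, logical(1L))
  }
  arrests <- list()
  if (length(peak_t) >= 2L) {
    gap_big <- which(periods > arrest_factor * med_p)
    for (k in gap_big)
      arrests[[length(arrests) + 1L]] <- c(peak_t[k] + med_p, peak_t[k + 1L])
  }
  if (peak_t[1L] - span[1L] > arrest_factor * med_p)
    arrests <- c(list(c(span[1L], peak_t[1L])), arrests)
  if (span[2L] - peak_t[length(peak_t)] > arrest_factor * med_p)
    arrests[[length(arrests) + 1L]] <-
      c(peak_t[length(peak_t)] + med_p, span[2L])
  structure(list(peak_times = peak_t, peak_values = pk$value,
                 peak_indices = peak_idx, baseline = baseline,
                 cycle_periods = periods, arrest_intervals = arrests,
                 closure_ok_per_cycle = closure_ok),
            class = "oscillogram_features")
}

#' @export
print.oscillogram_features <- function(x, ...) {
  cat(sprintf("<oscillogram_features> %d peak(s), baseline %.3g, median period %s s\n",
              length(x$peak_times), x$baseline,
              if (length(x$cycle_periods))
                sprintf("%.3g", stats::median(x$cycle_periods)) else "NA"))
  if (length(x$arrest_intervals))
    cat("  arrests:", paste(vapply(x$arrest_intervals, function(iv)
      sprintf("[%.3g, %.3g]", iv[1L], iv[2L]), character(1L)),
      collapse = " "), "\n")
  if (length(x$closure_ok_per_cycle))
    cat(sprintf("  closure verified in %d/%d cycles\n",
                sum(x$closure_ok_per_cycle), length(x$closure_ok_per_cycle)))
  invisible(x)
}

#' Flood-fill segmentation of a dye packet
#'
#' Region growing from a seed pixel, the automated counterpart of outlining
#' a dye packet with a wand tool: the segment is the set of pixels
#' connected to the seed whose intensity differs from the seed intensity by
#' at most `tolerance`. Connectivity is 8-connected by default (the legacy
#' wand behaviour) and switchable to 4.
#'
#' @param frame Numeric matrix.
#' @param seed_point `c(row, col)` inside the frame.
#' @param tolerance Intensity tolerance (>= 0).
#' @param connectivity 8 (default) or 4.
#' @param pixel_size Optional um/px to report area in um^2.
#' @param background_max Optional intensity; a seed at or below it is
#'   treated as lying on background: a single-pixel segment is returned
#'   with a warning instead of flooding the background.
#' @return An object of class `packet_segment`: `pixels` (n x 2 matrix of
#'   row/col), `area_px`, `area_um2` (NA without `pixel_size`),
#'   `mean_intensity`, `seed_point`, `connectivity`.
#' @export
segment_packet <- function(frame, seed_point, tolerance,
                           connectivity = 8L, pixel_size = NULL,
                           background_max = NULL) {
  stopifnot(is.matrix(frame), length(seed_point) == 2L)
  h <- nrow(frame); w <- ncol(frame)
  sr <- as.integer(seed_point[1L]); sc <- as.integer(seed_point[2L])
  if (sr < 1L || sr > h || sc < 1L || sc > w)
    stop("seed point outside the frame", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  seed_val <- frame[sr, sc]
  make_segment <- function(px_mat) {
    vals <- frame[px_mat]
    structure(list(pixels = px_mat, area_px = nrow(px_mat),
                   area_um2 = if (is.null(pixel_size)) NA_real_
                              else nrow(px_mat) * pixel_size^2,
                   mean_intensity = mean(vals),
                   seed_point = c(sr, sc),
                   connectivity = as.integer(connectivity)),
              class = "packet_segment")
  }
  if (!is.null(background_max) && seed_val <= background_max) {
    warning("seed lies on background (intensity ", seed_val, " <= ",
            background_max, "): returning single-pixel segment")
    return(make_segment(matrix(c(sr, sc), 1L, 2L,
                               dimnames = list(NULL, c("row", "col")))))
  }
  ok <- abs(frame - seed_val) <= tolerance
  visited <- matrix(FALSE, h, w)
  visited[sr, sc] <- TRUE
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  frontier_r <- sr; frontier_c <- sc
  all_r <- sr; all_c <- sc
  while (length(frontier_r)) {
    nr <- integer(0); nc <- integer(0)
    for (k in seq_along(dr)) {
      rr <- frontier_r + dr[k]; cc <- frontier_c + dc[k]
      keep <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      rr <- rr[keep]; cc <- cc[keep]
      if (!length(rr)) next
      lin <- cbind(rr, cc)
      fresh <- ok[lin] & !visited[lin]
      if (any(fresh)) {
        rr <- rr[fresh]; cc <- cc[fresh]
        visited[cbind(rr, cc)] <- TRUE
        nr <- c(nr, rr); nc <- c(nc, cc)
      }
    }
    if (length(nr)) {
      d <- !duplicated(cbind(nr, nc))
      nr <- nr[d]; nc <- nc[d]
    }
    all_r <- c(all_r, nr); all_c <- c(all_c, nc)
    frontier_r <- nr; frontier_c <- nc
  }
  make_segment(matrix(c(all_r, all_c), ncol = 2L,
                      dimnames = list(NULL, c("row", "col"))))
}

#' @export
print.packet_segment <- function(x, ...) {
  cat(sprintf("<packet_segment> %d px%s, mean intensity %.4g, seed (%d, %d), %d-connected\n",
              x$area_px,
              if (is.na(x$area_um2)) "" else sprintf(" (%.4g um^2)", x$area_um2),
              x$mean_intensity, x$seed_point[1L], x$seed_point[2L],
              x$connectivity))
  invisible(x)
}

#' Mean intensity of dye packets across cycles
#'
#' Segments one dye packet per analysed cycle (one seed per cycle) and
#' reports the per-packet mean intensity together with the per-animal
#' summary (mean over packets) -- the per-beat ejected-dye readout. Seeds
#' that do not land on a packet (segment smaller than `min_area_px` or on
#' background) are flagged and excluded from the summary.
#'
#' @param stack A single-channel [video_stack()] (background-subtracted).
#' @param seeds Data frame with columns `frame`, `row`, `col`, one row per
#'   analysed cycle.
#' @param tolerance Flood-fill intensity tolerance.
#' @param min_area_px Minimum credible packet area; default 4 px.
#' @param ... Passed to [segment_packet()] (`connectivity`,
#'   `background_max`).
#' @return List with `segments` (one [segment_packet()] result per seed),
#'   `mean_intensities` (NA where excluded), `summary_mean`, `n_excluded`.
#' @export
packet_intensity_series <- function(stack, seeds, tolerance,
                                    min_area_px = 4L, ...) {
  stopifnot(inherits(stack, "video_stack"), is.data.frame(seeds))
  if (!all(c("frame", "row", "col") %in% names(seeds)))
    stop("`seeds` needs columns frame, row, col", call. = FALSE)
  segs <- vector("list", nrow(seeds))
  vals <- rep(NA_real_, nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    fr <- get_frame(stack, seeds$frame[i])
    seg <- segment_packet(fr, c(seeds$row[i], seeds$col[i]), tolerance,
                          pixel_size = stack$pixel_size, ...)
    segs[[i]] <- seg
    if (seg$area_px >= min_area_px) vals[i] <- seg$mean_intensity
  }
  list(segments = segs, mean_intensities = vals,
       summary_mean = if (all(is.na(vals))) NA_real_
                      else mean(vals, na.rm = TRUE),
       n_excluded = sum(is.na(vals)))
}

#' Two-ROI transit-time velocimetry
#'
#' Estimates hemolymph velocity in the aorta from two ROI oscillograms: per
#' cycle, the transit time is the interval between a packet's intensity
#' peak in the posterior ROI and its matching peak in the anterior ROI;
#' velocity is the ROI separation divided by the mean transit time over the
#' first `n_cycles` matched cycles. Peaks are matched order-preservingly:
#' each posterior peak takes the first unused anterior peak that follows it
#' within one median cycle period.
#'
#' @param trace_posterior,trace_anterior [intensity_trace()]s on the same
#'   time base (posterior upstream of anterior).
#' @param distance Centre-to-centre ROI separation in mm (> 0).
#' @param n_cycles Number of matched cycles to average. Default 3.
#' @param min_prominence,refine_peaks Passed to [detect_cycles()];
#'   sub-frame refinement is worthwhile here because transit times span
#'   only a handful of frames.
#' @return Object of class `velocity_estimate`: `velocity` (mm/s),
#'   `transit_times` (s, the cycles used), `distance`, `matches` (data
#'   frame of matched peak times).
#' @export
estimate_velocity <- function(trace_posterior, trace_anterior, distance,
                              n_cycles = 3L, min_prominence = NULL,
                              refine_peaks = FALSE) {
  stopifnot(inherits(trace_posterior, "intensity_trace"),
            inherits(trace_anterior, "intensity_trace"))
  if (!isTRUE(all.equal(trace_posterior$times, trace_anterior$times)))
    stop("traces must share a time base", call. = FALSE)
  if (!is.numeric(distance) || distance <= 0)
    stop("`distance` must be positive (mm)", call. = FALSE)
  fp <- detect_cycles(trace_posterior, min_prominence = min_prominence,
                      refine_peaks = refine_peaks)
  fa <- detect_cycles(trace_anterior, min_prominence = min_prominence,
                      refine_peaks = refine_peaks)
  if (!length(fp$peak_times) || !length(fa$peak_times))
    stop("no peaks detected in ",
         if (!length(fp$peak_times)) "posterior" else "anterior",
         " trace", call. = FALSE)
  med_p <- if (length(fp$cycle_periods)) stats::median(fp$cycle_periods)
           else diff(range(trace_posterior$times))
  used <- logical(length(fa$peak_times))
  m_post <- numeric(0); m_ant <- numeric(0); orphans <- numeric(0)
  for (tp in fp$peak_times) {
    j <- which(!used & fa$peak_times > tp &
                 fa$peak_times <= tp + med_p)
    if (length(j)) {
      used[j[1L]] <- TRUE
      m_post <- c(m_post, tp); m_ant <- c(m_ant, fa$peak_times[j[1L]])
    } else {
      orphans <- c(orphans, tp)
    }
  }
  if (length(m_post) < n_cycles)
    stop(sprintf(paste0("only %d matched peak pair(s), %d requested; ",
                        "unmatched posterior peaks at: %s"),
                 length(m_post), n_cycles,
                 if (length(orphans))
                   paste(sprintf("%.3g s", orphans), collapse = ", ")
                 else "none"), call. = FALSE)
  transit <- (m_ant - m_post)[seq_len(n_cycles)]
  if (any(transit <= 0))
    stop("non-positive transit time: flow direction violated", call. = FALSE)
  structure(list(velocity = distance / mean(transit),
                 transit_times = transit, distance = distance,
                 matches = data.frame(posterior = m_post, anterior = m_ant)),
            class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("<velocity_estimate> %.4g mm/s over %.4g mm (%d cycle(s); transit %s s)\n",
              x$velocity, x$distance, length(x$transit_times),
              paste(sprintf("%.4g", x$transit_times), collapse = ", ")))
  invisible(x)
}
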