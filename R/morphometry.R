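# Fold an axial angle (radians) into [-pi/2, pi/2).
fold_axial <- function(a) ((a + pi / 2) %% pi) - pi / 2

#' Fourier directionality histogram of an oriented texture
#'
#' Orientation analysis by Fourier components: the windowed 2-D power
#' spectrum is computed, every spectral sample (excluding the DC
#' neighbourhood) is assigned to the angular bin of the image structure it
#' represents, and per-bin power is normalised to sum 1. Oriented fibers
#' concentrate spectral power at the frequency angle of their normal, so
#' the histogram peaks at the fiber orientation. Defaults follow the
#' common Fourier-components directionality setup: 90 bins of 2 degrees
#' covering \[-90, 90).
#'
#' Angles are axial (theta and theta + 180 degrees are the same fiber) and
#' use the package convention: 0 = horizontal structures, positive =
#' counter-clockwise on screen. A Hann window suppresses edge leakage.
#'
#' @param image Numeric matrix, side >= 64 px.
#' @param n_bins Number of angular bins over 180 degrees. Default 90.
#' @return Object of class `orientation_histogram`: `bin_centers`
#'   (degrees), `amplitudes` (normalised power, sums to 1),
#'   `dominant_angle` (centre of the maximal bin, degrees), `dispersion`
#'   (axial circular standard deviation, degrees).
#' @export
directionality_histogram <- function(image, n_bins = 90L) {
  stopifnot(is.matrix(image))
  h <- nrow(image); w <- ncol(image)
  if (min(h, w) < 64L)
    stop("image side must be >= 64 px for a stable spectrum", call. = FALSE)
  n_bins <- as.integer(n_bins)
  binw <- 180 / n_bins
  centers <- seq(-90 + binw / 2, 90 - binw / 2, by = binw)
  uniform <- function() {
    warning("spectrally flat image: directionality undefined",
            call. = FALSE)
    structure(list(bin_centers = centers,
                   amplitudes = rep(1 / n_bins, n_bins),
                   dominant_angle = NA_real_, dispersion = NA_real_),
              class = "orientation_histogram")
  }
  if (max(image) == min(image)) return(uniform())
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  win <- outer(hann(h), hann(w))
  img <- (image - mean(image)) * win
  P <- Mod(stats::fft(img))^2
  fr <- (seq_len(h) - 1) / h; fr[fr > 0.5] <- fr[fr > 0.5] - 1
  fc <- (seq_len(w) - 1) / w; fc[fc > 0.5] <- fc[fc > 0.5] - 1
  FR <- matrix(fr, h, w); FC <- matrix(fc, h, w, byrow = TRUE)
  rad <- sqrt(FR^2 + FC^2)
  keep <- rad * min(h, w) >= 3          # exclude DC / window leakage core
  if (sum(P[keep]) <= 0) return(uniform())
  # structure angle: counter-clockwise on screen, axial
  ang <- fold_axial(atan2(FC[keep], FR[keep])) * 180 / pi
  pw <- P[keep]
  bin <- pmin(pmax(floor((ang + 90) / binw) + 1L, 1L), n_bins)
  amp <- vapply(seq_len(n_bins), function(b) sum(pw[bin == b]), numeric(1L))
  amp <- amp / sum(amp)
  dom <- centers[which.max(amp)]
  # axial circular dispersion via doubled angles
  z <- sum(amp * exp(2i * centers * pi / 180))
  R <- Mod(z)
  disp <- if (R > 0) sqrt(-2 * log(R)) / 2 * 180 / pi else Inf
  structure(list(bin_centers = centers, amplitudes = amp,
                 dominant_angle = dom, dispersion = disp),
            class = "orientation_histogram")
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf("<orientation_histogram> %d bins; dominant %.4g deg, dispersion %.3g deg\n",
              length(x$bin_centers), x$dominant_angle, x$dispersion))
  invisible(x)
}

#' Myofiber coverage density in an ROI
#'
#' Threshold-based density: the fraction of ROI pixels whose intensity
#' exceeds the threshold (Otsu by default, or a fixed value). Reads out
#' how much of the sampled heart-wall area is covered by stained
#' myofibers.
#'
#' @param image Numeric matrix in \[0, 255\].
#' @param roi Optional [roi_spec()]; default whole image.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold Fixed threshold (8-bit), required when
#'   `threshold_method = "fixed"`.
#' @return Fraction in \[0, 1\].
#' @export
fiber_density <- function(image, roi = NULL,
                          threshold_method = c("otsu", "fixed"),
                          threshold = NULL) {
  stopifnot(is.matrix(image))
  threshold_method <- match.arg(threshold_method)
  sub <- if (is.null(roi)) image else {
    check_roi_in_bounds(roi, nrow(image), ncol(image), "image")
    image[roi_rows(roi), roi_cols(roi)]
  }
  if (threshold_method == "fixed") {
    if (is.null(threshold)) stop("fixed method needs `threshold`",
                                 call. = FALSE)
    thr <- threshold
  } else {
    if (max(sub) == min(sub))
      stop("Otsu threshold failed: constant ROI has no bimodality",
           call. = FALSE)
    thr <- EBImage::otsu(EBImage::Image(sub / 255), range = c(0, 1)) * 255
  }
  mean(sub > thr)
}

# TRUE if the two closed segments p1-p2 and p3-p4 properly intersect.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1L] - a[1L]) * (c[2L] - a[2L]) -
    (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Area of a simple polygon
#'
#' Shoelace area of a polygon outline (e.g. a heart lumen traced on an
#' orthogonal confocal section), converted to um^2.
#'
#' @param vertices Numeric matrix/data frame of `(row, col)` vertices in
#'   order (>= 3, not all collinear, non-self-intersecting).
#' @param pixel_size um/px. Default 1.
#' @return Area in um^2.
#' @export
polygon_area <- function(vertices, pixel_size = 1) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L)
    stop("need >= 3 (row, col) vertices", call. = FALSE)
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) <= 1L || (i == 1L && j == n) || (i == n && j == 1L))
      next
    if (segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]))
      stop("polygon is self-intersecting", call. = FALSE)
  }
  area_px <- abs(sum(v[, 1L] * v[nxt, 2L] - v[nxt, 1L] * v[, 2L])) / 2
  if (area_px == 0) stop("vertices are collinear", call. = FALSE)
  area_px * pixel_size^2
}

#' Moment-ellipse shape descriptors of a binary mask
#'
#' Fits the ellipse whose second-order central moments match the mask's
#' (the standard fitted ellipse of shape-descriptor tools: axes
#' `4 * sqrt(eigenvalue)` of the pixel covariance) and reports the larval
#' shape readouts. Roundness is `4 * area / (pi * major_axis^2)` -- the
#' inverse aspect ratio for an ellipse: 1 for a circle, toward 0 for an
#' elongated body.
#'
#' @param mask Logical or numeric matrix; non-zero pixels form one
#'   connected component.
#' @param pixel_size um/px. Default 1.
#' @return Object of class `shape_descriptors`: `area` (um^2),
#'   `major_axis`, `minor_axis` (um), `orientation` (radians,
#'   counter-clockwise from the column axis, axial in \[-pi/2, pi/2)),
#'   `roundness`.
#' @export
fit_shape_descriptors <- function(mask, pixel_size = 1) {
  stopifnot(is.matrix(mask))
  m <- mask > 0
  if (!any(m)) stop("empty mask", call. = FALSE)
  lab <- EBImage::bwlabel(m)
  if (max(lab) != 1L)
    stop("mask must contain exactly one connected component (found ",
         max(lab), ")", call. = FALSE)
  idx <- which(m, arr.ind = TRUE)
  r <- idx[, 1L]; c_ <- idx[, 2L]
  mr <- mean(r); mc <- mean(c_)
  cov <- matrix(c(mean((r - mr)^2), mean((r - mr) * (c_ - mc)),
                  mean((r - mr) * (c_ - mc)), mean((c_ - mc)^2)), 2L, 2L)
  eg <- eigen(cov, symmetric = TRUE)
  major <- 4 * sqrt(max(eg$values[1L], 0)) * pixel_size
  minor <- 4 * sqrt(max(eg$values[2L], 0)) * pixel_size
  v <- eg$vectors[, 1L]
  orientation <- fold_axial(atan2(-v[1L], v[2L]))
  area <- nrow(idx) * pixel_size^2
  structure(list(area = area, major_axis = major, minor_axis = minor,
                 orientation = orientation,
                 roundness = if (major > 0) 4 * area / (pi * major^2)
                             else NA_real_),
            class = "shape_descriptors")
}

#' @export
print.shape_descriptors <- function(x, ...) {
  cat(sprintf(paste0("<shape_descriptors> area %.4g um^2; axes %.4g x %.4g um; ",
                     "orientation %.3g deg; roundness %.3g\n"),
              x$area, x$major_axis, x$minor_axis,
              x$orientation * 180 / pi, x$roundness))
  invisible(x)
}
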