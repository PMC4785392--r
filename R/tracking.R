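# NIR diameter tracking: per-frame moving threshold from vessel and
# background ROIs, background-normalized line profile, supra-threshold
# pixel counting, and micrometre scaling. Image frames are numeric matrices
# indexed [row (y), column (x)], 1-based pixel centres.

# Pixel-centre coordinates of every in-frame pixel whose centre lies within
# `radius` of `center` (x, y). Errors when the disc misses the frame.
.discIndex <- function(dim, center, radius) {
  xlo <- max(1, floor(center[1] - radius))
  xhi <- min(dim[2], ceiling(center[1] + radius))
  ylo <- max(1, floor(center[2] - radius))
  yhi <- min(dim[1], ceiling(center[2] + radius))
  if (xlo > xhi || ylo > yhi)
    stopInvalid("disc lies outside the frame")
  xr <- xlo:xhi; yr <- ylo:yhi
  g <- expand.grid(y = yr, x = xr)
  keep <- (g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2
  if (!any(keep)) stopInvalid("disc contains no pixel centres inside the frame")
  cbind(g$y[keep], g$x[keep])
}

#' Mean intensity over a circular ROI
#'
#' Mean over the pixels whose centres lie within the disc (a pixel belongs
#' to the disc iff its centre is within the radius). Pixels outside the
#' frame are ignored; a disc entirely outside the frame is an error.
#'
#' @param frame numeric matrix, \code{frame[y, x]}.
#' @param center (x, y) disc centre in pixels.
#' @param radius disc radius in pixels.
#' @return Mean intensity.
#' @export
discMean <- function(frame, center, radius) {
  idx <- .discIndex(dim(frame), center, radius)
  mean(frame[idx])
}

#' Moving threshold from vessel and background ROI intensities
#'
#' The per-frame vessel-edge threshold: the mean signal intensity of the
#' vessel ROI divided by the mean signal intensity of the background ROI.
#' "Moving" because it is re-evaluated at every time point, absorbing
#' perfusion and contractility-driven brightness changes.
#'
#' @param vesselMFI,backgroundMFI mean ROI intensities (background > 0).
#' @return The dimensionless threshold T.
#' @examples
#' movingThreshold(600, 100)  # 6.0, the typical NIR vessel/background regime
#' @export
movingThreshold <- function(vesselMFI, backgroundMFI) {
  if (!is.finite(backgroundMFI) || backgroundMFI <= 0)
    stopInvalid("background MFI must be positive")
  vesselMFI / backgroundMFI
}

# Line sample positions for a geometry: round(3r) + 1 points at unit-pixel
# spacing from the background-ROI centre (center + 2r n) through the vessel
# centre to the far edge of the vessel ROI (center - r n).
.linePositions <- function(geometry) {
  gc <- geometry@center; nv <- geometry@normal; r <- geometry@r
  start <- gc + 2 * r * nv
  nSamp <- round(3 * r) + 1
  u <- -nv                                  # toward the vessel and beyond
  s <- (seq_len(nSamp) - 1)
  cbind(x = start[1] + s * u[1], y = start[2] + s * u[2])
}

# Bilinear interpolation of frame values at fractional (x, y) positions.
.bilinear <- function(frame, pos) {
  d <- dim(frame)
  x <- pos[, "x"]; y <- pos[, "y"]
  if (any(x < 1 - 1e-9 | x > d[2] + 1e-9 | y < 1 - 1e-9 | y > d[1] + 1e-9))
    stopInvalid("measurement line exits the frame")
  x <- pmin(pmax(x, 1), d[2]); y <- pmin(pmax(y, 1), d[1])
  x0 <- pmin(floor(x), d[2] - 1L); y0 <- pmin(floor(y), d[1] - 1L)
  fx <- x - x0; fy <- y - y0
  v00 <- frame[cbind(y0, x0)];     v01 <- frame[cbind(y0, x0 + 1)]
  v10 <- frame[cbind(y0 + 1, x0)]; v11 <- frame[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Sample the vessel-bisecting line profile
#'
#' Intensities at unit-pixel spacing along the measurement line defined by
#' the geometry, ordered from the background-ROI centre toward the far edge
#' of the vessel ROI, interpolated bilinearly. The first ten samples lie in
#' the background region and serve as the profile normalizer.
#'
#' @param frame numeric matrix.
#' @param geometry a [VesselGeometry-class].
#' @return A list with \code{samples} (numeric, \code{round(3r) + 1} values)
#'   and \code{positions} (matrix of x, y pixel coordinates).
#' @export
sampleLineProfile <- function(frame, geometry) {
  stopifnot(is(geometry, "VesselGeometry"))
  pos <- .linePositions(geometry)
  list(samples = .bilinear(frame, pos), positions = pos)
}

#' Convert a line profile to a diameter
#'
#' Normalizes the profile by the mean of its first ten samples (the
#' background reference of that frame), counts the samples whose normalized
#' intensity strictly exceeds the threshold, and scales the count to
#' micrometres. All supra-threshold samples are counted, with no contiguity
#' requirement (COUNTIF semantics); \code{contiguous = TRUE} instead counts
#' the longest contiguous supra-threshold run.
#'
#' @param profile numeric vector of line-profile samples (>= 10), or the
#'   list returned by [sampleLineProfile()].
#' @param threshold the moving threshold T (see [movingThreshold()]).
#' @param scale micrometres per pixel.
#' @param contiguous count the longest contiguous run instead (default FALSE).
#' @return A list with \code{pixelCount} and \code{diameter} (um). A count
#'   of zero flags possible occlusion or an unperfused vessel, not an error.
#' @export
profileToDiameter <- function(profile, threshold, scale, contiguous = FALSE) {
  p <- if (is.list(profile)) profile$samples else as.numeric(profile)
  if (length(p) < 10)
    stopInvalid("profile needs at least 10 samples for background normalization")
  norm <- mean(p[1:10])
  if (!is.finite(norm) || norm <= 0)
    stopInvalid("profile background normalizer must be positive")
  above <- (p / norm) > threshold
  count <- if (!contiguous) sum(above) else {
    r <- rle(above)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  }
  list(pixelCount = as.integer(count), diameter = count * scale)
}

#' Track vessel diameter through an image stack
#'
#' Applies the full per-frame pipeline: vessel and background ROI means,
#' moving threshold, line-profile sampling, background normalization,
#' supra-threshold pixel counting and micrometre scaling. Frames whose
#' background MFI or profile normalizer is non-positive are marked missing
#' (NA) rather than interpolated; more than 10% failed frames aborts.
#'
#' @param stack 3-D numeric array \code{[row, col, frame]} (see
#'   [readStack()]), or a list of frames.
#' @param geometry a [VesselGeometry-class].
#' @param frameRate frames per second.
#' @param contiguous see [profileToDiameter()].
#' @return A list with \code{trace} (a [Trace-class] of diameters in um;
#'   NULL if any frame failed), \code{table} (data.frame with columns
#'   \code{frame}, \code{time_s}, \code{diameter_um}, \code{pixel_count},
#'   \code{threshold}, \code{vessel_mfi}, \code{background_mfi}) and
#'   \code{failures} (indices of failed frames).
#' @export
trackDiameter <- function(stack, geometry, frameRate = 2.5,
                          contiguous = FALSE) {
  stopifnot(is(geometry, "VesselGeometry"))
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) != 3) stopInvalid("stack must be [row, col, frame]")
  d <- dim(stack)
  nFrames <- d[3]
  gc <- geometry@center; nv <- geometry@normal; r <- geometry@r
  vIdx <- .discIndex(d[1:2], gc, r)
  bCenter <- gc + 2 * r * nv
  bIdx <- .discIndex(d[1:2], bCenter, 0.5 * r)
  pos <- .linePositions(geometry)

  out <- data.frame(frame = seq_len(nFrames),
                    time_s = (seq_len(nFrames) - 1) / frameRate,
                    diameter_um = NA_real_, pixel_count = NA_integer_,
                    threshold = NA_real_, vessel_mfi = NA_real_,
                    background_mfi = NA_real_)
  failures <- integer(0)
  for (j in seq_len(nFrames)) {
    frame <- stack[, , j]
    v <- mean(frame[vIdx]); b <- mean(frame[bIdx])
    out$vessel_mfi[j] <- v; out$background_mfi[j] <- b
    if (!is.finite(b) || b <= 0) { failures <- c(failures, j); next }
    th <- v / b
    prof <- .bilinear(frame, pos)
    nrm <- mean(prof[1:10])
    if (!is.finite(nrm) || nrm <= 0) { failures <- c(failures, j); next }
    cnt <- sum((prof / nrm) > th)
    if (contiguous) {
      rl <- rle((prof / nrm) > th)
      m <- rl$lengths[rl$values]
      cnt <- if (length(m)) max(m) else 0L
    }
    out$threshold[j] <- th
    out$pixel_count[j] <- as.integer(cnt)
    out$diameter_um[j] <- cnt * geometry@scale
  }
  if (length(failures) > 0.1 * nFrames)
    stopInvalid(sprintf("diameter tracking failed on %d of %d frames",
                        length(failures), nFrames))
  trace <- if (length(failures) == 0)
    Trace(out$diameter_um, frameRate, t0 = 0) else NULL
  list(trace = trace, table = out, failures = failures)
}

#' Extract a mean-fluorescence-intensity trace from a stack
#'
#' Per-frame mean intensity over a circular ROI — the NIR fluorescence
#' contractility readout. Optionally subtracts a background ROI mean per
#' frame.
#'
#' @param stack 3-D array \code{[row, col, frame]} or list of frames.
#' @param center (x, y) ROI centre in pixels.
#' @param radius ROI radius in pixels.
#' @param frameRate frames per second.
#' @param background optional list(center =, radius =) of a background ROI
#'   whose per-frame mean is subtracted.
#' @return A [Trace-class].
#' @export
extractMFITrace <- function(stack, center, radius, frameRate = 2.5,
                            background = NULL) {
  if (is.list(stack) && !is.array(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) != 3) stopInvalid("stack must be [row, col, frame]")
  d <- dim(stack)
  idx <- .discIndex(d[1:2], center, radius)
  bIdx <- if (!is.null(background))
    .discIndex(d[1:2], background$center, background$radius) else NULL
  vals <- vapply(seq_len(d[3]), function(j) {
    frame <- stack[, , j]
    m <- mean(frame[idx])
    if (!is.null(bIdx)) m - mean(frame[bIdx]) else m
  }, numeric(1))
  Trace(vals, frameRate, t0 = 0)
}

#' Suggest a measurement geometry from a frame
#'
#' Optional helper: estimates the vessel axis row of a (roughly horizontal)
#' vessel from the row-mean intensity ridge and proposes a geometry with the
#' normal pointing toward the image edge with more background room. Never a
#' substitute for user-confirmed geometry — the returned object is a
#' starting point to adjust.
#'
#' @param frame numeric matrix.
#' @param scale micrometres per pixel.
#' @param r vessel ROI radius in pixels; default 2x the estimated
#'   full-width-at-half-maximum of the ridge.
#' @return A [VesselGeometry-class].
#' @export
suggestGeometry <- function(frame, scale, r = NULL) {
  rowMean <- rowMeans(frame)
  axis <- which.max(rowMean)
  bg <- stats::median(rowMean)
  half <- bg + (rowMean[axis] - bg) / 2
  above <- which(rowMean > half)
  fwhm <- if (length(above)) diff(range(above)) + 1 else 10
  if (is.null(r)) r <- max(3, 2 * fwhm)
  dirUp <- axis > nrow(frame) / 2     # more room above?
  normal <- if (dirUp) c(0, -1) else c(0, 1)
  vesselGeometry(center = c(ncol(frame) / 2, axis), normal = normal,
                 r = r, scale = scale)
}
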