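# Bilinear interpolation of a 2D image (rows = y, cols = x; pixel centers at
# (index - 1) * voxel) at points (y_um, x_um).
bilinear <- function(img, y_um, x_um, voxel_xy) {
  yi <- y_um / voxel_xy; xi <- x_um / voxel_xy
  ny <- nrow(img); nx <- ncol(img)
  y0 <- pmin(pmax(floor(yi), 0), ny - 2); x0 <- pmin(pmax(floor(xi), 0), nx - 2)
  fy <- yi - y0; fx <- xi - x0
  i <- cbind(y0 + 1, x0 + 1)
  v00 <- img[i]; v01 <- img[cbind(y0 + 1, x0 + 2)]
  v10 <- img[cbind(y0 + 2, x0 + 1)]; v11 <- img[cbind(y0 + 2, x0 + 2)]
  v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
    v10 * fy * (1 - fx) + v11 * fy * fx
}

#' Extract a 2D plane from a movie stack
#'
#' @param stack 5D array `t x c x z x y x x`.
#' @param frame Frame index.
#' @param channel Channel index.
#' @param z Slice index, or `"max"` for a maximum-intensity projection
#'   along z (the default matches how 3D panels are typically rendered).
#' @return A 2D matrix (y, x).
#' @export
extract_plane <- function(stack, frame, channel, z = "max") {
  pl <- stack[frame, channel, , , ]
  if (identical(z, "max")) {
    apply(pl, c(2, 3), max)
  } else {
    matrix(pl[z, , ], dim(stack)[4], dim(stack)[5])
  }
}

#' Intensity profile along a line segment
#'
#' Samples one or more co-registered 2D images by bilinear interpolation at
#' evenly spaced points from `p0` to `p1` and normalizes each channel by the
#' profile maximum, reproducing the line-scan panels used to visualize zone
#' segregation within single cisternae.
#'
#' @param images A 2D matrix (one channel) or list of 2D matrices (rows =
#'   y, cols = x), e.g. from [extract_plane()].
#' @param p0,p1 Segment endpoints `c(y_um, x_um)` in image coordinates
#'   (pixel-center convention), inside the image.
#' @param spacing Sample spacing along the segment, um; defaults to half a
#'   pixel.
#' @param voxel_xy Pixel size, um.
#' @param normalize Normalize each channel by its profile maximum.
#' @return A `line_profile`: list with `position_um` (0 at `p0`),
#'   `intensity` (samples x channels), `profile` (normalized, max 1 per
#'   channel when `normalize`), `p0`, `p1`.
#' @export
profile_along_line <- function(images, p0, p1, spacing = NULL, voxel_xy = 0.1,
                               normalize = TRUE) {
  if (is.matrix(images)) images <- list(images)
  if (is.null(spacing)) spacing <- voxel_xy / 2
  stopifnot_scalar(spacing, "spacing"); stopifnot_scalar(voxel_xy, "voxel_xy")
  if (length(p0) != 2L || length(p1) != 2L) {
    stop("'p0' and 'p1' must be c(y_um, x_um)", call. = FALSE)
  }
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length segment", call. = FALSE)
  ext <- c(nrow(images[[1]]) - 1, ncol(images[[1]]) - 1) * voxel_xy
  for (p in list(p0, p1)) {
    if (any(p < 0) || p[1] > ext[1] || p[2] > ext[2]) {
      stop("segment endpoints must lie inside the image", call. = FALSE)
    }
  }
  pos <- seq(0, len, by = spacing)
  if (pos[length(pos)] < len) pos <- c(pos, len)
  fy <- p0[1] + (p1[1] - p0[1]) * pos / len
  fx <- p0[2] + (p1[2] - p0[2]) * pos / len
  raw <- vapply(images, bilinear, numeric(length(pos)),
                y_um = fy, x_um = fx, voxel_xy = voxel_xy)
  raw <- matrix(raw, nrow = length(pos))
  prof <- if (normalize) {
    apply(raw, 2, function(v) if (max(v) > 0) v / max(v) else v)
  } else raw
  prof <- matrix(prof, nrow = length(pos))
  structure(list(position_um = pos, intensity = raw, profile = prof,
                 p0 = p0, p1 = p1), class = "line_profile")
}

#' Zone-segregation metrics of a two-channel line profile
#'
#' Scalar summaries of how far apart the two markers' sub-zones sit along
#' the scan line: the distance between the per-channel profile maxima and
#' the distance between the per-channel intensity centroids.
#'
#' @param profile A [profile_along_line()] result with >= 2 channels.
#' @param channels Which two channels to compare.
#' @return Named numeric: `peak_offset_um`, `centroid_offset_um`.
#' @export
segregation_metrics <- function(profile, channels = c(1L, 2L)) {
  ii <- profile$intensity[, channels, drop = FALSE]
  if (ncol(ii) != 2L) stop("need two channels", call. = FALSE)
  for (j in 1:2) {
    if (diff(range(ii[, j])) == 0) {
      stop("flat profile in a channel: segregation is undefined", call. = FALSE)
    }
  }
  x <- profile$position_um
  peaks <- vapply(1:2, function(j) x[which.max(ii[, j])], 0)
  cents <- vapply(1:2, function(j) sum(x * ii[, j]) / sum(ii[, j]), 0)
  c(peak_offset_um = abs(peaks[1] - peaks[2]),
    centroid_offset_um = abs(cents[1] - cents[2]))
}
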