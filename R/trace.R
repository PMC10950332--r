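#' Extract a per-cisterna multi-channel fluorescence trace
#'
#' For every frame of a track's lifetime (bridged gaps included, with
#' linearly interpolated centers) the mean intensity over a spherical ROI --
#' ellipsoidal in voxel units, so the z anisotropy is respected -- is
#' computed per channel, optionally background-subtracted, and normalized to
#' F/F_peak, where F_peak is the channel maximum over the observation
#' period.
#'
#' @param track_spots Rows of a `track_table` belonging to one track.
#' @param stack 5D array `t x c x z x y x x` of counts.
#' @param config The [acquisition_config()] of the stack (voxel sizes and
#'   frame interval).
#' @param roi_radius ROI radius, um; the default 0.35 um covers a 0.5 um
#'   cisterna plus PSF spread.
#' @param background Background policy: `"none"` (raw ROI means),
#'   `"constant"` (subtract `background_value`) or `"median"` (subtract the
#'   per-frame, per-channel image median).
#' @param background_value Constant background, counts.
#' @return A `cisterna_trace`: list with `time_s`, `frame`, `F` (matrix
#'   frames x channels), `F_norm` (F/F_peak per channel), `centers`,
#'   `roi_radius`, `background`.
#' @export
extract_trace <- function(track_spots, stack, config, roi_radius = 0.35,
                          background = c("none", "constant", "median"),
                          background_value = 0) {
  background <- match.arg(background)
  stopifnot_scalar(roi_radius, "roi_radius")
  if (length(dim(stack)) != 5L) stop("'stack' must be t x c x z x y x x")
  ctr <- track_centers(track_spots)
  nch <- dim(stack)[2]
  dims <- dim(stack)[3:5]
  voxel <- c(config$voxel_z, config$voxel_xy, config$voxel_xy)
  Fmat <- matrix(NA_real_, nrow(ctr), nch)
  truncated <- FALSE
  for (i in seq_len(nrow(ctr))) {
    cen <- c(ctr$z_um[i], ctr$y_um[i], ctr$x_um[i])
    rng <- vector("list", 3)
    for (a in 1:3) {
      lo <- floor((cen[a] - roi_radius) / voxel[a]) + 1L
      hi <- ceiling((cen[a] + roi_radius) / voxel[a]) + 1L
      if (lo < 1L || hi > dims[a]) truncated <- TRUE
      rng[[a]] <- max(1L, lo):min(dims[a], hi)
    }
    dz2 <- (((rng[[1]] - 1) * voxel[1] - cen[1]) / roi_radius)^2
    dy2 <- (((rng[[2]] - 1) * voxel[2] - cen[2]) / roi_radius)^2
    dx2 <- (((rng[[3]] - 1) * voxel[3] - cen[3]) / roi_radius)^2
    inside <- outer(outer(dz2, dy2, "+"), dx2, "+") <= 1
    if (!any(inside)) next
    for (ch in seq_len(nch)) {
      cube <- stack[ctr$frame[i], ch, rng[[1]], rng[[2]], rng[[3]]]
      val <- mean(cube[inside])
      if (background == "median") {
        val <- val - median(stack[ctr$frame[i], ch, , , ])
      } else if (background == "constant") {
        val <- val - background_value
      }
      Fmat[i, ch] <- val
    }
  }
  if (truncated) {
    warning("ROI truncated at the image boundary for some frames")
  }
  Fnorm <- apply(Fmat, 2, function(x) {
    m <- max(x, na.rm = TRUE)
    if (is.finite(m) && m > 0) x / m else x
  })
  structure(list(time_s = (ctr$frame - 1L) * config$frame_interval,
                 frame = ctr$frame, F = Fmat, F_norm = Fnorm,
                 centers = ctr, roi_radius = roi_radius,
                 background = background),
            class = "cisterna_trace")
}

#' Locate the fluorescence peak of one channel
#'
#' The series is smoothed with a centered moving average (shrinking windows
#' at the edges) and the time of its maximum is returned; ties are broken to
#' the earliest time. No sub-frame interpolation is attempted, so peak times
#' are frame times.
#'
#' @param intensity Numeric intensity series (>= 3 samples).
#' @param time_s Sample times, seconds (strictly increasing, same length).
#' @param smoothing_window Moving-average window in frames (odd; 1 disables
#'   smoothing).
#' @return Peak time in seconds.
#' @export
find_peak <- function(intensity, time_s, smoothing_window = 3L) {
  if (length(intensity) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (length(time_s) != length(intensity) || any(diff(time_s) <= 0)) {
    stop("'time_s' must be strictly increasing and match 'intensity'",
         call. = FALSE)
  }
  if (smoothing_window %% 2L != 1L) {
    stop("'smoothing_window' must be odd", call. = FALSE)
  }
  ok <- is.finite(intensity)
  if (!all(ok)) stop("intensity contains non-finite values", call. = FALSE)
  sm <- moving_average(intensity, smoothing_window)
  if (diff(range(sm)) == 0) {
    stop("no unique peak: trace is constant after smoothing", call. = FALSE)
  }
  time_s[which.max(sm)]
}

#' Peak-to-peak delay of a two-channel trace
#'
#' The maturation statistic: the time between the green-channel and
#' red-channel fluorescence maxima of one cisterna, positive when the red
#' marker peaks later, together with the midpoint used as the alignment
#' origin.
#'
#' @param trace A [extract_trace()] result (or any list with `time_s` and a
#'   frames x channels matrix `F`).
#' @param green,red Channel indices.
#' @param smoothing_window Passed to [find_peak()].
#' @return A `peak_pair`: list with `t_green_peak`, `t_red_peak`, `delta`
#'   (= red - green, s) and `midpoint` (= (green + red) / 2, s).
#' @export
peak_to_peak <- function(trace, green = 1L, red = 2L, smoothing_window = 3L) {
  tg <- find_peak(trace$F[, green], trace$time_s, smoothing_window)
  tr <- find_peak(trace$F[, red], trace$time_s, smoothing_window)
  structure(list(t_green_peak = tg, t_red_peak = tr, delta = tr - tg,
                 midpoint = (tg + tr) / 2),
            class = "peak_pair")
}

#' Align traces at their peak midpoints and average
#'
#' Each cisterna's time axis is shifted so that time 0 is the midpoint
#' between its green and red fluorescence peaks; the normalized traces are
#' then resampled by linear interpolation onto a common grid and averaged.
#' Only traces covering a grid point contribute to its mean and SEM (no
#' extrapolation).
#'
#' @param traces List of [extract_trace()] results.
#' @param pairs Optional list of matching [peak_to_peak()] results (computed
#'   with defaults when omitted).
#' @param grid_spacing Grid spacing in seconds (default: the trace frame
#'   spacing).
#' @param label Optional label for the marker pair.
#' @return A `maturation_summary`: `n`, `delta_mean`, `delta_sd`,
#'   `delta_sem`, `grid` (aligned times, s), `curve_mean`, `curve_sem`,
#'   `curve_n` (grid x channel matrices of F/F_peak statistics) and
#'   `deltas` (per-cisterna values).
#' @export
align_and_average <- function(traces, pairs = NULL, grid_spacing = NULL,
                              label = NULL) {
  if (!length(traces)) stop("need at least one trace", call. = FALSE)
  if (is.null(pairs)) pairs <- lapply(traces, peak_to_peak)
  if (length(pairs) != length(traces)) {
    stop("'pairs' must match 'traces'", call. = FALSE)
  }
  if (is.null(grid_spacing)) {
    grid_spacing <- min(diff(traces[[1]]$time_s))
  }
  deltas <- vapply(pairs, function(p) p$delta, 0)
  nch <- ncol(traces[[1]]$F)
  shifted <- Map(function(tr, p) tr$time_s - p$midpoint, traces, pairs)
  lo <- floor(min(vapply(shifted, min, 0)) / grid_spacing) * grid_spacing
  hi <- ceiling(max(vapply(shifted, max, 0)) / grid_spacing) * grid_spacing
  grid <- seq(lo, hi, by = grid_spacing)
  curve_mean <- curve_sem <- matrix(NA_real_, length(grid), nch)
  curve_n <- matrix(0L, length(grid), nch)
  for (ch in seq_len(nch)) {
    vals <- vapply(seq_along(traces), function(i) {
      approx(shifted[[i]], traces[[i]]$F_norm[, ch], xout = grid,
             rule = 1)$y
    }, numeric(length(grid)))
    vals <- matrix(vals, nrow = length(grid))
    n <- rowSums(!is.na(vals))
    curve_n[, ch] <- n
    curve_mean[, ch] <- ifelse(n > 0, rowMeans(vals, na.rm = TRUE), NA_real_)
    rs <- apply(vals, 1, function(v) if (sum(!is.na(v)) > 1)
      sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))) else NA_real_)
    curve_sem[, ch] <- rs
  }
  structure(list(label = label, n = length(traces),
                 delta_mean = mean(deltas),
                 delta_sd = if (length(deltas) > 1) sd(deltas) else NA_real_,
                 delta_sem = if (length(deltas) > 1) std_err(deltas) else NA_real_,
                 deltas = deltas, grid = grid, curve_mean = curve_mean,
                 curve_sem = curve_sem, curve_n = curve_n),
            class = "maturation_summary")
}

#' @export
print.maturation_summary <- function(x, ...) {
  cat(sprintf("maturation_summary%s: n = %d cisternae\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"), x$n))
  cat(sprintf("  peak-to-peak delay: %.1f +/- %.1f s (mean +/- SD), SEM %.2f s\n",
              x$delta_mean, x$delta_sd, x$delta_sem))
  invisible(x)
}

#' Residence interval of an averaged marker curve
#'
#' First and last times at which a mean F/F_peak curve stays at or above a
#' threshold fraction of its maximum, with linear interpolation at the
#' crossings; a simple operational definition of a marker's residence
#' period on the maturing cisterna.
#'
#' @param grid Aligned time grid, seconds.
#' @param curve Mean normalized curve on `grid` (maximum 1).
#' @param threshold_fraction Threshold as a fraction of the peak
#'   (default 0.2). 0 returns the full observed support.
#' @return Numeric `c(start, end)` in seconds.
#' @export
residency_interval <- function(grid, curve, threshold_fraction = 0.2) {
  ok <- is.finite(curve)
  grid <- grid[ok]; curve <- curve[ok]
  if (!length(curve)) stop("empty curve", call. = FALSE)
  if (threshold_fraction <= 0) return(range(grid))
  above <- curve >= threshold_fraction
  if (!any(above)) {
    stop("curve never reaches the threshold", call. = FALSE)
  }
  first <- which(above)[1]
  last <- rev(which(above))[1]
  start <- if (first == 1L) grid[1] else {
    approx(curve[(first - 1):first], grid[(first - 1):first],
           xout = threshold_fraction)$y
  }
  end <- if (last == length(curve)) grid[length(grid)] else {
    approx(curve[last:(last + 1)], grid[last:(last + 1)],
           xout = threshold_fraction)$y
  }
  c(start, end)
}
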