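# Add an axis-aligned 3D Gaussian spot to `arr` ([z, y, x]) in place-ish
# (returns the modified array). center/sigmas in um; voxel centers at
# (index - 1) * voxel size.
add_gaussian_spot <- function(arr, center, sigmas, amplitude, voxel) {
  dims <- dim(arr)
  idx <- vector("list", 3)
  g <- vector("list", 3)
  for (a in 1:3) {
    half <- 4 * sigmas[a]
    lo <- max(1L, floor((center[a] - half) / voxel[a]) + 1L)
    hi <- min(dims[a], ceiling((center[a] + half) / voxel[a]) + 1L)
    if (lo > hi) return(arr)
    idx[[a]] <- lo:hi
    x <- (idx[[a]] - 1) * voxel[a]
    g[[a]] <- exp(-(x - center[a])^2 / (2 * sigmas[a]^2))
  }
  patch <- amplitude * (g[[1]] %o% g[[2]] %o% g[[3]])
  # c() both sides: length-1 ranges would otherwise drop dims
  arr[idx[[1]], idx[[2]], idx[[3]]] <-
    arr[idx[[1]], idx[[2]], idx[[3]]] + c(patch)
  arr
}

# Per-axis total Gaussian sigma of a rendered object: object size (sigma =
# diameter / 4) convolved with the PSF -> variances add.
spot_sigmas <- function(diameter, config) {
  so2 <- (diameter / 4)^2
  c(sqrt(config$psf_sigma_z^2 + so2),
    sqrt(config$psf_sigma_xy^2 + so2),
    sqrt(config$psf_sigma_xy^2 + so2))
}

#' Render a ground-truthed multi-channel 4D movie
#'
#' Renders every cisterna marker as a 3D Gaussian spot (object size convolved
#' analytically with the PSF) at its per-frame center plus the marker's
#' sub-zone offset, scaled by the marker's kinetic pulse; static ERES spots
#' are added to their channel. Expected photon counts are then passed through
#' Poisson shot noise, and Gaussian read noise plus the camera offset are
#' added. With the same config (including seed) and scene the output is
#' bit-identical.
#'
#' @param config An [acquisition_config()].
#' @param scene A list with elements `cisternae` (list of [sim_cisterna()])
#'   and `eres` (list of [sim_eres()]), e.g. from [sim_maturation_scene()].
#' @param noise If `FALSE`, return noiseless expected counts (no offset).
#' @return A list of class `sim_movie`:
#' \describe{
#'   \item{stack}{5D array `t x c x z x y x x` of counts.}
#'   \item{config}{the acquisition config.}
#'   \item{truth}{ground truth: `cisternae` (id, per-channel true peak times,
#'     true red-minus-green delay, birth/death), `centers` (per frame true
#'     centers) and `contacts` (programmed contact events).}
#' }
#' @export
generate_movie <- function(config, scene, noise = TRUE) {
  if (!inherits(config, "acquisition_config")) {
    stop("'config' must be an acquisition_config", call. = FALSE)
  }
  cisternae <- scene$cisternae
  eres <- if (is.null(scene$eres)) list() else scene$eres
  n_channels <- max(1L,
                    vapply(cisternae, function(ci) length(ci$kinetics), 0L),
                    vapply(eres, function(e) e$channel, 0L))
  voxel <- c(config$voxel_z, config$voxel_xy, config$voxel_xy)
  ext <- (c(config$nz, config$ny, config$nx) - 1) * voxel
  times <- frame_times(config)

  # field-of-view check: every rendered center must stay inside with a margin
  for (ci in cisternae) {
    if (nrow(ci$trajectory) != config$n_frames) {
      stop(sprintf("cisterna %d: trajectory has %d rows, movie has %d frames",
                   ci$id, nrow(ci$trajectory), config$n_frames), call. = FALSE)
    }
    margin <- ci$diameter / 4
    offs <- vapply(ci$kinetics, function(k) k$zone_offset, numeric(3))
    reach <- apply(abs(offs), 1, max)
    for (a in 1:3) {
      lo <- min(ci$trajectory[, a]) - reach[a] - margin
      hi <- max(ci$trajectory[, a]) + reach[a] + margin
      if (lo < 0 || hi > ext[a]) {
        stop(sprintf("cisterna %d leaves the field of view along axis %d",
                     ci$id, a), call. = FALSE)
      }
    }
  }

  stack <- array(0, dim = c(config$n_frames, n_channels,
                            config$nz, config$ny, config$nx))
  for (t in seq_len(config$n_frames)) {
    for (ch in seq_len(n_channels)) {
      frame <- array(0, dim = c(config$nz, config$ny, config$nx))
      for (ci in cisternae) {
        if (ch > length(ci$kinetics)) next
        k <- ci$kinetics[[ch]]
        amp <- kinetic_profile(times[t], k)
        if (amp < 1e-4 * max(k$amplitude, 1e-12)) next
        frame <- add_gaussian_spot(frame, ci$trajectory[t, ] + k$zone_offset,
                                   spot_sigmas(ci$diameter, config), amp,
                                   voxel)
      }
      for (e in eres) {
        if (e$channel != ch) next
        frame <- add_gaussian_spot(frame, e$position,
                                   spot_sigmas(e$diameter, config),
                                   e$amplitude, voxel)
      }
      stack[t, ch, , , ] <- frame
    }
  }

  if (noise) {
    stack <- with_seed(config$seed, {
      n <- length(stack)
      counts <- rpois(n, stack * config$photons_per_unit)
      counts <- counts + config$camera_offset +
        rnorm(n, 0, config$read_noise_sd)
      array(counts, dim = dim(stack))
    })
  }

  empty_cis <- data.frame(cisterna = integer(), peak_green_s = numeric(),
                          peak_red_s = numeric(), delta_true_s = numeric(),
                          birth_s = numeric(), death_s = numeric(),
                          diameter_um = numeric())
  truth_cis <- do.call(rbind, lapply(cisternae, function(ci) {
    peaks <- vapply(ci$kinetics, function(k) k$peak_time, 0)
    data.frame(
      cisterna = ci$id,
      peak_green_s = peaks[1],
      peak_red_s = if (length(peaks) >= 2) peaks[2] else NA_real_,
      delta_true_s = if (length(peaks) >= 2) peaks[2] - peaks[1] else NA_real_,
      birth_s = ci$birth_time, death_s = ci$death_time,
      diameter_um = ci$diameter)
  }))
  truth_centers <- do.call(rbind, lapply(cisternae, function(ci) {
    data.frame(cisterna = ci$id, frame = seq_len(config$n_frames),
               time_s = times, z_um = ci$trajectory[, 1],
               y_um = ci$trajectory[, 2], x_um = ci$trajectory[, 3])
  }))
  if (is.null(truth_cis)) truth_cis <- empty_cis
  if (is.null(truth_centers)) {
    truth_centers <- data.frame(cisterna = integer(), frame = integer(),
                                time_s = numeric(), z_um = numeric(),
                                y_um = numeric(), x_um = numeric())
  }
  truth_contacts <- do.call(rbind, lapply(eres, function(e) {
    if (!nrow(e$contact_schedule)) return(NULL)
    cbind(eres = e$id, e$contact_schedule)
  }))
  if (is.null(truth_contacts)) {
    truth_contacts <- data.frame(eres = integer(), cisterna = integer(),
                                 start_s = numeric(), end_s = numeric())
  }
  eres_tab <- do.call(rbind, lapply(eres, function(e) {
    data.frame(eres = e$id, z_um = e$position[1], y_um = e$position[2],
               x_um = e$position[3], diameter_um = e$diameter,
               channel = e$channel)
  }))
  if (is.null(eres_tab)) {
    eres_tab <- data.frame(eres = integer(), z_um = numeric(),
                           y_um = numeric(), x_um = numeric(),
                           diameter_um = numeric(), channel = integer())
  }

  structure(list(stack = stack, config = config,
                 truth = list(cisternae = truth_cis, centers = truth_centers,
                              contacts = truth_contacts, eres = eres_tab)),
            class = "sim_movie")
}
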