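#' Acquisition configuration for simulated SCLIM-style movies
#'
#' Describes the voxel grid, temporal sampling, point-spread function and
#' camera noise of a simulated spinning-disk confocal acquisition. Axis order
#' is (z, y, x) everywhere; a voxel with 0-based index i has its center at
#' i * voxel size, in micrometers.
#'
#' @param nx,ny,nz Field of view in voxels (x, y) and optical slices (z).
#' @param voxel_xy,voxel_z Voxel size in micrometers. The default z step of
#'   0.2 um matches the 4D maturation acquisitions the simulator emulates.
#' @param n_frames Number of time points.
#' @param frame_interval Time between volumes, seconds (default 5 s).
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigma in micrometers. The
#'   lateral default corresponds to ~180 nm FWHM.
#' @param camera_offset Constant camera offset, counts.
#' @param read_noise_sd Gaussian read noise, counts.
#' @param photons_per_unit Expected photon count produced by one intensity
#'   unit of the rendered scene at a voxel.
#' @param seed Integer seed controlling the shot/read noise of
#'   [generate_movie()].
#' @return An object of class `acquisition_config` (a named list).
#' @examples
#' cfg <- acquisition_config(nx = 32, ny = 32, nz = 9, n_frames = 4)
#' cfg$frame_interval
#' @export
acquisition_config <- function(nx = 64, ny = 64, nz = 21,
                               voxel_xy = 0.1, voxel_z = 0.2,
                               n_frames = 30, frame_interval = 5,
                               psf_sigma_xy = 0.0765, psf_sigma_z = 0.2,
                               camera_offset = 100, read_noise_sd = 3,
                               photons_per_unit = 200, seed = 1L) {
  for (nm in c("nx", "ny", "nz", "n_frames")) {
    stopifnot_scalar(get(nm), nm, positive = TRUE, integer = TRUE)
  }
  for (nm in c("voxel_xy", "voxel_z", "frame_interval",
               "psf_sigma_xy", "psf_sigma_z", "photons_per_unit")) {
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  }
  stopifnot_scalar(camera_offset, "camera_offset", positive = FALSE)
  stopifnot_scalar(read_noise_sd, "read_noise_sd", positive = FALSE)
  if (camera_offset < 0 || read_noise_sd < 0) {
    stop("'camera_offset' and 'read_noise_sd' must be >= 0", call. = FALSE)
  }
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
    voxel_xy = voxel_xy, voxel_z = voxel_z,
    n_frames = as.integer(n_frames), frame_interval = frame_interval,
    psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
    camera_offset = camera_offset, read_noise_sd = read_noise_sd,
    photons_per_unit = photons_per_unit, seed = as.integer(seed)
  ), class = "acquisition_config")
}

#' Acquisition presets mirroring the three SCLIM imaging regimes
#'
#' `preset_survey()` is the single-timepoint 3D survey (41 slices, 0.2 um
#' apart), `preset_maturation()` the 4D maturation regime (21 slices, 0.2 um,
#' one volume every 5 s) and `preset_contact()` the fast ERES-contact regime
#' (9 slices, 0.25 um, one volume every 1.1 s).
#'
#' @param ... Overrides passed on to [acquisition_config()].
#' @return An `acquisition_config`.
#' @export
preset_maturation <- function(...) {
  args <- modify_defaults(list(nz = 21L, voxel_z = 0.2, frame_interval = 5),
                          list(...))
  do.call(acquisition_config, args)
}

#' @rdname preset_maturation
#' @export
preset_contact <- function(...) {
  args <- modify_defaults(list(nz = 9L, voxel_z = 0.25, frame_interval = 1.1,
                               n_frames = 40L), list(...))
  do.call(acquisition_config, args)
}

#' @rdname preset_maturation
#' @export
preset_survey <- function(...) {
  args <- modify_defaults(list(nz = 41L, voxel_z = 0.2, n_frames = 1L),
                          list(...))
  do.call(acquisition_config, args)
}

modify_defaults <- function(defaults, overrides) {
  defaults[names(overrides)] <- overrides
  defaults
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "acquisition_config: %d x %d x %d voxels (%.3g x %.3g um), %d frames @ %.3g s\n",
    x$nx, x$ny, x$nz, x$voxel_xy, x$voxel_z, x$n_frames, x$frame_interval))
  cat(sprintf("  PSF sigma %.3g/%.3g um (xy/z); offset %g, read noise %g, %g photons/unit\n",
              x$psf_sigma_xy, x$psf_sigma_z, x$camera_offset,
              x$read_noise_sd, x$photons_per_unit))
  invisible(x)
}

frame_times <- function(config) {
  (seq_len(config$n_frames) - 1L) * config$frame_interval
}
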