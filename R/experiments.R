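#' Replicated delay-recovery experiment
#'
#' Simulates movies whose per-cisterna red-minus-green peak delays are drawn
#' from a normal distribution with the given mean and SD, runs the full
#' detect/track/trace/summarize pipeline on each, and reports the estimated
#' mean delay per replicate plus the grand mean. This is the calibration
#' experiment for the peak-to-peak estimator: with an unbiased pipeline the
#' grand mean converges to the programmed mean.
#'
#' @param delay_mean,delay_sd Programmed delay distribution, seconds.
#' @param n_cisternae Cisternae per replicate movie.
#' @param n_reps Number of replicate simulations.
#' @param base_seed Integer; replicate r uses seed `base_seed * 1000 + r`.
#' @param params A [pipeline_params()].
#' @return List with `per_rep` (data frame: rep, seed, n_kept, mean_delta_s,
#'   true_mean_delta_s), `grand_mean_s`, `grand_true_mean_s`, and the
#'   programmed `delay_mean`/`delay_sd`.
#' @export
delay_recovery_experiment <- function(delay_mean, delay_sd, n_cisternae,
                                      n_reps = 20L, base_seed = 1L,
                                      params = pipeline_params()) {
  per <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    seed <- base_seed * 1000L + r
    scene <- sim_maturation_scene(n_cisternae, delay_mean, delay_sd,
                                  seed = seed)
    cfg <- scene$config; cfg$seed <- seed
    movie <- generate_movie(cfg, scene)
    res <- analyze_movie(movie, params = params)
    per[[r]] <- data.frame(
      rep = r, seed = seed, n_kept = nrow(res$pairs),
      mean_delta_s = if (nrow(res$pairs)) mean(res$pairs$delta_s) else NA_real_,
      true_mean_delta_s = mean(movie$truth$cisternae$delta_true_s))
  }
  per <- do.call(rbind, per)
  list(per_rep = per,
       grand_mean_s = mean(per$mean_delta_s, na.rm = TRUE),
       grand_true_mean_s = mean(per$true_mean_delta_s),
       delay_mean = delay_mean, delay_sd = delay_sd)
}

#' Diameter-recovery experiment for isolated puncta
#'
#' Renders isolated spots of known diameter one per small noisy volume,
#' detects them, and collects the PSF-corrected diameter estimates.
#'
#' @param n_spots Number of spots (one per rendered volume).
#' @param diameter True diameter, um.
#' @param base_seed Integer seed.
#' @param config Optional [acquisition_config()] template for the small
#'   volumes.
#' @return List with `diameters_um` (per-spot estimates), `mean_um`,
#'   `n_detected`.
#' @export
diameter_recovery_experiment <- function(n_spots = 50L, diameter = 0.5,
                                         base_seed = 1L, config = NULL) {
  if (is.null(config)) {
    config <- acquisition_config(nx = 28, ny = 28, nz = 15, n_frames = 1L)
  }
  voxel <- c(config$voxel_z, config$voxel_xy, config$voxel_xy)
  ext <- (c(config$nz, config$ny, config$nx) - 1) * voxel
  est <- numeric(0)
  for (i in seq_len(n_spots)) {
    seed <- base_seed * 1000L + i
    frame <- with_seed(seed, {
      ctr <- ext / 2 + runif(3, -0.5, 0.5) * voxel
      arr <- add_gaussian_spot(array(0, dim = c(config$nz, config$ny, config$nx)),
                               ctr, spot_sigmas(diameter, config), 1, voxel)
      n <- length(arr)
      array(rpois(n, arr * config$photons_per_unit) + config$camera_offset +
              rnorm(n, 0, config$read_noise_sd), dim = dim(arr))
    })
    sp <- detect_spots(frame, voxel_xy = config$voxel_xy,
                       voxel_z = config$voxel_z,
                       psf_sigma_xy = config$psf_sigma_xy,
                       psf_sigma_z = config$psf_sigma_z)
    if (nrow(sp)) est <- c(est, sp$diameter_um[which.max(sp$response)])
  }
  list(diameters_um = est, mean_um = mean(est), n_detected = length(est))
}

#' Contact-recovery experiment at fast sampling
#'
#' Simulates hug-and-kiss scenes at the 1.1 s contact preset, detects and
#' tracks the visiting cisternae, detects contact events against the true
#' ERES position, and compares recovered event durations with the
#' programmed dwell times.
#'
#' @param n_reps Replicate scenes.
#' @param n_cisternae Visiting cisternae per scene.
#' @param base_seed Integer seed.
#' @param contact_distance,min_frames Passed to [detect_contacts()].
#' @return List with `events` (recovered), `truth` (programmed),
#'   `mean_recovered_s`, `mean_true_s` (over matched events),
#'   `mean_abs_error_s`.
#' @export
contact_recovery_experiment <- function(n_reps = 6L, n_cisternae = 3L,
                                        base_seed = 1L,
                                        contact_distance = 0.35,
                                        min_frames = 2L) {
  all_ev <- list(); all_truth <- list(); errs <- numeric(0)
  for (r in seq_len(n_reps)) {
    seed <- base_seed * 1000L + r
    scene <- sim_contact_scene(n_cisternae = n_cisternae, seed = seed)
    cfg <- scene$config; cfg$seed <- seed
    movie <- generate_movie(cfg, scene)
    # detect + track the cisterna (green) channel only
    nt <- dim(movie$stack)[1]
    spots <- do.call(rbind, lapply(seq_len(nt), function(t) {
      sp <- detect_spots(movie$stack[t, 1, , , ],
                         voxel_xy = cfg$voxel_xy, voxel_z = cfg$voxel_z,
                         psf_sigma_xy = cfg$psf_sigma_xy,
                         psf_sigma_z = cfg$psf_sigma_z)
      if (nrow(sp)) sp$frame <- t
      sp
    }))
    tracks <- link_tracks(spots, max_displacement = 1.2, max_gap = 1L)
    ev <- detect_contacts(tracks, movie$truth$eres,
                          frame_interval = cfg$frame_interval,
                          contact_distance = contact_distance,
                          min_frames = min_frames)
    truth <- movie$truth$contacts
    truth$duration_s <- truth$end_s - truth$start_s
    # match each true contact to the recovered event overlapping it in time
    for (k in seq_len(nrow(truth))) {
      if (!nrow(ev)) next
      t0 <- (ev$start_frame - 1) * cfg$frame_interval
      t1 <- (ev$end_frame - 1) * cfg$frame_interval
      hit <- which(t1 >= truth$start_s[k] - cfg$frame_interval &
                     t0 <= truth$end_s[k] + cfg$frame_interval)
      if (length(hit)) {
        hit <- hit[1]
        errs <- c(errs, ev$duration_s[hit] - truth$duration_s[k])
        all_ev[[length(all_ev) + 1L]] <-
          cbind(rep = r, ev[hit, , drop = FALSE])
        all_truth[[length(all_truth) + 1L]] <-
          cbind(rep = r, truth[k, , drop = FALSE])
      }
    }
  }
  ev <- if (length(all_ev)) do.call(rbind, all_ev) else NULL
  tr <- if (length(all_truth)) do.call(rbind, all_truth) else NULL
  list(events = ev, truth = tr,
       mean_recovered_s = if (!is.null(ev)) mean(ev$duration_s) else NA_real_,
       mean_true_s = if (!is.null(tr)) mean(tr$duration_s) else NA_real_,
       mean_abs_error_s = if (length(errs)) mean(abs(errs)) else NA_real_,
       n_matched = length(errs))
}
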