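#' A simulated maturing cisterna
#'
#' @param id Integer id, unique within a scene.
#' @param trajectory Matrix `n_frames` x 3 of center positions (z, y, x, um),
#'   one row per frame.
#' @param kinetics List of [marker_kinetics()], one per channel.
#' @param diameter Cisterna diameter, um (default 0.5, the punctum size the
#'   analysis is built around).
#' @param birth_time,death_time Appearance window, seconds. Defaults are
#'   derived from the kinetics (first peak minus 3 rise sigmas to last peak
#'   plus 3 decay sigmas), giving lifetimes of a few minutes with the default
#'   widths.
#' @return A `sim_cisterna` object.
#' @export
sim_cisterna <- function(id, trajectory, kinetics, diameter = 0.5,
                         birth_time = NULL, death_time = NULL) {
  stopifnot_scalar(diameter, "diameter")
  if (!is.matrix(trajectory) || ncol(trajectory) != 3L) {
    stop("'trajectory' must be an n_frames x 3 matrix (z, y, x um)",
         call. = FALSE)
  }
  if (!length(kinetics) || !all(vapply(kinetics, inherits, TRUE,
                                       "marker_kinetics"))) {
    stop("'kinetics' must be a list of marker_kinetics, one per channel",
         call. = FALSE)
  }
  peaks <- vapply(kinetics, function(k) k$peak_time, 0)
  if (is.null(birth_time)) {
    birth_time <- min(vapply(kinetics, function(k)
      k$peak_time - 3 * k$rise_sigma, 0))
  }
  if (is.null(death_time)) {
    death_time <- max(vapply(kinetics, function(k)
      k$peak_time + 3 * k$decay_sigma, 0))
  }
  if (death_time <= birth_time) {
    stop("'death_time' must be greater than 'birth_time'", call. = FALSE)
  }
  structure(list(id = as.integer(id), trajectory = trajectory,
                 kinetics = kinetics, diameter = diameter,
                 birth_time = birth_time, death_time = death_time),
            class = "sim_cisterna")
}

#' A simulated ER exit site (static reference punctum)
#'
#' ERES are rendered as immobile spots; `contact_schedule` records the
#' intervals during which a partner cisterna is programmed to sit within
#' contact range (the "hug-and-kiss" events), as a data frame with columns
#' `cisterna`, `start_s`, `end_s`.
#'
#' @param id Integer id.
#' @param position Length-3 center (z, y, x um).
#' @param diameter Spot diameter, um (default 0.5).
#' @param amplitude Peak intensity, arbitrary units.
#' @param channel Channel index the ERES marker is imaged in.
#' @param contact_schedule Data frame of programmed contacts (may be empty).
#' @return A `sim_eres` object.
#' @export
sim_eres <- function(id, position, diameter = 0.5, amplitude = 1,
                     channel = 2L, contact_schedule = NULL) {
  if (length(position) != 3L) stop("'position' must be length 3 (z, y, x)")
  stopifnot_scalar(diameter, "diameter")
  if (is.null(contact_schedule)) {
    contact_schedule <- data.frame(cisterna = integer(), start_s = numeric(),
                                   end_s = numeric())
  }
  structure(list(id = as.integer(id), position = as.numeric(position),
                 diameter = diameter, amplitude = amplitude,
                 channel = as.integer(channel),
                 contact_schedule = contact_schedule),
            class = "sim_eres")
}

# Confined random walk: per-frame Gaussian steps of sd `step_sd`, reflected
# at a box of half-width `confinement` around `home`. Cisterna speeds are not
# known from live imaging, so the defaults are chosen to keep tracks linkable
# at 5 s sampling (see the methods vignette).
confined_walk <- function(home, n_frames, step_sd = 0.08, confinement = 0.2) {
  pos <- matrix(0, n_frames, 3)
  cur <- c(0, 0, 0)
  for (t in seq_len(n_frames)) {
    cur <- cur + rnorm(3, 0, step_sd)
    # triangle-wave reflection into [-confinement, confinement]
    cur <- confinement -
      abs((cur + confinement) %% (4 * confinement) - 2 * confinement)
    pos[t, ] <- home + cur
  }
  pos
}

# Jittered 3D grid of home positions with guaranteed minimum spacing, inside
# the field of view with margin.
home_grid <- function(n, config, margin = 0.8, spacing = 1.3, jitter = 0.12) {
  ext <- c((config$nz - 1) * config$voxel_z,
           (config$ny - 1) * config$voxel_xy,
           (config$nx - 1) * config$voxel_xy)
  lo <- rep(margin, 3)
  hi <- ext - margin
  if (any(hi <= lo)) stop("field of view too small for the requested margin")
  nxy <- pmax(1L, floor((hi - lo)[2:3] / spacing) + 1L)
  nz <- pmax(1L, floor((hi - lo)[1] / spacing) + 1L)
  gz <- seq(lo[1], hi[1], length.out = nz)
  gy <- seq(lo[2], hi[2], length.out = nxy[1])
  gx <- seq(lo[3], hi[3], length.out = nxy[2])
  sites <- as.matrix(expand.grid(z = gz, y = gy, x = gx))
  if (nrow(sites) < n) {
    stop(sprintf("field of view holds only %d well-separated cisternae (%d requested)",
                 nrow(sites), n))
  }
  sites <- sites[sample.int(nrow(sites), n), , drop = FALSE]
  sites + matrix(rnorm(3 * n, 0, jitter), n, 3)
}

#' Build a two-channel maturation scene with programmed peak-to-peak delays
#'
#' Creates `n_cisternae` cisternae whose green-channel peaks are staggered
#' uniformly over a short window and whose red-minus-green peak delays are
#' drawn from a normal distribution with the given mean and SD, emulating a
#' measured marker pair. The movie length is chosen so that (for delays
#' within 3.5 SD of the mean) both peaks fall well inside the observation
#' window, mirroring the selection of trackable cisternae with two
#' detectable peaks.
#'
#' @param n_cisternae Number of cisternae.
#' @param delay_mean,delay_sd Mean and SD of the programmed red-minus-green
#'   peak delays, seconds. Negative draws are allowed.
#' @param config Optional [acquisition_config()]; `n_frames` and the lateral
#'   field of view are enlarged as needed.
#' @param rise_sigma,decay_sigma Pulse widths, seconds.
#' @param zone_separation Distance between the green and red sub-zones, um
#'   (split symmetrically along x).
#' @param seed Integer seed for delays, stagger and trajectories.
#' @return A list with `config` (possibly resized), `cisternae` (list of
#'   [sim_cisterna()]), `eres` (empty list) and `truth` (see
#'   [generate_movie()] for the rendered counterpart).
#' @export
sim_maturation_scene <- function(n_cisternae, delay_mean = 31, delay_sd = 24.1,
                                 config = NULL, rise_sigma = 25,
                                 decay_sigma = 25, zone_separation = 0,
                                 seed = 1L) {
  stopifnot_scalar(n_cisternae, "n_cisternae", integer = TRUE)
  if (is.null(config)) config <- preset_maturation(seed = seed)
  # green peaks must sit late enough that even the most negative plausible
  # red peak stays clear of the movie start
  t0 <- 15 + max(5, 3.5 * delay_sd - delay_mean)
  stagger <- 5 * config$frame_interval
  t_end <- t0 + stagger + delay_mean + 3.5 * delay_sd +
    2 * config$frame_interval + 10
  n_frames <- as.integer(ceiling(t_end / config$frame_interval) + 1L)
  nx <- config$nx
  if (n_cisternae > 16) nx <- max(nx, 96L)  # room for dense scenes
  config <- acquisition_config(
    nx = nx, ny = nx, nz = config$nz, voxel_xy = config$voxel_xy,
    voxel_z = config$voxel_z, n_frames = max(config$n_frames, n_frames),
    frame_interval = config$frame_interval, psf_sigma_xy = config$psf_sigma_xy,
    psf_sigma_z = config$psf_sigma_z, camera_offset = config$camera_offset,
    read_noise_sd = config$read_noise_sd,
    photons_per_unit = config$photons_per_unit, seed = config$seed)
  with_seed(seed, {
    homes <- home_grid(n_cisternae, config)
    t_green <- runif(n_cisternae, t0, t0 + stagger)
    # antithetic normal draws: each delay is marginally N(mean, sd^2) but
    # (z, -z) pairing keeps the realized per-scene mean close to the
    # programmed one, sharpening recovery benchmarks
    m <- ceiling(n_cisternae / 2)
    z <- rnorm(m)
    delays <- delay_mean + delay_sd * c(z, -z)[seq_len(n_cisternae)]
    cisternae <- lapply(seq_len(n_cisternae), function(i) {
      off <- c(0, 0, zone_separation / 2)
      sim_cisterna(
        id = i,
        trajectory = confined_walk(homes[i, ], config$n_frames),
        kinetics = list(
          marker_kinetics(t_green[i], rise_sigma, decay_sigma,
                          zone_offset = -off),
          marker_kinetics(t_green[i] + delays[i], rise_sigma, decay_sigma,
                          zone_offset = off)))
    })
    list(config = config, cisternae = cisternae, eres = list())
  })
}

#' Build a fast-sampling ERES contact scene
#'
#' One static ERES (red channel) and `n_cisternae` cisternae (green channel)
#' that each approach it once, dwell within contact range for a programmed
#' 2-3 s, and withdraw -- the "hug-and-kiss" behavior. Sampling defaults to
#' the 1.1 s contact preset.
#'
#' @param n_cisternae Number of visiting cisternae.
#' @param contact_duration Length-2 range (seconds) the dwell times are drawn
#'   from, default `c(2, 3)`.
#' @param config Optional [acquisition_config()] (default [preset_contact()]).
#' @param seed Integer seed.
#' @return As [sim_maturation_scene()], plus `eres` holding one [sim_eres()]
#'   whose `contact_schedule` is the ground truth.
#' @export
sim_contact_scene <- function(n_cisternae = 3, contact_duration = c(2, 3),
                              config = NULL, seed = 1L) {
  if (is.null(config)) config <- preset_contact(seed = seed)
  if (length(contact_duration) != 2L || diff(contact_duration) < 0) {
    stop("'contact_duration' must be an increasing length-2 range")
  }
  total_t <- (config$n_frames - 1) * config$frame_interval
  with_seed(seed, {
    ext <- c((config$nz - 1) * config$voxel_z,
             (config$ny - 1) * config$voxel_xy,
             (config$nx - 1) * config$voxel_xy)
    eres_pos <- ext / 2
    sched <- data.frame(cisterna = integer(), start_s = numeric(),
                        end_s = numeric())
    far <- 1.0    # resting distance from the ERES, um
    near <- 0.15  # dwell distance, um
    slots <- seq(0.15, 0.85, length.out = n_cisternae) * total_t
    cisternae <- vector("list", n_cisternae)
    for (i in seq_len(n_cisternae)) {
      dur <- runif(1, contact_duration[1], contact_duration[2])
      start <- slots[i] + runif(1, 0, config$frame_interval)
      angle <- runif(1, 0, 2 * pi)
      dir <- c(0, sin(angle), cos(angle))
      tt <- frame_times(config)
      # piecewise distance-to-ERES: approach over one interval, dwell, leave
      dt <- config$frame_interval
      dist <- ifelse(tt < start - dt, far,
              ifelse(tt < start, far + (near - far) * (tt - (start - dt)) / dt,
              ifelse(tt <= start + dur, near,
              ifelse(tt <= start + dur + dt,
                     near + (far - near) * (tt - (start + dur)) / dt, far))))
      traj <- t(vapply(dist, function(d) eres_pos + d * dir, numeric(3)))
      # small in-plane wobble, kept well below the contact threshold
      traj <- traj + cbind(0, rnorm(config$n_frames, 0, 0.02),
                           rnorm(config$n_frames, 0, 0.02))
      cisternae[[i]] <- sim_cisterna(
        id = i, trajectory = traj,
        kinetics = list(marker_kinetics(
          peak_time = total_t / 2, rise_sigma = total_t, decay_sigma = total_t,
          amplitude = 1)))
      sched <- rbind(sched, data.frame(cisterna = i, start_s = start,
                                       end_s = start + dur))
    }
    eres <- list(sim_eres(1L, eres_pos, channel = 2L,
                          contact_schedule = sched))
    list(config = config, cisternae = cisternae, eres = eres)
  })
}
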