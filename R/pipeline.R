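#' Analysis parameters for the end-to-end pipeline
#'
#' Bundles every tunable parameter of the detect/track/trace/summarize
#' chain with its default. All lengths are in micrometers, times in
#' seconds.
#'
#' @param min_diameter,max_diameter Detection scale range, um.
#' @param threshold Detection threshold in robust SDs of the filter
#'   response.
#' @param max_displacement Linking gate per frame interval, um.
#' @param max_gap Maximum bridged detection dropout, frames.
#' @param roi_radius Trace ROI radius, um.
#' @param background Trace background policy (see [extract_trace()]).
#' @param smoothing_window Peak-finding moving-average window, frames.
#' @param min_track_frames Minimum track length used for traces.
#' @param min_peak_snr Minimum peak prominence in robust noise SDs for a
#'   channel peak to count as detected.
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(min_diameter = 0.3, max_diameter = 0.8,
                            threshold = 8, max_displacement = 0.5,
                            max_gap = 2L, roi_radius = 0.35,
                            background = "none", smoothing_window = 3L,
                            min_track_frames = 5L, min_peak_snr = 5) {
  structure(as.list(environment()), class = "pipeline_params")
}

# robust per-trace noise scale: MAD of successive differences / sqrt(2)
trace_noise_sd <- function(x) {
  d <- diff(x)
  max(mad(d) / sqrt(2), 1e-9)
}

#' Run detection, tracking, tracing and delay summarization on one movie
#'
#' Spots are detected per frame on the channel-summed volume (a maturing
#' cisterna is visible in at least one channel throughout its lifetime),
#' linked into tracks, and a two-channel trace is extracted along each
#' sufficiently long track. Cisternae are kept for the delay statistics
#' only if both channels show a detected peak (prominence above
#' `min_peak_snr` robust noise SDs) strictly inside the track's observation
#' window -- the automated equivalent of selecting cisternae whose two
#' fluorescence peaks are both captured. Excluded tracks are listed with a
#' reason.
#'
#' @param movie A `sim_movie`, or a list with `stack` (5D array) and
#'   `config` ([acquisition_config()]).
#' @param params A [pipeline_params()].
#' @return List with `spots`, `tracks` (track_table), `track_info`,
#'   `traces` (kept traces), `pairs` (per-kept-track peak times and
#'   deltas), `excluded` (track, reason), `summary`
#'   ([align_and_average()] result, or NULL if nothing was kept).
#' @export
analyze_movie <- function(movie, params = pipeline_params()) {
  stack <- movie$stack
  config <- movie$config
  nt <- dim(stack)[1]
  spots_list <- vector("list", nt)
  for (t in seq_len(nt)) {
    fr <- array(0, dim(stack)[3:5])
    for (ch in seq_len(dim(stack)[2])) fr <- fr + stack[t, ch, , , ]
    sp <- detect_spots(fr, voxel_xy = config$voxel_xy,
                       voxel_z = config$voxel_z,
                       min_diameter = params$min_diameter,
                       max_diameter = params$max_diameter,
                       threshold = params$threshold,
                       psf_sigma_xy = config$psf_sigma_xy,
                       psf_sigma_z = config$psf_sigma_z)
    if (nrow(sp)) sp$frame <- t
    spots_list[[t]] <- sp
  }
  spots <- do.call(rbind, spots_list[vapply(spots_list, nrow, 0L) > 0])
  if (is.null(spots)) {
    spots <- data.frame(frame = integer(), z_um = numeric(), y_um = numeric(),
                        x_um = numeric())
  }
  tracks <- link_tracks(spots, max_displacement = params$max_displacement,
                        max_gap = params$max_gap)
  info <- track_summary(tracks)
  traces <- list(); pairs <- list(); excluded <- list()
  keep_ids <- integer()
  for (i in seq_len(nrow(info))) {
    tid <- info$track[i]
    if (info$death_frame[i] - info$birth_frame[i] + 1L <
        params$min_track_frames) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(track = tid, reason = "track-too-short")
      next
    }
    tr <- extract_trace(tracks[tracks$track == tid, , drop = FALSE], stack,
                        config, roi_radius = params$roi_radius,
                        background = params$background)
    pk <- try(peak_to_peak(tr, smoothing_window = params$smoothing_window),
              silent = TRUE)
    if (inherits(pk, "try-error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(track = tid, reason = "no-unique-peak")
      next
    }
    edge_times <- tr$time_s[c(1L, length(tr$time_s))]
    if (pk$t_green_peak %in% edge_times || pk$t_red_peak %in% edge_times) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(track = tid, reason = "peak-at-window-edge")
      next
    }
    prom_ok <- vapply(1:2, function(ch) {
      x <- tr$F[, ch]
      (max(x) - min(x)) >= params$min_peak_snr * trace_noise_sd(x)
    }, TRUE)
    if (!all(prom_ok)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(track = tid, reason = "peak-below-noise")
      next
    }
    keep_ids <- c(keep_ids, tid)
    traces[[length(traces) + 1L]] <- tr
    pairs[[length(pairs) + 1L]] <- pk
  }
  pair_tab <- if (length(pairs)) {
    data.frame(track = keep_ids,
               t_green_peak = vapply(pairs, `[[`, 0, "t_green_peak"),
               t_red_peak = vapply(pairs, `[[`, 0, "t_red_peak"),
               delta_s = vapply(pairs, `[[`, 0, "delta"),
               midpoint_s = vapply(pairs, `[[`, 0, "midpoint"))
  } else {
    data.frame(track = integer(), t_green_peak = numeric(),
               t_red_peak = numeric(), delta_s = numeric(),
               midpoint_s = numeric())
  }
  summary <- if (length(traces)) {
    align_and_average(traces, pairs,
                      grid_spacing = config$frame_interval)
  } else NULL
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(track = integer(), reason = character())
  list(spots = spots, tracks = tracks, track_info = info, traces = traces,
       pairs = pair_tab, excluded = excluded, summary = summary)
}

# Polynomial rolling hash of a string, as 8 hex digits; stamps outputs with
# their configuration. (Stays within exact double-precision integers.)
config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 127 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' End-to-end pipeline configuration
#'
#' Round-trips losslessly through JSON; every field has a documented
#' default.
#'
#' @param n_cisternae Number of simulated cisternae.
#' @param delay_mean,delay_sd Programmed red-minus-green delay
#'   distribution, seconds.
#' @param seed Integer seed for scene and noise.
#' @param out_dir Output directory for [run_pipeline()].
#' @param params A [pipeline_params()] (stored as a plain list).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_cisternae = 10L, delay_mean = 31,
                            delay_sd = 24.1, seed = 1L, out_dir = tempdir(),
                            params = pipeline_params()) {
  structure(list(n_cisternae = as.integer(n_cisternae),
                 delay_mean = delay_mean, delay_sd = delay_sd,
                 seed = as.integer(seed), out_dir = out_dir,
                 params = unclass(params)),
            class = "pipeline_config")
}

#' Run the simulate-detect-track-trace-summarize pipeline to disk
#'
#' Simulates a maturation movie from the config, runs [analyze_movie()],
#' and writes `spots.csv`, `tracks.csv`, `traces.csv`, `pairs.csv`,
#' `summary.csv` and `excluded.csv` to the output directory, each stamped
#' (in `run_info.json`) with the seed and a hash of the configuration.
#' Rerunning with the same config reproduces identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the [analyze_movie()] result plus `files`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must be a pipeline_config", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  if (config$n_cisternae == 0L) {
    warning("zero cisternae configured: writing empty tables")
    res <- list(
      spots = data.frame(frame = integer(), z_um = numeric(),
                         y_um = numeric(), x_um = numeric()),
      tracks = data.frame(frame = integer(), z_um = numeric(),
                          y_um = numeric(), x_um = numeric(),
                          track = integer()),
      pairs = data.frame(track = integer(), t_green_peak = numeric(),
                         t_red_peak = numeric(), delta_s = numeric(),
                         midpoint_s = numeric()),
      excluded = data.frame(track = integer(), reason = character()),
      summary = NULL, traces = list())
  } else {
    scene <- sim_maturation_scene(config$n_cisternae, config$delay_mean,
                                  config$delay_sd, seed = config$seed)
    cfg <- scene$config; cfg$seed <- config$seed
    movie <- generate_movie(cfg, scene)
    res <- analyze_movie(movie, params = do.call(pipeline_params,
                                                 config$params))
  }
  files <- c(spots = "spots.csv", tracks = "tracks.csv", pairs = "pairs.csv",
             excluded = "excluded.csv")
  paths <- character()
  for (nm in names(files)) {
    p <- file.path(config$out_dir, files[[nm]])
    write.csv(res[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  trace_tab <- if (length(res$traces)) {
    do.call(rbind, lapply(seq_along(res$traces), function(i) {
      tr <- res$traces[[i]]
      nch <- ncol(tr$F)
      do.call(rbind, lapply(seq_len(nch), function(ch) {
        data.frame(trace = i, channel = ch, time_s = tr$time_s,
                   F = tr$F[, ch], F_norm = tr$F_norm[, ch])
      }))
    }))
  } else {
    data.frame(trace = integer(), channel = integer(), time_s = numeric(),
               F = numeric(), F_norm = numeric())
  }
  paths["traces"] <- file.path(config$out_dir, "traces.csv")
  write.csv(trace_tab, paths["traces"], row.names = FALSE)
  sum_tab <- if (!is.null(res$summary)) {
    s <- res$summary
    data.frame(n = s$n, delta_mean_s = s$delta_mean, delta_sd_s = s$delta_sd,
               delta_sem_s = s$delta_sem)
  } else {
    data.frame(n = integer(), delta_mean_s = numeric(),
               delta_sd_s = numeric(), delta_sem_s = numeric())
  }
  paths["summary"] <- file.path(config$out_dir, "summary.csv")
  write.csv(sum_tab, paths["summary"], row.names = FALSE)
  jsonlite::write_json(list(seed = config$seed,
                            config_hash = config_hash(as.character(cfg_json)),
                            config = unclass(config)),
                       file.path(config$out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  res$files <- paths
  invisible(res)
}
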