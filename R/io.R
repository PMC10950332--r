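#' Write a movie stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered t-major, then channel, then z (axes `t, c, z, y, x`).
#' TIFF samples are stored as 32-bit float scaled into `[0, 1]`; the scale
#' factor, axis sizes, voxel sizes and frame interval are recorded in a
#' JSON sidecar (`<path>.json`) so that [read_stack()] can restore the
#' calibrated array without guessing. Round trips are exact to float32
#' precision.
#'
#' @param stack 5D array `t x c x z x y x x`, or a `sim_movie`.
#' @param path Output TIFF path.
#' @param voxel_xy,voxel_z,frame_interval Calibration metadata (taken from
#'   the movie's config when a `sim_movie` is given).
#' @return Invisibly, the sidecar metadata list.
#' @export
write_stack <- function(stack, path, voxel_xy = NULL, voxel_z = NULL,
                        frame_interval = NULL) {
  if (inherits(stack, "sim_movie")) {
    cfg <- stack$config
    voxel_xy <- cfg$voxel_xy; voxel_z <- cfg$voxel_z
    frame_interval <- cfg$frame_interval
    stack <- stack$stack
  }
  if (length(dim(stack)) != 5L) {
    stop("'stack' must be a 5D array t x c x z x y x x", call. = FALSE)
  }
  if (is.null(voxel_xy) || is.null(voxel_z) || is.null(frame_interval)) {
    stop("voxel sizes and frame interval are required metadata", call. = FALSE)
  }
  d <- dim(stack)
  lo <- min(stack); hi <- max(stack)
  scale <- max(hi - lo, 1e-12)
  pages <- vector("list", d[1] * d[2] * d[3])
  p <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    pages[[p]] <- (matrix(stack[t, ch, z, , ], d[4], d[5]) - lo) / scale
    p <- p + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(axes = "tczyx", n_frames = d[1], n_channels = d[2],
               nz = d[3], ny = d[4], nx = d[5],
               voxel_xy_um = voxel_xy, voxel_z_um = voxel_z,
               frame_interval_s = frame_interval,
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(meta)
}

#' Read a movie stack written by [write_stack()]
#'
#' Restores the calibrated `t x c x z x y x x` array from the TIFF and its
#' JSON sidecar. Without a sidecar the axis sizes and calibration must be
#' supplied explicitly; silent defaults are never assumed.
#'
#' @param path TIFF path.
#' @param meta Optional metadata list overriding/replacing the sidecar
#'   (same fields as the sidecar; all of `n_frames`, `n_channels`, `nz`,
#'   `voxel_xy_um`, `voxel_z_um`, `frame_interval_s` are required).
#' @return List with `stack`, `voxel_xy`, `voxel_z`, `frame_interval`.
#' @export
read_stack <- function(path, meta = NULL) {
  sidecar <- paste0(path, ".json")
  if (is.null(meta)) {
    if (!file.exists(sidecar)) {
      stop("no JSON sidecar found and no metadata supplied: axis sizes and ",
           "calibration (voxel sizes, frame interval) are required",
           call. = FALSE)
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  need <- c("n_frames", "n_channels", "nz", "voxel_xy_um", "voxel_z_um",
            "frame_interval_s")
  if (!all(need %in% names(meta))) {
    stop("metadata must provide: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nt <- meta$n_frames; nc <- meta$n_channels; nz <- meta$nz
  if (length(pages) != nt * nc * nz) {
    stop(sprintf("TIFF has %d pages; metadata implies %d",
                 length(pages), nt * nc * nz), call. = FALSE)
  }
  off <- if (is.null(meta$intensity_offset)) 0 else meta$intensity_offset
  sc <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  stack <- array(0, dim = c(nt, nc, nz, ny, nx))
  p <- 1L
  for (t in seq_len(nt)) for (ch in seq_len(nc)) for (z in seq_len(nz)) {
    stack[t, ch, z, , ] <- pages[[p]] * sc + off
    p <- p + 1L
  }
  list(stack = stack, voxel_xy = meta$voxel_xy_um, voxel_z = meta$voxel_z_um,
       frame_interval = meta$frame_interval_s)
}

#' Write simulator ground truth as CSV files
#'
#' @param truth The `truth` element of a [generate_movie()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cisternae = file.path(dir, "truth_cisternae.csv"),
             centers = file.path(dir, "truth_centers.csv"),
             contacts = file.path(dir, "truth_contacts.csv"),
             eres = file.path(dir, "truth_eres.csv"))
  for (nm in names(paths)) {
    write.csv(truth[[nm]], paths[[nm]], row.names = FALSE)
  }
  invisible(paths)
}

#' Read ground truth written by [write_ground_truth()]
#' @param dir Directory holding the CSV files.
#' @return List of data frames (`cisternae`, `centers`, `contacts`, `eres`).
#' @export
read_ground_truth <- function(dir) {
  out <- list()
  for (nm in c("cisternae", "centers", "contacts", "eres")) {
    d <- read.csv(file.path(dir, paste0("truth_", nm, ".csv")))
    # all-NA numeric columns come back logical; every truth column except
    # the ids is numeric by schema
    for (col in names(d)) {
      if (is.logical(d[[col]])) d[[col]] <- as.numeric(d[[col]])
    }
    out[[nm]] <- d
  }
  out
}
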