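#' Two-channel co-localization phantom with known overlap
#'
#' Renders two channels that share a fraction `rho_target` of their spot
#' positions; the remaining spots are placed independently per channel. As
#' `rho_target` approaches 1 (without noise) the masked Pearson correlation
#' approaches 1; with dense independent spots and `rho_target = 0` it
#' fluctuates around 0.
#'
#' @param config An [acquisition_config()] (only the grid, PSF and noise
#'   fields are used; a single frame is rendered).
#' @param rho_target Fraction of shared spots in `[0, 1]`.
#' @param n_spots Spots per channel (>= 1).
#' @param diameter Spot diameter, um.
#' @param noise Apply the camera noise model (default FALSE: clean phantom).
#' @param seed Integer seed (default: `config$seed`).
#' @return List with `A`, `B` (3D arrays z, y, x), `shared`, `unique_A`,
#'   `unique_B` (matrices of true spot centers, columns z/y/x um).
#' @export
generate_coloc_phantom <- function(config, rho_target, n_spots,
                                   diameter = 0.5, noise = FALSE,
                                   seed = NULL) {
  if (rho_target < 0 || rho_target > 1) {
    stop("'rho_target' must be in [0, 1]", call. = FALSE)
  }
  stopifnot_scalar(n_spots, "n_spots", integer = TRUE)
  if (is.null(seed)) seed <- config$seed
  voxel <- c(config$voxel_z, config$voxel_xy, config$voxel_xy)
  ext <- (c(config$nz, config$ny, config$nx) - 1) * voxel
  sig <- spot_sigmas(diameter, config)
  n_shared <- round(rho_target * n_spots)
  n_unique <- n_spots - n_shared
  # centers are drawn over a margin-extended volume so that the expected
  # intensity is spatially uniform inside the field of view; otherwise the
  # shared edge-clipping profile correlates the two channels
  m <- 3 * max(sig)
  with_seed(seed, {
    draw <- function(n) {
      cbind(runif(n, -m, ext[1] + m), runif(n, -m, ext[2] + m),
            runif(n, -m, ext[3] + m))
    }
    shared <- draw(n_shared)
    ua <- draw(n_unique); ub <- draw(n_unique)
    render <- function(centers) {
      arr <- array(0, dim = c(config$nz, config$ny, config$nx))
      for (i in seq_len(nrow(centers))) {
        arr <- add_gaussian_spot(arr, centers[i, ], sig, 1, voxel)
      }
      arr
    }
    A <- render(rbind(shared, ua))
    B <- render(rbind(shared, ub))
    if (noise) {
      n <- length(A)
      A <- array(rpois(n, A * config$photons_per_unit) + config$camera_offset +
                   rnorm(n, 0, config$read_noise_sd), dim = dim(A))
      B <- array(rpois(n, B * config$photons_per_unit) + config$camera_offset +
                   rnorm(n, 0, config$read_noise_sd), dim = dim(B))
    }
    list(A = A, B = B, shared = shared, unique_A = ua, unique_B = ub)
  })
}
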