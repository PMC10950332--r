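# Small acquisition config used across tests
tiny_config <- function(...) {
  args <- list(nx = 24, ny = 24, nz = 11, n_frames = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(acquisition_config, args)
}

# Independent brute-force Costes oracle: OLS line from moment formulas,
# exhaustive downward scan over all distinct values of A, plain cor().
costes_oracle <- function(A, B, below = "and") {
  a <- as.numeric(A); b <- as.numeric(B)
  slope <- cov(a, b) / var(a)
  intercept <- mean(b) - slope * mean(a)
  if (slope <= 0) {
    return(list(threshold_A = NA_real_, threshold_B = NA_real_,
                r_below = NA_real_, slope = slope, intercept = intercept,
                flag = "no-positive-correlation-threshold"))
  }
  lev <- sort(unique(a), decreasing = TRUE)
  t_stop <- lev[length(lev)]; r_stop <- NA_real_
  for (ta in lev) {
    tb <- slope * ta + intercept
    sel <- if (below == "and") (a <= ta & b <= tb) else (a <= ta | b <= tb)
    if (sum(sel) < 2) next
    if (sd(a[sel]) == 0 || sd(b[sel]) == 0) next
    r <- cor(a[sel], b[sel])
    t_stop <- ta; r_stop <- r
    if (r <= 0) break
  }
  list(threshold_A = t_stop, threshold_B = slope * t_stop + intercept,
       r_below = r_stop, slope = slope, intercept = intercept, flag = "ok")
}

# Render one noiseless spot in a small volume; returns list(frame, center)
render_single_spot <- function(config, center = NULL, diameter = 0.5,
                               amplitude = 1) {
  voxel <- c(config$voxel_z, config$voxel_xy, config$voxel_xy)
  ext <- (c(config$nz, config$ny, config$nx) - 1) * voxel
  if (is.null(center)) center <- ext / 2
  frame <- golgitrace:::add_gaussian_spot(
    array(0, dim = c(config$nz, config$ny, config$nx)), center,
    golgitrace:::spot_sigmas(diameter, config), amplitude, voxel)
  list(frame = frame, center = center)
}
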