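test_that("an empty scene renders pure camera background", {
  cfg <- tiny_config(n_frames = 2L, seed = 11L)
  mv <- generate_movie(cfg, list(cisternae = list(), eres = list()))
  expect_equal(dim(mv$stack), c(2L, 1L, 11L, 24L, 24L))
  expect_equal(mean(mv$stack), cfg$camera_offset, tolerance = 0.01)
  expect_equal(sd(mv$stack), cfg$read_noise_sd, tolerance = 0.05)
  expect_equal(nrow(mv$truth$cisternae), 0L)
})

test_that("a noiseless static cisterna peaks at its true center", {
  cfg <- tiny_config(n_frames = 1L)
  voxel <- c(cfg$voxel_z, cfg$voxel_xy, cfg$voxel_xy)
  center <- c(1.03, 1.17, 1.12)
  traj <- matrix(center, 1, 3)
  ci <- sim_cisterna(1L, traj, list(marker_kinetics(0, 10, 10)))
  mv <- generate_movie(cfg, list(cisternae = list(ci), eres = list()),
                       noise = FALSE)
  frame <- mv$stack[1, 1, , , ]
  idx <- which(frame == max(frame), arr.ind = TRUE)[1, ]
  found <- (idx - 1) * voxel
  expect_true(all(abs(found - center) <= voxel))
})

test_that("identical config and seed give bit-identical movies", {
  scene <- sim_maturation_scene(2L, 10, 5, seed = 7L)
  cfg <- scene$config; cfg$seed <- 7L
  m1 <- generate_movie(cfg, scene)
  m2 <- generate_movie(cfg, scene)
  expect_identical(m1$stack, m2$stack)
  expect_identical(m1$truth, m2$truth)
  # and the scene builder itself is seed-deterministic
  scene2 <- sim_maturation_scene(2L, 10, 5, seed = 7L)
  expect_identical(scene$cisternae[[1]]$trajectory,
                   scene2$cisternae[[1]]$trajectory)
})

test_that("ground-truth delay equals the programmed kinetic peak difference", {
  scene <- sim_maturation_scene(8L, 31, 24.1, seed = 3L)
  truth <- generate_movie(scene$config, scene, noise = FALSE)$truth$cisternae
  peaks <- t(vapply(scene$cisternae, function(ci)
    c(ci$kinetics[[1]]$peak_time, ci$kinetics[[2]]$peak_time), numeric(2)))
  expect_identical(truth$delta_true_s, peaks[, 2] - peaks[, 1])
})

test_that("doubling the amplitude doubles the rendered spot integral", {
  cfg <- tiny_config()
  s1 <- render_single_spot(cfg, amplitude = 1)
  s2 <- render_single_spot(cfg, amplitude = 2)
  expect_equal(sum(s2$frame), 2 * sum(s1$frame))
})

test_that("a cisterna leaving the field of view is reported by id", {
  cfg <- tiny_config()
  traj <- matrix(c(0.05, 0.5, 0.5), 1, 3)  # z too close to the boundary
  ci <- sim_cisterna(7L, traj, list(marker_kinetics(0)))
  expect_error(generate_movie(cfg, list(cisternae = list(ci))),
               "cisterna 7")
})

test_that("coloc phantom hits both correlation extremes", {
  cfg <- acquisition_config(nx = 20, ny = 20, nz = 10, voxel_z = 0.25,
                            n_frames = 1L)
  ph <- generate_coloc_phantom(cfg, 1, 40, seed = 2)
  expect_equal(pearson_r(ph$A, ph$B), 1)
  r0 <- vapply(1:10, function(s)
    pearson_r2 <- with(generate_coloc_phantom(cfg, 0, 200, seed = s),
                       pearson_r(A, B)), 0)
  expect_lt(abs(mean(r0)), 0.1)
  r5 <- mean(vapply(1:10, function(s)
    with(generate_coloc_phantom(cfg, 0.5, 200, seed = s),
         pearson_r(A, B)), 0))
  expect_gt(r5, mean(r0))
  expect_lt(r5, 1)
  expect_error(generate_coloc_phantom(cfg, 1.2, 10), "rho_target")
  expect_error(generate_coloc_phantom(cfg, 0.5, 0), "n_spots")
})

test_that("noiseless localization is better than a quarter voxel", {
  cfg <- tiny_config()
  voxel <- c(cfg$voxel_z, cfg$voxel_xy, cfg$voxel_xy)
  for (s in 1:5) {
    ctr <- c(1.0, 1.1, 1.2) + (s / 10) * voxel
    sp <- render_single_spot(cfg, center = ctr, amplitude = 200)
    det <- detect_spots(sp$frame, cfg$voxel_xy, cfg$voxel_z,
                        threshold_type = "absolute", threshold = 1)
    expect_equal(nrow(det), 1L)
    err_vox <- abs(c(det$z_um, det$y_um, det$x_um) - ctr) / voxel
    expect_true(all(err_vox < 0.25))
  }
})
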