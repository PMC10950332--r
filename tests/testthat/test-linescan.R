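test_that("profiles reproduce ramps and constants", {
  img <- outer(rep(1, 21), 0:20)  # I(y, x) = x index
  pr <- profile_along_line(img, c(1.0, 0.2), c(1.0, 1.8), voxel_xy = 0.1,
                           normalize = FALSE)
  expect_equal(pr$position_um[1], 0)
  fit <- lm(pr$intensity[, 1] ~ pr$position_um)
  expect_equal(unname(coef(fit)[2]), 10, tolerance = 1e-6)  # 1 index per 0.1 um
  const <- profile_along_line(matrix(4, 15, 15), c(0.5, 0.2), c(0.5, 1.2),
                              voxel_xy = 0.1)
  expect_true(all(const$profile == 1))
  expect_error(profile_along_line(img, c(1, 1), c(1, 1)), "zero-length")
  expect_error(profile_along_line(img, c(1, -1), c(1, 1), voxel_xy = 0.1),
               "inside")
})

test_that("segregation metrics separate offset zones and respect symmetry", {
  x <- seq(0, 3, by = 0.05)
  g <- exp(-(x - 1)^2 / 0.02); r <- exp(-(x - 2)^2 / 0.02)
  prof <- structure(list(position_um = x, intensity = cbind(g, r),
                         profile = cbind(g, r)), class = "line_profile")
  m <- segregation_metrics(prof)
  expect_equal(unname(m["peak_offset_um"]), 1, tolerance = 0.01)
  expect_equal(unname(m["centroid_offset_um"]), 1, tolerance = 0.01)
  ident <- structure(list(position_um = x, intensity = cbind(g, g),
                          profile = cbind(g, g)), class = "line_profile")
  expect_equal(unname(segregation_metrics(ident)), c(0, 0))
  # reversing the segment leaves the metrics unchanged
  rev_prof <- structure(list(position_um = x,
                             intensity = cbind(rev(g), rev(r)),
                             profile = cbind(rev(g), rev(r))),
                        class = "line_profile")
  expect_equal(segregation_metrics(rev_prof), m, tolerance = 1e-9)
  # positive rescaling invariance
  sc <- structure(list(position_um = x, intensity = cbind(5 * g, 0.2 * r),
                       profile = cbind(g, r)), class = "line_profile")
  expect_equal(segregation_metrics(sc), m)
  flat <- structure(list(position_um = x, intensity = cbind(g, rep(1, length(x))),
                         profile = cbind(g, rep(1, length(x)))),
                    class = "line_profile")
  expect_error(segregation_metrics(flat), "flat")
})

test_that("rendered sub-zone offsets are recovered from line scans", {
  scene <- sim_maturation_scene(1L, 0, 0.001, zone_separation = 0.3, seed = 2L)
  cfg <- scene$config
  mv <- generate_movie(cfg, scene, noise = FALSE)
  ci <- scene$cisternae[[1]]
  f <- round(ci$kinetics[[1]]$peak_time / cfg$frame_interval) + 1
  pos <- ci$trajectory[f, ]
  zi <- round(pos[1] / cfg$voxel_z) + 1
  planes <- list(extract_plane(mv$stack, f, 1, zi),
                 extract_plane(mv$stack, f, 2, zi))
  pr <- profile_along_line(planes, c(pos[2], pos[3] - 0.6),
                           c(pos[2], pos[3] + 0.6), voxel_xy = cfg$voxel_xy)
  m <- segregation_metrics(pr)
  expect_equal(unname(m["peak_offset_um"]), 0.3, tolerance = 0.1)
  # overlapping zones score strictly lower than segregated ones
  scene0 <- sim_maturation_scene(1L, 0, 0.001, zone_separation = 0, seed = 2L)
  mv0 <- generate_movie(scene0$config, scene0, noise = FALSE)
  planes0 <- list(extract_plane(mv0$stack, f, 1, zi),
                  extract_plane(mv0$stack, f, 2, zi))
  pr0 <- profile_along_line(planes0, c(pos[2], pos[3] - 0.6),
                            c(pos[2], pos[3] + 0.6), voxel_xy = cfg$voxel_xy)
  m0 <- segregation_metrics(pr0)
  expect_lt(m0["peak_offset_um"], m["peak_offset_um"])
  expect_lt(m0["centroid_offset_um"], m["centroid_offset_um"])
})
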