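test_that("a slowly moving spot forms a single full-length track", {
  spots <- data.frame(frame = 1:20, z_um = 1 + 0.01 * (1:20),
                      y_um = 2, x_um = 2 + 0.05 * (1:20))
  tr <- link_tracks(spots)
  expect_equal(length(unique(tr$track)), 1L)
  expect_equal(sort(tr$frame), 1:20)
})

test_that("well-separated stationary spots keep distinct identities", {
  spots <- do.call(rbind, lapply(1:15, function(f) {
    data.frame(frame = f, z_um = c(1, 1), y_um = c(1, 3), x_um = c(1, 3))
  }))
  tr <- link_tracks(spots)
  expect_equal(length(unique(tr$track)), 2L)
  # zero identity switches: each track stays at one position
  for (tid in unique(tr$track)) {
    s <- tr[tr$track == tid, ]
    expect_equal(length(unique(s$y_um)), 1L)
  }
})

test_that("linking never reuses a frame within a track and handles empties", {
  empty <- link_tracks(data.frame(frame = integer(), z_um = numeric(),
                                  y_um = numeric(), x_um = numeric()))
  expect_equal(nrow(empty), 0L)
  scene <- sim_maturation_scene(4L, 15, 10, seed = 9L)
  cfg <- scene$config; cfg$seed <- 9L
  mv <- generate_movie(cfg, scene)
  res <- analyze_movie(mv)
  per <- split(res$tracks$frame, res$tracks$track)
  expect_true(all(vapply(per, anyDuplicated, 0L) == 0L))
})

test_that("gap closing bridges a missed frame into one track", {
  spots <- data.frame(frame = c(1:5, 8:12), z_um = 1, y_um = 1, x_um = 1)
  tr <- link_tracks(spots, max_gap = 2L)
  expect_equal(length(unique(tr$track)), 1L)
  tr2 <- link_tracks(spots, max_gap = 1L)
  expect_equal(length(unique(tr2$track)), 2L)
})

test_that("a noiseless cisterna track matches the true trajectory", {
  scene <- sim_maturation_scene(1L, 20, 0.001, seed = 4L)
  cfg <- scene$config
  mv <- generate_movie(cfg, scene, noise = FALSE)
  nt <- dim(mv$stack)[1]
  spots <- do.call(rbind, lapply(seq_len(nt), function(t) {
    fr <- mv$stack[t, 1, , , ] + mv$stack[t, 2, , , ]
    sp <- detect_spots(fr, cfg$voxel_xy, cfg$voxel_z,
                       threshold_type = "absolute", threshold = 0.05)
    if (nrow(sp)) sp$frame <- t
    sp
  }))
  tr <- link_tracks(spots)
  expect_equal(length(unique(tr$track)), 1L)
  truth <- mv$truth$centers
  m <- merge(tr, truth, by = "frame")
  rmse <- sqrt(mean((m$z_um.x - m$z_um.y)^2 + (m$y_um.x - m$y_um.y)^2 +
                      (m$x_um.x - m$x_um.y)^2))
  expect_lt(rmse, 0.5 * cfg$voxel_xy)
})

test_that("contact events follow the run-length and duration conventions", {
  # distance below threshold on frames 5-7 at 1.1 s sampling
  frames <- 1:12
  x <- rep(2, 12); x[5:7] <- 0.2
  tracks <- structure(data.frame(frame = frames, z_um = 1, y_um = 1,
                                 x_um = x, track = 1L),
                      class = c("track_table", "data.frame"))
  eres <- data.frame(eres = 1L, z_um = 1, y_um = 1, x_um = 0)
  ev <- detect_contacts(tracks, eres, frame_interval = 1.1,
                        contact_distance = 0.35, min_frames = 2L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 2.2)
  expect_equal(ev$start_frame, 5L)
  # never below threshold -> no events; missing frame interval -> error
  far <- tracks; far$x_um <- 2
  expect_equal(nrow(detect_contacts(far, eres, frame_interval = 1.1)), 0L)
  expect_error(detect_contacts(tracks, eres), "frame_interval")
  # single-frame dips are ignored at min_frames = 2
  dip <- tracks; dip$x_um <- 2; dip$x_um[6] <- 0.2
  expect_equal(nrow(detect_contacts(dip, eres, frame_interval = 1.1,
                                    min_frames = 2L)), 0L)
})
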