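test_that("a stationary, noise-free scene renders identical frames", {
  cfg <- video_sim_config(
    n_frames = 5, axial_velocity_mm_s = 0, noise_sd = 0,
    jitter_sd_px = 0, blur_sigma_px = 0, seed = 1
  )
  sim <- render_vessel_video(cfg)
  f1 <- sim$stack$frames[, , 1]
  for (t in 2:5) expect_equal(sim$stack$frames[, , t], f1)
})

test_that("the ground-truth mask has the configured width (pixel counting)", {
  # D = 20 um at 2 um/px -> 10 px wide; straight horizontal vessel
  cfg <- video_sim_config(
    image_height_px = 60, image_width_px = 120, n_frames = 2,
    um_per_px = 2, vessel_diameter_um = 20,
    centerline_waypoints = cbind(x = c(10, 110), y = c(30, 30)),
    noise_sd = 0, jitter_sd_px = 0, blur_sigma_px = 0, seed = 1
  )
  sim <- render_vessel_video(cfg)
  widths <- colSums(sim$truth$mask)[20:100] # clear of the rounded ends
  expect_true(all(abs(widths - 10) <= 1))
})

test_that("plugs advect at the configured velocity (minimum tracking)", {
  # Va = 0.50 mm/s at 60 fps, 1 um/px -> 8.33 px/frame
  cfg <- video_sim_config(
    image_height_px = 60, image_width_px = 220, n_frames = 6,
    um_per_px = 1, fps = 60, axial_velocity_mm_s = 0.5,
    vessel_diameter_um = 16,
    centerline_waypoints = cbind(x = c(12, 208), y = c(30, 30)),
    plug_spacing_um = 100, plug_length_um = 14,
    noise_sd = 0, jitter_sd_px = 0, blur_sigma_px = 0, seed = 1
  )
  sim <- render_vessel_video(cfg)
  # follow one plug: argmin within a +/- 15 px window of its last position
  pos <- numeric(6)
  pos[1] <- 59 + which.min(sim$stack$frames[30, 60:160, 1])
  for (t in 2:6) {
    lo <- pos[t - 1] - 2; hi <- pos[t - 1] + 15
    pos[t] <- lo - 1 + which.min(sim$stack$frames[30, lo:hi, t])
  }
  steps <- diff(pos)
  # integer pixel minima alternate 8/9 around the true 8.33; the tracked
  # mean displacement resolves it
  expect_lte(abs(mean(steps) - 8.33), 0.5)
  expect_true(all(abs(steps - 8.33) <= 1))
})

test_that("identical configs render bit-identical stacks and truths", {
  a <- render_vessel_video(video_sim_config(n_frames = 4, seed = 42))
  b <- render_vessel_video(video_sim_config(n_frames = 4, seed = 42))
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$per_frame_shift_px, b$truth$per_frame_shift_px)
})

test_that("rendering rejects out-of-bounds vessels and too-short videos", {
  expect_error(
    video_sim_config(centerline_waypoints = cbind(x = c(1, 50), y = c(2, 2))),
    "outside"
  )
  cfg <- video_sim_config(seed = 1)
  cfg$n_frames <- 1L
  expect_error(render_vessel_video(cfg), "n_frames")
})

test_that("ground-truth shifts exactly describe the applied jitter", {
  # re-render jitter-free, shift by the recorded truth, compare
  base_cfg <- video_sim_config(
    n_frames = 6, noise_sd = 0, blur_sigma_px = 0,
    jitter_sd_px = 2, seed = 5
  )
  sim <- render_vessel_video(base_cfg)
  still_cfg <- base_cfg
  still_cfg$jitter_sd_px <- 0
  still <- render_vessel_video(still_cfg)
  for (t in c(1, 3, 6)) {
    sh <- sim$truth$per_frame_shift_px[t, ]
    expected <- ocuflow:::shift_frame(
      still$stack$frames[, , t], sh[["dy"]], sh[["dx"]], fill = 0.85
    )
    expect_equal(sim$stack$frames[, , t], expected, tolerance = 1e-12)
  }
})

test_that("video TIFF + truth JSON round-trip preserves the stack", {
  sim <- render_vessel_video(video_sim_config(n_frames = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_simulated_video(sim, path)
  back <- read_frame_stack(path, fps = 60, um_per_px = 1.5)
  expect_equal(dim(back$frames), dim(sim$stack$frames))
  rng <- range(sim$stack$frames)
  rescaled <- (sim$stack$frames - rng[1]) / diff(rng)
  expect_lt(max(abs(back$frames - rescaled)), 2e-4) # 16-bit quantisation
  truth <- jsonlite::read_json(paste0(path, ".truth.json"), simplifyVector = TRUE)
  expect_equal(truth$axial_velocity_mm_s, 0.5)
  expect_equal(nrow(truth$per_frame_shift_px), 3)
})
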