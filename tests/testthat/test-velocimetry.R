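test_that("the STI has the definitional shape and a stationary scene is static", {
  sim <- render_vessel_video(video_sim_config(
    n_frames = 12, axial_velocity_mm_s = 0, noise_sd = 0,
    jitter_sd_px = 0, blur_sigma_px = 0, seed = 2
  ))
  cl <- sim$truth$centerline_px
  sti <- build_sti(sim$stack, cbind(x = cl[, 1], y = cl[, 2]))
  expect_identical(nrow(sti$values), 12L)
  expect_gte(ncol(sti$values), 8L)
  expect_lt(max(apply(sti$values, 2, var)), 1e-20) # columns constant in time
})

test_that("STI streak slope matches the true velocity (minimum tracking)", {
  sim <- render_vessel_video(video_sim_config(
    n_frames = 20, axial_velocity_mm_s = 0.5, noise_sd = 0,
    jitter_sd_px = 0, blur_sigma_px = 0,
    plug_spacing_um = 120, seed = 4
  ))
  cl <- sim$truth$centerline_px
  sti <- build_sti(sim$stack, cbind(x = cl[, 1], y = cl[, 2]))
  # brute-force local minimum tracking: follow one plug from frame to
  # frame within a +/- 15-sample window, then take the least-squares
  # slope (beats the integer quantisation of single-step differences)
  L <- ncol(sti$values)
  pos <- numeric(12)
  pos[1] <- which.min(sti$values[1, seq_len(floor(L / 2))])
  for (t in 2:12) {
    lo <- max(1, round(pos[t - 1]) - 2)
    hi <- min(L, round(pos[t - 1]) + 15)
    pos[t] <- lo - 1 + which.min(sti$values[t, lo:hi])
  }
  slope_px_per_frame <- unname(stats::coef(stats::lm(pos ~ seq_along(pos)))[2])
  slope_um_per_s <- slope_px_per_frame * sti$ds_um / sti$dt_s
  expect_lt(abs(slope_um_per_s - 500) / 500, 0.05)
})

test_that("a centerline leaving the frame is rejected", {
  sim <- render_vessel_video(video_sim_config(n_frames = 4, seed = 1))
  bad <- cbind(x = c(-5, 50), y = c(10, 10))
  expect_error(build_sti(sim$stack, bad), "bounds")
})

test_that("CWT velocimetry recovers a constructed 0.50 mm/s streak", {
  # Gaussian dark blob translating 8.33 um/frame at 60 fps
  st <- translating_blob_stack(v_px = 8.33, Tn = 18, W = 220, fps = 60)
  line <- cbind(x = 1:220, y = rep(20, 220))
  sti <- build_sti(st, line)
  est <- estimate_axial_velocity_cwt(sti)
  expect_identical(est$status, "ok")
  expect_lt(abs(est$va_mm_s - 0.5) / 0.5, 0.05)
})

test_that("a stationary pattern yields zero velocity, noise is indeterminate", {
  st <- translating_blob_stack(v_px = 0, Tn = 12)
  sti <- build_sti(st, cbind(x = 1:120, y = rep(20, 120)))
  est <- estimate_axial_velocity_cwt(sti)
  expect_identical(est$status, "ok")
  expect_identical(est$va_mm_s, 0)
  set.seed(5)
  noise <- structure(
    list(values = matrix(rnorm(40 * 120), 40, 120), ds_um = 1, dt_s = 1 / 60),
    class = "sti"
  )
  expect_identical(estimate_axial_velocity_cwt(noise)$status, "indeterminate")
})

test_that("the integer-lag oracle is exact on a constructed integer slope", {
  # pattern translating 3 px/frame, ds = 1 um, 60 fps -> 0.18 mm/s exactly
  set.seed(8)
  base <- stats::filter(rnorm(300), rep(1 / 5, 5), circular = TRUE)
  V <- t(vapply(0:19, function(t) {
    as.numeric(base[((seq_len(120) + 3 * t - 1) %% 300) + 1])
  }, numeric(120)))
  sti <- structure(list(values = V, ds_um = 1, dt_s = 1 / 60), class = "sti")
  expect_equal(axial_velocity_oracle(sti), 0.18, tolerance = 1e-12)
  flat <- structure(list(values = matrix(1, 10, 60), ds_um = 1, dt_s = 1 / 60),
                    class = "sti")
  expect_identical(axial_velocity_oracle(flat), 0)
})

test_that("CWT agrees with the cross-correlation oracle across velocities", {
  for (va in c(0.3, 0.5, 0.7)) {
    sim <- render_vessel_video(video_sim_config(
      axial_velocity_mm_s = va, n_frames = 40, seed = round(100 * va)
    ))
    reg <- register_frames(sim$stack)
    cl <- sim$truth$centerline_px
    sti <- build_sti(reg$registered, cbind(x = cl[, 1], y = cl[, 2]),
                     ds_um = 0.75)
    cwt <- estimate_axial_velocity_cwt(sti)
    # lag search capped below half the plug-train period so the
    # correlation cannot lock onto the neighbouring aggregate
    orc <- axial_velocity_oracle(sti, max_lag = 30)
    expect_identical(cwt$status, "ok")
    expect_lt(abs(cwt$va_mm_s - orc) / orc, 0.10)
  }
})

test_that("the velocity estimate is invariant to affine intensity rescaling", {
  sim <- render_vessel_video(video_sim_config(n_frames = 20, seed = 17))
  cl <- sim$truth$centerline_px
  sti1 <- build_sti(sim$stack, cbind(x = cl[, 1], y = cl[, 2]))
  rescaled <- sim$stack
  rescaled$frames <- 3.7 * rescaled$frames + 0.4
  sti2 <- build_sti(rescaled, cbind(x = cl[, 1], y = cl[, 2]))
  v1 <- estimate_axial_velocity_cwt(sti1)$va_mm_s
  v2 <- estimate_axial_velocity_cwt(sti2)$va_mm_s
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("haemodynamic formulas give the hand-computed values", {
  # Vs = 0.35 mm/s, D = 20 um: Q = 350*pi*400/4 / 1000 pl/s, WSR = 8*350/20
  expect_equal(blood_flow(0.35, 20), 109.9557, tolerance = 1e-4)
  expect_equal(wall_shear_rate(0.35, 20), 140)
  expect_identical(blood_flow(0, 15), 0)
  expect_identical(wall_shear_rate(0, 15), 0)
  # scaling laws
  expect_equal(blood_flow(0.4, 30) / blood_flow(0.4, 15), 4)
  expect_equal(wall_shear_rate(0.4, 10) / wall_shear_rate(0.4, 20), 2)
  expect_error(blood_flow(0.3, 0), "d must be > 0")
  expect_error(wall_shear_rate(-0.1, 10), "vs must be >= 0")
})

test_that("axial-to-cross conversion matches the paired velocity summaries", {
  cfg <- velocimetry_config(k_axial_to_cross = 1.42)
  expect_equal(cross_sectional_velocity(0.54, cfg), 0.380, tolerance = 5e-3)
  expect_equal(cross_sectional_velocity(0.50, cfg), 0.352, tolerance = 5e-3)
  expect_identical(cross_sectional_velocity(0, cfg), 0)
  expect_error(velocimetry_config(k_axial_to_cross = 0.9), ">= 1")
})

test_that("emitted haemodynamics satisfy their defining identities exactly", {
  h <- segment_haemodynamics(diameter_um = 24.2, va_mm_s = 0.61)
  expect_equal(h$q_pl_s, h$vs_mm_s * 1000 * pi * h$d_um^2 / 4 / 1000)
  expect_equal(h$wsr_per_s, 8 * h$vs_mm_s * 1000 / h$d_um)
  expect_lte(h$vs_mm_s, h$va_mm_s)
})
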