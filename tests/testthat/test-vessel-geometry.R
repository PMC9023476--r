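test_that("a constant frame yields an empty mask, not an error", {
  m <- segment_vessels(matrix(0.7, 50, 50), um_per_px = 1)
  expect_false(any(m$mask))
  expect_identical(nrow(extract_centerlines(m)), 0L)
})

test_that("segmentation overlaps the ground-truth mask (Dice)", {
  # noiseless: Dice >= 0.90; 10%-of-contrast noise: Dice >= 0.80
  cfg0 <- video_sim_config(n_frames = 10, noise_sd = 0, jitter_sd_px = 0,
                           blur_sigma_px = 0, seed = 3)
  sim0 <- render_vessel_video(cfg0)
  mean0 <- apply(sim0$stack$frames, c(1, 2), mean)
  m0 <- segment_vessels(mean0, um_per_px = cfg0$um_per_px)
  expect_gte(dice_coefficient(m0$mask, sim0$truth$mask), 0.90)

  cfgn <- video_sim_config(n_frames = 10, jitter_sd_px = 0, seed = 3)
  cfgn$noise_sd <- 0.10 * cfgn$vessel_contrast
  simn <- render_vessel_video(cfgn)
  meann <- apply(simn$stack$frames, c(1, 2), mean)
  mn <- segment_vessels(meann, um_per_px = cfgn$um_per_px)
  expect_gte(dice_coefficient(mn$mask, simn$truth$mask), 0.80)
})

test_that("a straight band yields one centerline on the analytic midline", {
  mask <- band_mask(40, 80, y0 = 20, width_px = 9)
  cl <- extract_centerlines(mask, um_per_px = 1)
  expect_identical(length(unique(cl$segment_id)), 1L)
  expect_lte(max(abs(cl$y - 20)), 1)
})

test_that("disjoint bands produce separate segments; specks are pruned", {
  mask <- band_mask(60, 80, y0 = 15, width_px = 7) |
    band_mask(60, 80, y0 = 45, width_px = 7)
  cl <- extract_centerlines(mask, um_per_px = 1)
  expect_identical(length(unique(cl$segment_id)), 2L)
  speck <- matrix(FALSE, 30, 30); speck[15, 15] <- TRUE
  expect_identical(nrow(extract_centerlines(speck, um_per_px = 1)), 0L)
})

test_that("EDT diameters match expectations on analytic shapes", {
  # 9 px band at 1 um/px -> 9 um within the 1 px discretisation band
  mask <- band_mask(40, 80, y0 = 20, width_px = 9)
  cl <- edt_diameter(mask, extract_centerlines(mask, um_per_px = 1))
  inner <- cl[cl$x > 10 & cl$x < 70, ]
  expect_lte(abs(mean(inner$diameter_um) - 9), 1)
  # disc of radius 10: centre diameter 2r within 1 px either side
  disc <- matrix(FALSE, 41, 41)
  for (i in 1:41) for (j in 1:41) {
    disc[i, j] <- sqrt((i - 21)^2 + (j - 21)^2) <= 10
  }
  centre <- tibble::tibble(segment_id = 1L, point_index = 1L,
                           x = 21, y = 21, s_um = 0)
  attr(centre, "um_per_px") <- 1
  d <- edt_diameter(disc, centre)$diameter_um
  expect_lte(abs(d - 20), 2)
})

test_that("EDT equals the brute-force nearest-background oracle exactly", {
  set.seed(71)
  for (rep in 1:25) {
    H <- sample(12:40, 1); W <- sample(12:40, 1)
    mask <- matrix(runif(H * W) < 0.4, H, W)
    # smooth into blobs so there is real structure
    mask <- ocuflow:::drop_small_objects(mask, 3)
    fg <- which(mask, arr.ind = TRUE)
    if (nrow(fg) == 0) next
    take <- fg[sample(nrow(fg), min(10, nrow(fg))), , drop = FALSE]
    got <- ocuflow:::edt_at_points(mask, take[, 2], take[, 1])
    want <- vapply(seq_len(nrow(take)), function(i) {
      brute_edt(mask, take[i, 2], take[i, 1])
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("points outside the foreground are rejected by name", {
  mask <- band_mask(20, 20, y0 = 10, width_px = 5)
  bad <- tibble::tibble(segment_id = 1L, point_index = 1L,
                        x = 5, y = 1, s_um = 0)
  attr(bad, "um_per_px") <- 1
  expect_error(edt_diameter(mask, bad), "x=5, y=1")
})

test_that("noiseless diameter recovery is within 1 px across the size range", {
  for (d_um in c(10, 16, 22, 30)) {
    cfg <- video_sim_config(
      n_frames = 4, vessel_diameter_um = d_um, noise_sd = 0,
      jitter_sd_px = 0, blur_sigma_px = 0, seed = 30 + d_um
    )
    sim <- render_vessel_video(cfg)
    fr <- apply(sim$stack$frames, c(1, 2), mean)
    m <- segment_vessels(fr, um_per_px = cfg$um_per_px)
    cl <- edt_diameter(m, extract_centerlines(m))
    err_px <- abs(mean(cl$diameter_um) - d_um) / cfg$um_per_px
    expect_lte(err_px, 1)
  }
})

test_that("dilating the mask grows every diameter by at most 2*sqrt(2) px", {
  mask <- band_mask(40, 60, y0 = 20, width_px = 9)
  cl <- extract_centerlines(mask, um_per_px = 1)
  d0 <- edt_diameter(mask, cl)$diameter_um
  grown <- EBImage::dilate(EBImage::Image(mask * 1), EBImage::makeBrush(3, "box"))
  grown <- as.matrix(grown) > 0
  d1 <- edt_diameter(grown, cl)$diameter_um
  expect_true(all(d1 - d0 >= 0))
  expect_true(all(d1 - d0 <= 2 * sqrt(2) + 1e-9))
})
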