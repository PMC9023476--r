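#' Configuration for the synthetic microvessel video generator
#'
#' Describes one simulated slit-lamp acquisition: a single dark vessel of
#' known diameter on a bright scleral background, with dark cell aggregates
#' ("plugs") advecting along the centerline at a known axial velocity, plus
#' frame-to-frame jitter, defocus blur and sensor noise. The rendered stack
#' and its exact ground truth drive the parameter-recovery tests of the
#' registration, geometry and velocimetry stages.
#'
#' Defaults emulate the acquisition geometry the analysis is designed for:
#' 60 frames/s capture of vessels 15-30 um wide with axial velocities around
#' 0.3-0.7 mm/s. The default duration is kept short (80 frames) so a full
#' render-and-recover cycle runs at desk scale.
#'
#' @param image_height_px,image_width_px frame size in pixels.
#' @param n_frames number of frames (>= 2 to render).
#' @param fps frame rate, frames/s.
#' @param um_per_px pixel pitch, um/pixel.
#' @param vessel_diameter_um true vessel diameter D, um.
#' @param axial_velocity_mm_s true axial (centerline) velocity Va, mm/s (>= 0).
#' @param centerline_waypoints two-column matrix of (x, y) pixel coordinates
#'   the vessel passes through, in order. Default: a gentle S-curve across
#'   the field of view.
#' @param plug_length_um full width at half maximum of one advecting dark
#'   aggregate, um.
#' @param plug_spacing_um centre-to-centre spacing of the periodic plug
#'   train, um. Must exceed `plug_length_um`.
#' @param vessel_contrast peak darkening of the vessel relative to the
#'   background, in (0, 1].
#' @param noise_sd Gaussian sensor noise standard deviation (intensity
#'   units; background is 0.85).
#' @param jitter_sd_px standard deviation of the per-frame rigid translation
#'   (pixels). Jitter is integer-rounded unless `subpixel_jitter = TRUE`.
#' @param blur_sigma_px per-frame Gaussian defocus sigma in pixels; a scalar
#'   or a length-`n_frames` vector (to make one frame sharpest).
#' @param subpixel_jitter keep jitter at sub-pixel resolution instead of
#'   rounding to integers.
#' @param seed integer seed; identical configurations render bit-identical
#'   stacks.
#'
#' @return An object of class `video_sim_config`.
#' @export
video_sim_config <- function(image_height_px = 120,
                             image_width_px = 160,
                             n_frames = 80,
                             fps = 60,
                             um_per_px = 1.5,
                             vessel_diameter_um = 22,
                             axial_velocity_mm_s = 0.5,
                             centerline_waypoints = NULL,
                             plug_length_um = 18,
                             plug_spacing_um = 65,
                             vessel_contrast = 0.55,
                             noise_sd = 0.015,
                             jitter_sd_px = 1,
                             blur_sigma_px = 0.6,
                             subpixel_jitter = FALSE,
                             seed = 1L) {
  if (is.null(centerline_waypoints)) {
    # gentle S-curve spanning the width, vertically centred, clear of the
    # borders by the vessel radius plus a safety margin
    margin <- vessel_diameter_um / (2 * um_per_px) + 3
    xs <- seq(margin, image_width_px - margin, length.out = 5)
    ys <- image_height_px / 2 +
      0.12 * image_height_px * sin(seq(0, pi, length.out = 5))
    centerline_waypoints <- cbind(x = xs, y = ys)
  }
  centerline_waypoints <- as.matrix(centerline_waypoints)
  cfg <- structure(
    list(
      image_height_px = as.integer(image_height_px),
      image_width_px = as.integer(image_width_px),
      n_frames = as.integer(n_frames),
      fps = fps, um_per_px = um_per_px,
      vessel_diameter_um = vessel_diameter_um,
      axial_velocity_mm_s = axial_velocity_mm_s,
      centerline_waypoints = centerline_waypoints,
      plug_length_um = plug_length_um,
      plug_spacing_um = plug_spacing_um,
      vessel_contrast = vessel_contrast,
      noise_sd = noise_sd,
      jitter_sd_px = jitter_sd_px,
      blur_sigma_px = blur_sigma_px,
      subpixel_jitter = isTRUE(subpixel_jitter),
      seed = as.integer(seed)
    ),
    class = "video_sim_config"
  )
  validate_video_sim_config(cfg)
  cfg
}

validate_video_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "video_sim_config"))
  if (cfg$fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (cfg$um_per_px <= 0) stop("um_per_px must be > 0", call. = FALSE)
  if (cfg$vessel_diameter_um <= 0) stop("vessel_diameter_um must be > 0", call. = FALSE)
  if (cfg$axial_velocity_mm_s < 0) stop("axial_velocity_mm_s must be >= 0", call. = FALSE)
  if (cfg$vessel_contrast <= 0 || cfg$vessel_contrast > 1) {
    stop("vessel_contrast must be in (0, 1]", call. = FALSE)
  }
  if (cfg$plug_spacing_um <= cfg$plug_length_um) {
    stop("plug_spacing_um must exceed plug_length_um", call. = FALSE)
  }
  r_px <- cfg$vessel_diameter_um / (2 * cfg$um_per_px)
  wp <- cfg$centerline_waypoints
  if (any(wp[, 1] - r_px < 1) || any(wp[, 1] + r_px > cfg$image_width_px) ||
      any(wp[, 2] - r_px < 1) || any(wp[, 2] + r_px > cfg$image_height_px)) {
    stop(sprintf(
      "vessel (radius %.1f px) extends outside the %d x %d px image bounds",
      r_px, cfg$image_height_px, cfg$image_width_px
    ), call. = FALSE)
  }
  invisible(cfg)
}

# evaluate RNG-dependent code under a seed, restoring global RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# interpolate waypoints with a natural cubic spline and resample to equal
# arc-length steps of `step_px`; returns matrix (x, y, s) with s in pixels
resample_centerline <- function(waypoints, step_px = 0.5) {
  x <- waypoints[, 1]; y <- waypoints[, 2]
  if (nrow(waypoints) < 2) stop("need at least 2 waypoints", call. = FALSE)
  chord <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  n_dense <- max(200L, ceiling(4 * max(chord)))
  tt <- seq(0, max(chord), length.out = n_dense)
  if (nrow(waypoints) == 2) {
    xd <- stats::approx(chord, x, xout = tt)$y
    yd <- stats::approx(chord, y, xout = tt)$y
  } else {
    xd <- stats::spline(chord, x, xout = tt, method = "natural")$y
    yd <- stats::spline(chord, y, xout = tt, method = "natural")$y
  }
  s_dense <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2)))
  s_out <- seq(0, max(s_dense), by = step_px)
  cbind(
    x = stats::approx(s_dense, xd, xout = s_out)$y,
    y = stats::approx(s_dense, yd, xout = s_out)$y,
    s = s_out
  )
}

# per-pixel distance to the polyline and arc length of the nearest vertex,
# computed in chunks to bound memory; returns list(dist, s) of H x W matrices
pixel_line_geometry <- function(H, W, poly) {
  px <- rep(seq_len(W), each = H)   # column-major: x = column index
  py <- rep(seq_len(H), times = W)  # y = row index
  best_d2 <- rep(Inf, H * W)
  best_s <- rep(0, H * W)
  idx <- seq_len(nrow(poly))
  for (block in split(idx, ceiling(idx / 128))) {
    d2 <- outer(px, poly[block, 1], `-`)^2 + outer(py, poly[block, 2], `-`)^2
    j <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_along(px), j)]
    upd <- dmin < best_d2
    best_d2[upd] <- dmin[upd]
    best_s[upd] <- poly[block, 3][j[upd]]
  }
  list(
    dist = matrix(sqrt(best_d2), H, W),
    s = matrix(best_s, H, W)
  )
}

#' Render a ground-truthed synthetic microvessel video
#'
#' Draws an anti-aliased dark tube along the spline through the configured
#' waypoints, advects a periodic train of Gaussian dark plugs along it at the
#' true axial velocity (arc-length parameterised, so speed is constant along
#' curves), then applies per-frame rigid jitter, defocus blur and additive
#' Gaussian noise, in that order. The returned ground truth records exactly
#' what was applied, so every downstream estimator can be scored against it.
#'
#' @param config a [video_sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{stack}{the rendered [frame_stack()].}
#'     \item{truth}{a `video_ground_truth` list: `diameter_um`,
#'       `axial_velocity_mm_s`, `per_frame_shift_px` (n_frames x 2 matrix of
#'       (dx, dy)), `centerline_px` (x, y, s at ~1 px spacing), `mask`
#'       (binary H x W vessel image, unjittered scene), and the background
#'       and contrast actually used.}
#'   }
#' @export
render_vessel_video <- function(config) {
  validate_video_sim_config(config)
  if (config$n_frames < 2) {
    stop("n_frames must be >= 2 to render a video", call. = FALSE)
  }
  H <- config$image_height_px; W <- config$image_width_px
  Tn <- config$n_frames
  bg <- 0.85

  poly <- resample_centerline(config$centerline_waypoints, step_px = 0.5)
  geom <- pixel_line_geometry(H, W, poly)
  r_px <- config$vessel_diameter_um / (2 * config$um_per_px)

  # anti-aliased tube: 1 inside, 0 outside, linear ramp over one pixel
  tube <- pmin(1, pmax(0, r_px + 0.5 - geom$dist))
  mask <- geom$dist <= r_px
  inside <- which(tube > 0)
  s_um <- geom$s[inside] * config$um_per_px

  # plug train: periodic Gaussian darkening along arc length
  sigma_um <- config$plug_length_um / 2.355 # FWHM -> sigma
  spacing <- config$plug_spacing_um
  v_um_per_frame <- config$axial_velocity_mm_s * 1000 / config$fps
  plug_profile <- function(offset_um) {
    u <- (s_um - offset_um) %% spacing
    d <- pmin(u, spacing - u) # distance to nearest plug centre
    exp(-0.5 * (d / sigma_um)^2)
  }

  blur <- config$blur_sigma_px
  if (length(blur) == 1L) blur <- rep(blur, Tn)
  if (length(blur) != Tn) {
    stop("blur_sigma_px must be scalar or length n_frames", call. = FALSE)
  }

  frames <- array(0, dim = c(H, W, Tn))
  shifts <- with_seed(config$seed, {
    sh <- matrix(stats::rnorm(2 * Tn, sd = config$jitter_sd_px), ncol = 2)
    if (!config$subpixel_jitter) sh <- round(sh)
    colnames(sh) <- c("dx", "dy")
    noise <- if (config$noise_sd > 0) {
      array(stats::rnorm(H * W * Tn, sd = config$noise_sd), dim = c(H, W, Tn))
    } else NULL
    for (t in seq_len(Tn)) {
      scene <- matrix(bg, H, W)
      plug <- plug_profile((t - 1) * v_um_per_frame)
      depth <- 0.6 + 0.4 * plug # static tube + moving aggregates
      scene[inside] <- bg - config$vessel_contrast * tube[inside] * depth
      fr <- shift_frame(scene, sh[t, "dy"], sh[t, "dx"], fill = bg)
      if (blur[t] > 0) fr <- as.matrix(EBImage::gblur(fr, sigma = blur[t]))
      if (!is.null(noise)) fr <- fr + noise[, , t]
      frames[, , t] <- fr
    }
    sh
  })

  centerline_1px <- poly[seq(1, nrow(poly), by = 2), , drop = FALSE]
  truth <- structure(
    list(
      diameter_um = config$vessel_diameter_um,
      axial_velocity_mm_s = config$axial_velocity_mm_s,
      per_frame_shift_px = shifts,
      centerline_px = centerline_1px,
      mask = mask,
      background = bg,
      vessel_contrast = config$vessel_contrast
    ),
    class = "video_ground_truth"
  )
  list(
    stack = frame_stack(frames, fps = config$fps, um_per_px = config$um_per_px),
    truth = truth
  )
}

#' Write a simulated video and its ground truth to disk
#'
#' The stack goes to a multi-page TIFF and the ground truth (shifts,
#' centerline, diameter, velocity) to a sidecar JSON next to it.
#'
#' @param sim result of [render_vessel_video()].
#' @param path output TIFF path; the JSON is written at `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_simulated_video <- function(sim, path) {
  write_frame_stack(sim$stack, path)
  truth <- sim$truth
  jsonlite::write_json(
    list(
      diameter_um = truth$diameter_um,
      axial_velocity_mm_s = truth$axial_velocity_mm_s,
      per_frame_shift_px = unname(truth$per_frame_shift_px),
      centerline_px = unname(truth$centerline_px[, 1:2]),
      fps = sim$stack$fps,
      um_per_px = sim$stack$um_per_px
    ),
    paste0(path, ".truth.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
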