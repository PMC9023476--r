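#' Build the spatio-temporal image (kymograph) along a centerline
#'
#' Row t of the STI holds frame t's intensities sampled by bilinear
#' interpolation at equal arc-length steps along the centerline; advecting
#' cell aggregates then appear as oblique streaks whose slope (um per s)
#' is the axial velocity. Each row is detrended by subtracting its mean so
#' global illumination drifts cancel.
#'
#' @param stack a registered [frame_stack()].
#' @param centerline tibble with `x`, `y` columns (one segment, ordered),
#'   as produced by [extract_centerlines()], or a two-column matrix.
#' @param ds_um arc-length sampling step; defaults to one pixel pitch.
#' @return An object of class `sti`: list with `values` (T x L matrix),
#'   `ds_um`, `dt_s`.
#' @export
build_sti <- function(stack, centerline, ds_um = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.data.frame(centerline)) {
    centerline <- cbind(centerline$x, centerline$y)
  }
  if (nrow(centerline) < 2) stop("centerline needs >= 2 points", call. = FALSE)
  if (is.null(ds_um)) ds_um <- stack$um_per_px
  step_px <- ds_um / stack$um_per_px
  # resample the polyline at equal arc-length steps
  seg <- sqrt(diff(centerline[, 1])^2 + diff(centerline[, 2])^2)
  s <- c(0, cumsum(seg))
  s_out <- seq(0, max(s), by = step_px)
  if (length(s_out) < 8) stop("centerline too short for an STI (need >= 8 samples)",
                              call. = FALSE)
  xs <- stats::approx(s, centerline[, 1], xout = s_out)$y
  ys <- stats::approx(s, centerline[, 2], xout = s_out)$y
  H <- dim(stack$frames)[1]; W <- dim(stack$frames)[2]
  if (any(xs < 1 | xs > W | ys < 1 | ys > H)) {
    stop("centerline exits the frame bounds", call. = FALSE)
  }
  x0 <- pmin(floor(xs), W - 1); y0 <- pmin(floor(ys), H - 1)
  fx <- xs - x0; fy <- ys - y0
  Tn <- n_frames(stack)
  vals <- matrix(0, Tn, length(s_out))
  for (t in seq_len(Tn)) {
    f <- stack$frames[, , t]
    v <- (1 - fy) * (1 - fx) * f[cbind(y0, x0)] +
      fy * (1 - fx) * f[cbind(y0 + 1, x0)] +
      (1 - fy) * fx * f[cbind(y0, x0 + 1)] +
      fy * fx * f[cbind(y0 + 1, x0 + 1)]
    vals[t, ] <- v - mean(v)
  }
  structure(
    list(values = vals, ds_um = ds_um, dt_s = 1 / stack$fps),
    class = "sti"
  )
}

#' @export
print.sti <- function(x, ...) {
  cat(sprintf(
    "<sti> %d frames x %d samples, ds = %.2f um, dt = %.4f s (%.0f um span)\n",
    nrow(x$values), ncol(x$values), x$ds_um, x$dt_s,
    (ncol(x$values) - 1) * x$ds_um
  ))
  invisible(x)
}

#' Velocimetry configuration
#'
#' @param k_axial_to_cross dimensionless axial-to-cross-sectional velocity
#'   conversion factor (Vs = Va / k), default 1.42 — the ratio implied by
#'   typical paired axial/cross-sectional velocity summaries (0.54/0.38,
#'   0.50/0.35) under a blunted microvascular velocity profile. Must be
#'   >= 1 (the centerline is the fastest streamline).
#' @param wavelet_scales_um spatial scales (um) of the Mexican-hat wavelet
#'   bank; default NULL spans 0.5-2x the expected aggregate length of
#'   18 um.
#' @param min_streak_snr acceptance floor for the streak signal-to-noise
#'   ratio, defined as the working wavelet scale (samples) over the robust
#'   SD (1.4826 x MAD) of the per-interval ridge displacements after jump
#'   rejection. A noise-dominated STI has no stable ridge: its tracked
#'   position wanders by the order of the wavelet scale between frames
#'   and scores near 1; a true streak tracks to a fraction of a sample
#'   and scores far above the default floor of 4. A perfectly stationary
#'   pattern scores Inf.
#' @param max_jump_factor a ridge displacement is discarded when it exceeds
#'   this multiple of the running median displacement (default 3).
#' @return An object of class `velocimetry_config`.
#' @export
velocimetry_config <- function(k_axial_to_cross = 1.42,
                               wavelet_scales_um = NULL,
                               min_streak_snr = 4,
                               max_jump_factor = 3) {
  if (k_axial_to_cross < 1) {
    stop("k_axial_to_cross must be >= 1 (Vs cannot exceed Va)", call. = FALSE)
  }
  if (is.null(wavelet_scales_um)) {
    wavelet_scales_um <- seq(0.5, 2, length.out = 6) * 18
  }
  if (any(wavelet_scales_um <= 0)) stop("scales must be positive", call. = FALSE)
  structure(
    list(
      k_axial_to_cross = k_axial_to_cross,
      wavelet_scales_um = wavelet_scales_um,
      min_streak_snr = min_streak_snr,
      max_jump_factor = max_jump_factor
    ),
    class = "velocimetry_config"
  )
}

# Mexican-hat (second-derivative-of-Gaussian) CWT of one signal at one
# scale (in samples); 'same' convolution with zero padding
mexhat_cwt_row <- function(x, scale_samples) {
  s <- scale_samples
  half <- max(3L, ceiling(4 * s))
  t <- seq(-half, half)
  psi <- (1 - (t / s)^2) * exp(-0.5 * (t / s)^2)
  psi <- psi - mean(psi)
  psi <- psi / sqrt(sum(psi^2))
  n <- length(x)
  xp <- c(numeric(half), x, numeric(half))
  out <- numeric(n)
  # vectorised inner product via filter(): stats::filter handles this
  conv <- stats::filter(xp, rev(psi), method = "convolution", sides = 2)
  out <- conv[(half + 1):(half + n)]
  as.numeric(out)
}

# parabolic refinement of a discrete argmax
refine_peak <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(i)
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (den >= 0) return(i)
  i + max(-0.5, min(0.5, 0.5 * (y[i - 1] - y[i + 1]) / den))
}

#' Estimate axial velocity from an STI by continuous wavelet ridge tracking
#'
#' Each STI row (one time step) is transformed along the spatial axis with
#' a bank of Mexican-hat wavelets — matched to the dark, blob-like cell
#' aggregates — and the ridge (the scale-and-position of maximal modulus)
#' is located with sub-sample parabolic refinement. Ridge positions are
#' associated across consecutive rows (nearest ridge, displacements beyond
#' `max_jump_factor` times the running median rejected as plug-identity
#' switches), and the axial speed is the median per-interval displacement
#' divided by the frame interval. The magnitude is reported; direction is
#' discarded.
#'
#' @param sti an [build_sti()] result.
#' @param config a [velocimetry_config()].
#' @return A list of class `va_estimate`: `va_mm_s` (NA when
#'   indeterminate), `status` ("ok" or "indeterminate"), `snr` (median
#'   per-row ridge SNR), `n_intervals` (displacements used), `ridge_um`
#'   (per-row refined ridge position, um).
#' @export
estimate_axial_velocity_cwt <- function(sti, config = velocimetry_config()) {
  stopifnot(inherits(sti, "sti"))
  V <- sti$values
  Tn <- nrow(V); L <- ncol(V)
  scales <- pmax(config$wavelet_scales_um / sti$ds_um, 1)
  scales <- unique(pmin(scales, L / 4))
  # vessels are dark: aggregates are intensity minima -> use -intensity
  X <- -V
  ridge_pos <- rep(NA_real_, Tn)
  profiles <- vector("list", Tn)
  best_scales <- numeric(Tn)
  for (t in seq_len(Tn)) {
    best_mod <- -Inf; best_prof <- NULL; best_s <- scales[1]
    for (s in scales) {
      w <- mexhat_cwt_row(X[t, ], s)
      m <- max(w)
      if (m > best_mod) {
        best_mod <- m
        best_prof <- w
        best_s <- s
      }
    }
    profiles[[t]] <- best_prof
    best_scales[t] <- best_s
  }
  # candidate ridges per row: strong local maxima of the modulus profile
  candidates <- lapply(profiles, function(w) {
    n <- length(w)
    loc <- which(w > c(-Inf, w[-n]) & w >= c(w[-1], -Inf) & w >= 0.5 * max(w))
    vapply(loc, function(i) refine_peak(w, i), numeric(1))
  })
  # track: start at the global maximum, then associate the nearest
  # candidate in each subsequent row (plug-identity switches show up as
  # spacing-sized jumps and are filtered below)
  ridge_pos[1] <- refine_peak(profiles[[1]], which.max(profiles[[1]]))
  for (t in 2:Tn) {
    cand <- candidates[[t]]
    if (length(cand) == 0) cand <- refine_peak(profiles[[t]], which.max(profiles[[t]]))
    ridge_pos[t] <- cand[which.min(abs(cand - ridge_pos[t - 1]))]
  }
  disp <- diff(ridge_pos)
  med0 <- stats::median(abs(disp))
  if (is.finite(med0) && med0 > 0) {
    # drop plug-identity switches: jumps far beyond the typical displacement
    disp <- disp[abs(disp) <= config$max_jump_factor * pmax(med0, 1)]
  }
  spread <- stats::mad(disp) # robust SD of the track increments
  # coherence relative to the wavelet scale: a noise-dominated profile's
  # ridge wanders by the order of the scale between frames, a true streak
  # tracks to a fraction of a sample
  s_typ <- stats::median(best_scales)
  snr <- if (spread == 0) Inf else s_typ / spread
  indet <- length(disp) < max(4L, floor((Tn - 1) / 4)) ||
    !is.finite(stats::median(disp)) || snr < config$min_streak_snr
  if (indet) {
    return(structure(
      list(va_mm_s = NA_real_, status = "indeterminate",
           snr = snr, n_intervals = length(disp),
           ridge_um = ridge_pos * sti$ds_um),
      class = "va_estimate"
    ))
  }
  va_um_s <- abs(stats::median(disp)) * sti$ds_um / sti$dt_s
  structure(
    list(va_mm_s = va_um_s / 1000, status = "ok",
         snr = snr, n_intervals = length(disp),
         ridge_um = ridge_pos * sti$ds_um),
    class = "va_estimate"
  )
}

#' @export
print.va_estimate <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<va_estimate> Va = %.3f mm/s (SNR %.1f, %d intervals)\n",
                x$va_mm_s, x$snr, x$n_intervals))
  } else {
    cat(sprintf("<va_estimate> indeterminate (SNR %.1f below floor)\n", x$snr))
  }
  invisible(x)
}

#' Brute-force axial velocity oracle (integer-lag cross-correlation)
#'
#' Independent reference estimator used in tests: for each consecutive
#' pair of STI rows the integer lag maximising their normalised
#' cross-correlation is found by exhaustive search, and the speed is the
#' median lag times the sample spacing over the frame interval. No wavelet
#' machinery is shared with [estimate_axial_velocity_cwt()].
#'
#' @param sti an [build_sti()] result.
#' @param max_lag largest |lag| searched (samples); default L/4.
#' @return Axial speed in mm/s (0 for a constant STI).
#' @export
axial_velocity_oracle <- function(sti, max_lag = NULL) {
  stopifnot(inherits(sti, "sti"))
  V <- sti$values
  Tn <- nrow(V); L <- ncol(V)
  if (is.null(max_lag)) max_lag <- floor(L / 4)
  if (L < 2 * max_lag) stop("STI too short for the requested lag range", call. = FALSE)
  lags <- seq(-max_lag, max_lag)
  best <- numeric(Tn - 1)
  for (t in seq_len(Tn - 1)) {
    a <- V[t, ]; b <- V[t + 1, ]
    scores <- vapply(lags, function(l) {
      if (l >= 0) {
        x <- a[seq_len(L - l)]; y <- b[seq_len(L - l) + l]
      } else {
        x <- a[seq_len(L + l) - l]; y <- b[seq_len(L + l)]
      }
      sx <- stats::sd(x); sy <- stats::sd(y)
      if (sx == 0 || sy == 0) return(-Inf)
      stats::cor(x, y)
    }, numeric(1))
    if (all(!is.finite(scores))) best[t] <- 0 else best[t] <- lags[which.max(scores)]
  }
  abs(stats::median(best)) * sti$ds_um / sti$dt_s / 1000
}

#' Convert axial to cross-sectional velocity
#'
#' The cross-sectional (lumen-mean) velocity is the axial (centerline)
#' velocity divided by the profile factor k: Vs = Va / k.
#'
#' @param va axial velocity, mm/s (>= 0).
#' @param config a [velocimetry_config()] (supplies k).
#' @return Vs in mm/s.
#' @export
cross_sectional_velocity <- function(va, config = velocimetry_config()) {
  if (any(va < 0, na.rm = TRUE)) stop("va must be >= 0", call. = FALSE)
  if (config$k_axial_to_cross < 1) stop("k must be >= 1", call. = FALSE)
  va / config$k_axial_to_cross
}

#' Volumetric blood flow from cross-sectional velocity and diameter
#'
#' Q = Vs * pi * D^2 / 4, with Vs converted to um/s internally and the
#' result expressed in picolitres per second (1 pl = 1000 um^3).
#'
#' @param vs cross-sectional velocity, mm/s (>= 0).
#' @param d vessel diameter, um (> 0).
#' @return Flow Q in pl/s.
#' @export
blood_flow <- function(vs, d) {
  if (any(vs < 0, na.rm = TRUE)) stop("vs must be >= 0", call. = FALSE)
  if (any(d <= 0, na.rm = TRUE)) stop("d must be > 0", call. = FALSE)
  (vs * 1000) * pi * d^2 / 4 / 1000
}

#' Wall shear rate from cross-sectional velocity and diameter
#'
#' WSR = 8 * Vs / D, with Vs in um/s and D in um, giving s^-1.
#'
#' @inheritParams blood_flow
#' @return Wall shear rate in 1/s.
#' @export
wall_shear_rate <- function(vs, d) {
  if (any(vs < 0, na.rm = TRUE)) stop("vs must be >= 0", call. = FALSE)
  if (any(d <= 0, na.rm = TRUE)) stop("d must be > 0", call. = FALSE)
  8 * (vs * 1000) / d
}

#' Assemble per-segment haemodynamics
#'
#' Derives the full parameter set for one vessel segment from its diameter
#' and axial velocity: Vs = Va/k, Q = Vs*pi*D^2/4, WSR = 8Vs/D.
#'
#' @param diameter_um segment mean diameter, um.
#' @param va_mm_s axial velocity, mm/s.
#' @param config a [velocimetry_config()].
#' @return One-row tibble: `d_um`, `va_mm_s`, `vs_mm_s`, `q_pl_s`,
#'   `wsr_per_s`.
#' @export
segment_haemodynamics <- function(diameter_um, va_mm_s,
                                  config = velocimetry_config()) {
  vs <- cross_sectional_velocity(va_mm_s, config)
  tibble::tibble(
    d_um = diameter_um,
    va_mm_s = va_mm_s,
    vs_mm_s = vs,
    q_pl_s = blood_flow(vs, diameter_um),
    wsr_per_s = wall_shear_rate(vs, diameter_um)
  )
}
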