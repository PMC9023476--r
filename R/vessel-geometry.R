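#' Segment dark vessels in a grayscale frame
#'
#' Pipeline for dark tubular structure on a bright background: the
#' background is estimated by grey-scale closing with a disc wider than any
#' vessel and subtracted, giving each vessel's intensity dip as a positive
#' ridge response; the response is lightly denoised, the vessel core is
#' located by Otsu thresholding, the lumen edge is set at half the core
#' response level (full width at half maximum), and connected components
#' smaller than `min_object_px` are removed.
#'
#' @param frame H x W numeric matrix, vessels darker than background.
#' @param um_per_px pixel pitch, um/pixel (carried on the mask).
#' @param background_sigma_px radius (px) of the background-closing disc;
#'   must exceed the widest vessel radius.
#' @param smooth_sigma_px sigma of the pre-threshold denoising Gaussian.
#' @param min_object_px connected components smaller than this are dropped.
#' @return An object of class `vessel_mask`: list with `mask` (logical
#'   H x W) and `um_per_px`. A constant frame yields an empty mask.
#' @export
segment_vessels <- function(frame, um_per_px,
                            background_sigma_px = 20,
                            smooth_sigma_px = 1,
                            min_object_px = 50) {
  stopifnot(is.matrix(frame), um_per_px > 0)
  if (stats::sd(as.vector(frame)) == 0) {
    return(structure(
      list(mask = matrix(FALSE, nrow(frame), ncol(frame)), um_per_px = um_per_px),
      class = "vessel_mask"
    ))
  }
  # background by grey-scale closing: a disc wider than any vessel erases
  # dark tubes but follows the smooth scleral background, so the response
  # bg - frame is the vessel's own intensity dip, undistorted
  brush_d <- 2L * as.integer(background_sigma_px) + 1L
  brush_d <- min(brush_d, 2L * (min(dim(frame)) %/% 2L) - 1L)
  brush <- EBImage::makeBrush(brush_d, shape = "disc")
  bg <- as.matrix(EBImage::closing(EBImage::Image(frame), brush))
  resp <- bg - frame # dark vessels -> positive response
  if (smooth_sigma_px > 0) {
    resp <- as.matrix(EBImage::gblur(resp, sigma = smooth_sigma_px))
  }
  resp[resp < 0] <- 0
  mx <- max(resp)
  if (mx <= 0) {
    return(structure(
      list(mask = matrix(FALSE, nrow(frame), ncol(frame)), um_per_px = um_per_px),
      class = "vessel_mask"
    ))
  }
  # Otsu locates the vessel core; the final edge is set at half the core
  # response level (full-width-at-half-maximum), which for a blurred
  # flat-topped tube profile falls on the true lumen edge
  thr <- EBImage::otsu(EBImage::Image(resp / mx), range = c(0, 1)) * mx
  core <- resp > thr
  core <- drop_small_objects(core, min_object_px)
  if (!any(core)) {
    return(structure(
      list(mask = matrix(FALSE, nrow(frame), ncol(frame)), um_per_px = um_per_px),
      class = "vessel_mask"
    ))
  }
  level <- stats::quantile(resp[core], 0.7)
  mask <- resp >= 0.5 * level
  mask <- drop_small_objects(mask, min_object_px)
  structure(list(mask = mask, um_per_px = um_per_px), class = "vessel_mask")
}

# separable box mean filter with replicated borders (radius clipped to the
# image); cumsum-based so arbitrarily large kernels cost O(HW)
box_blur <- function(m, radius) {
  r <- max(1L, round(radius))
  run_mean <- function(x, r) {
    n <- length(x)
    r <- min(r, n - 1L)
    xp <- c(rep(x[1], r), x, rep(x[n], r))
    cs <- c(0, cumsum(xp))
    (cs[(2 * r + 1 + 1):(n + 2 * r + 1)] - cs[1:n]) / (2 * r + 1)
  }
  m <- apply(m, 2, run_mean, r = r)
  t(apply(t(m), 2, run_mean, r = r))
}

drop_small_objects <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf(
    "<vessel_mask> %d x %d px, %d foreground px (%.1f%%), %g um/px\n",
    nrow(x$mask), ncol(x$mask), sum(x$mask),
    100 * mean(x$mask), x$um_per_px
  ))
  invisible(x)
}

# ---- skeletonization -------------------------------------------------------

# one Zhang-Suen sub-iteration, fully vectorised over the image
zs_subiter <- function(M, first) {
  H <- nrow(M); W <- ncol(M)
  P <- matrix(0L, H + 2, W + 2); P[2:(H + 1), 2:(W + 1)] <- M
  nb <- function(dr, dc) P[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  # neighbours clockwise from north (row - 1)
  p2 <- nb(-1, 0); p3 <- nb(-1, 1); p4 <- nb(0, 1); p5 <- nb(1, 1)
  p6 <- nb(1, 0); p7 <- nb(1, -1); p8 <- nb(0, -1); p9 <- nb(-1, -1)
  B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  if (first) {
    cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
  } else {
    cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
  }
  del <- M == 1L & B >= 2 & B <= 6 & A == 1 & cond
  M[del] <- 0L
  list(M = M, changed = any(del))
}

# Zhang-Suen iterative thinning to a 1-px-wide 8-connected skeleton
skeletonize <- function(mask) {
  M <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    s1 <- zs_subiter(M, first = TRUE)
    s2 <- zs_subiter(s1$M, first = FALSE)
    M <- s2$M
    if (!s1$changed && !s2$changed) break
  }
  M == 1L
}

# 8-neighbour offsets
.nb8 <- cbind(
  dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

# decompose a skeleton into ordered simple branches; returns list of
# n x 2 matrices of (row, col) coordinates
skeleton_branches <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  if (nrow(pts) == 0) return(list())
  H <- nrow(skel); W <- ncol(skel)
  key <- function(r, c) (c - 1L) * H + r
  on <- logical(H * W); on[key(pts[, 1], pts[, 2])] <- TRUE
  deg <- integer(H * W)
  for (i in seq_len(8)) {
    r <- pts[, 1] + .nb8[i, "dr"]; c <- pts[, 2] + .nb8[i, "dc"]
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    hit <- logical(nrow(pts)); hit[ok] <- on[key(r[ok], c[ok])]
    deg[key(pts[, 1], pts[, 2])] <- deg[key(pts[, 1], pts[, 2])] + hit
  }
  junction <- logical(H * W)
  junction[key(pts[, 1], pts[, 2])] <- deg[key(pts[, 1], pts[, 2])] >= 3
  # walk branches: non-junction pixels, split at junctions
  visited <- logical(H * W)
  branches <- list()
  neighbours <- function(r, c) {
    rr <- r + .nb8[, "dr"]; cc <- c + .nb8[, "dc"]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    rr <- rr[ok]; cc <- cc[ok]
    hit <- on[key(rr, cc)]
    cbind(rr[hit], cc[hit])
  }
  walk <- function(r, c) {
    path <- matrix(c(r, c), 1, 2)
    visited[key(r, c)] <<- TRUE
    repeat {
      nb <- neighbours(r, c)
      k <- key(nb[, 1], nb[, 2])
      nxt <- which(!visited[k] & !junction[k])
      if (length(nxt) == 0) break
      j <- nxt[1]
      r <- nb[j, 1]; c <- nb[j, 2]
      visited[key(r, c)] <<- TRUE
      path <- rbind(path, c(r, c))
    }
    path
  }
  # start walks at endpoints (degree 1) first, then remaining unvisited
  ends <- pts[deg[key(pts[, 1], pts[, 2])] == 1, , drop = FALSE]
  for (i in seq_len(nrow(ends))) {
    k <- key(ends[i, 1], ends[i, 2])
    if (visited[k] || junction[k]) next
    branches[[length(branches) + 1L]] <- walk(ends[i, 1], ends[i, 2])
  }
  for (i in seq_len(nrow(pts))) {
    k <- key(pts[i, 1], pts[i, 2])
    if (visited[k] || junction[k]) next
    branches[[length(branches) + 1L]] <- walk(pts[i, 1], pts[i, 2])
  }
  branches
}

#' Extract ordered vessel centerlines from a binary mask
#'
#' The mask is thinned to a one-pixel skeleton (iterative Zhang-Suen
#' thinning), the skeleton is split at branch points, and each remaining
#' simple path becomes one candidate segment with its points ordered
#' end-to-end. Short spurs (below `min_length_px` points) are pruned.
#'
#' @param mask a `vessel_mask` from [segment_vessels()], or a logical
#'   matrix (then `um_per_px` must be given).
#' @param min_length_px prune branches shorter than this many skeleton
#'   pixels (default 10).
#' @param um_per_px pixel pitch when `mask` is a bare matrix.
#' @return A tibble of centerline points: `segment_id`, `point_index`,
#'   `x` (column), `y` (row), `s_um` (arc length from the segment start),
#'   with attribute `um_per_px`. Empty masks give an empty tibble.
#' @export
extract_centerlines <- function(mask, min_length_px = 10, um_per_px = NULL) {
  if (inherits(mask, "vessel_mask")) {
    um_per_px <- mask$um_per_px
    mask <- mask$mask
  }
  stopifnot(is.matrix(mask), !is.null(um_per_px))
  empty <- tibble::tibble(
    segment_id = integer(), point_index = integer(),
    x = numeric(), y = numeric(), s_um = numeric()
  )
  attr(empty, "um_per_px") <- um_per_px
  if (!any(mask)) return(empty)
  branches <- skeleton_branches(skeletonize(mask))
  branches <- branches[vapply(branches, nrow, integer(1)) >= min_length_px]
  if (length(branches) == 0) return(empty)
  out <- purrr::map_dfr(seq_along(branches), function(i) {
    b <- branches[[i]]
    step <- sqrt(diff(b[, 2])^2 + diff(b[, 1])^2)
    tibble::tibble(
      segment_id = i,
      point_index = seq_len(nrow(b)),
      x = b[, 2], y = b[, 1],
      s_um = c(0, cumsum(step)) * um_per_px
    )
  })
  attr(out, "um_per_px") <- um_per_px
  out
}

# exact Euclidean distance-to-background at given foreground points (px).
# EBImage::distmap is the workhorse; points outside the foreground raise.
edt_at_points <- function(mask, xs, ys) {
  fg <- mask[cbind(ys, xs)]
  if (any(!fg)) {
    i <- which(!fg)[1]
    stop(sprintf(
      "centerline point (x=%d, y=%d) lies outside the mask foreground",
      xs[i], ys[i]
    ), call. = FALSE)
  }
  dm <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean"))
  dm[cbind(ys, xs)]
}

#' Fill per-point vessel diameters via the Euclidean distance transform
#'
#' The diameter at a centerline point is twice its Euclidean distance to
#' the nearest background pixel, scaled to micrometres. Discretisation
#' makes individual points accurate to about one pixel; the segment
#' summary diameter is the mean over points.
#'
#' @param mask a `vessel_mask` (or logical matrix matching the centerline).
#' @param centerlines tibble from [extract_centerlines()].
#' @return `centerlines` with an added `diameter_um` column.
#' @export
edt_diameter <- function(mask, centerlines) {
  if (inherits(mask, "vessel_mask")) {
    um_per_px <- mask$um_per_px
    mask <- mask$mask
  } else {
    um_per_px <- attr(centerlines, "um_per_px")
  }
  stopifnot(is.matrix(mask), !is.null(um_per_px))
  if (nrow(centerlines) == 0) {
    centerlines$diameter_um <- numeric(0)
    return(centerlines)
  }
  d <- edt_at_points(mask, round(centerlines$x), round(centerlines$y))
  centerlines$diameter_um <- 2 * d * um_per_px
  attr(centerlines, "um_per_px") <- um_per_px
  centerlines
}

#' Summarise centerline segments with quality scores
#'
#' Per segment: arc length, mean diameter, and a quality score in [0, 1] =
#' the fraction of centerline points whose local contrast (background minus
#' vessel intensity, relative to the frame's intensity spread) clears a
#' floor. Segments shorter than `min_length_um` or below `min_quality` are
#' flagged excluded; downstream aggregation uses included segments only.
#'
#' @param centerlines tibble from [edt_diameter()].
#' @param frame the (registered reference) frame the mask came from;
#'   optional — without it quality defaults to 1.
#' @param contrast_floor minimum local contrast, as a fraction of the
#'   frame's 5th-to-95th percentile intensity spread.
#' @param min_quality quality floor for inclusion (default 0.5).
#' @param min_length_um minimum segment length for inclusion (default 50).
#' @return A tibble: `segment_id`, `n_points`, `length_um`,
#'   `mean_diameter_um`, `quality`, `included`.
#' @export
summarise_segments <- function(centerlines, frame = NULL,
                               contrast_floor = 0.2,
                               min_quality = 0.5, min_length_um = 50) {
  if (nrow(centerlines) == 0) {
    return(tibble::tibble(
      segment_id = integer(), n_points = integer(), length_um = numeric(),
      mean_diameter_um = numeric(), quality = numeric(), included = logical()
    ))
  }
  qual <- rep(1, nrow(centerlines))
  if (!is.null(frame)) {
    spread <- diff(stats::quantile(frame, c(0.05, 0.95)))
    hi <- stats::quantile(frame, 0.9) # background reference intensity
    val <- frame[cbind(round(centerlines$y), round(centerlines$x))]
    qual <- as.numeric((hi - val) / max(spread, .Machine$double.eps) >= contrast_floor)
  }
  centerlines$.q <- qual
  out <- centerlines |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      length_um = max(.data$s_um),
      mean_diameter_um = if ("diameter_um" %in% names(centerlines)) {
        mean(.data$diameter_um)
      } else NA_real_,
      quality = mean(.data$.q),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      included = .data$quality >= min_quality & .data$length_um >= min_length_um
    )
  out
}

#' Write centerline segments as CSV
#' @param centerlines tibble from [edt_diameter()] / [extract_centerlines()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(centerlines, path) {
  utils::write.csv(centerlines, path, row.names = FALSE)
  invisible(path)
}
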