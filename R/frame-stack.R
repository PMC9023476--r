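#' Grayscale video stack with physical calibration
#'
#' A `frame_stack` holds a time-ordered grayscale image sequence as an
#' H x W x T numeric array together with its acquisition metadata: the frame
#' rate in frames per second and the pixel pitch in micrometres per pixel.
#' All downstream geometry is expressed in micrometres and all velocities in
#' mm/s via these two calibration constants.
#'
#' @param frames numeric H x W x T array, or a list of H x W matrices.
#'   Intensities are arbitrary units; vessels are assumed darker than the
#'   surrounding sclera.
#' @param fps frame rate, frames per second (> 0).
#' @param um_per_px pixel pitch, micrometres per pixel (> 0).
#'
#' @return An object of class `frame_stack` with elements `frames`, `fps`,
#'   `um_per_px`.
#' @export
frame_stack <- function(frames, fps, um_per_px) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) {
      stop("all frames must have the same dimensions", call. = FALSE)
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be an H x W x T array or a list of matrices",
         call. = FALSE)
  }
  if (dim(frames)[3] < 1L) stop("a frame_stack needs at least one frame", call. = FALSE)
  if (!is.numeric(fps) || fps <= 0) stop("`fps` must be > 0", call. = FALSE)
  if (!is.numeric(um_per_px) || um_per_px <= 0) {
    stop("`um_per_px` must be > 0", call. = FALSE)
  }
  structure(
    list(frames = frames, fps = fps, um_per_px = um_per_px),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d x %d px, %d frames @ %g fps, %g um/px (%.2f s, %.0f x %.0f um)\n",
    d[1], d[2], d[3], x$fps, x$um_per_px,
    d[3] / x$fps, d[1] * x$um_per_px, d[2] * x$um_per_px
  ))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$frames)[3]
}

#' Extract one frame as a matrix
#' @param stack a [frame_stack()].
#' @param t frame index (1-based).
#' @return H x W numeric matrix.
#' @export
get_frame <- function(stack, t) {
  stopifnot(inherits(stack, "frame_stack"))
  if (t < 1 || t > n_frames(stack)) stop("frame index out of range", call. = FALSE)
  stack$frames[, , t]
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path path to a (multi-page) TIFF file.
#' @inheritParams frame_stack
#' @return a [frame_stack()].
#' @export
read_frame_stack <- function(path, fps, um_per_px) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # drop colour channels if present
    p
  })
  frame_stack(pages, fps = fps, um_per_px = um_per_px)
}

#' Write a frame stack to a multi-page TIFF
#'
#' Intensities are rescaled to [0, 1] over the whole stack (a constant stack
#' maps to 0) and written at 16 bits per sample.
#'
#' @param stack a [frame_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  f <- stack$frames
  rng <- range(f)
  f <- if (diff(rng) > 0) (f - rng[1]) / diff(rng) else f * 0
  pages <- lapply(seq_len(dim(f)[3]), function(t) f[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

# internal: shift a matrix by integer (dy, dx), filling exposed pixels
shift_int <- function(m, dy, dx, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  src_r <- seq_len(H) - dy
  src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# internal: bilinear shift by real (dy, dx); integer fast path
shift_frame <- function(m, dy, dx, fill = stats::median(m)) {
  if (dy == round(dy) && dx == round(dx)) {
    return(shift_int(m, round(dy), round(dx), fill))
  }
  fy <- floor(dy); fx <- floor(dx)
  ry <- dy - fy;   rx <- dx - fx
  m00 <- shift_int(m, fy,     fx,     fill)
  m10 <- shift_int(m, fy + 1, fx,     fill)
  m01 <- shift_int(m, fy,     fx + 1, fill)
  m11 <- shift_int(m, fy + 1, fx + 1, fill)
  (1 - ry) * (1 - rx) * m00 + ry * (1 - rx) * m10 +
    (1 - ry) * rx * m01 + ry * rx * m11
}
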