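# Independent brute-force oracles and small fixture builders used across
# the suite. Nothing here shares code with the implementation paths under
# test.

# exhaustive nearest-background distance (the EDT oracle)
brute_edt <- function(mask, x, y) {
  bgpts <- which(!mask, arr.ind = TRUE)
  if (nrow(bgpts) == 0) return(Inf)
  min(sqrt((bgpts[, 2] - x)^2 + (bgpts[, 1] - y)^2))
}

dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# straight horizontal band mask: rows [y0 - half, y0 + half]
band_mask <- function(H, W, y0, width_px) {
  m <- matrix(FALSE, H, W)
  half <- (width_px - 1) / 2
  rows <- which(abs(seq_len(H) - y0) <= half)
  m[rows, ] <- TRUE
  m
}

# exhaustive pair-enumeration AUROC (concordance with half credit for ties)
pair_auroc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}

# frame-stack of a dark Gaussian blob translating at a fixed px/frame rate
translating_blob_stack <- function(H = 40, W = 120, Tn = 30, v_px = 2,
                                   fps = 60, um_per_px = 1,
                                   y0 = 20, sigma = 3) {
  frames <- array(0.8, dim = c(H, W, Tn))
  for (t in seq_len(Tn)) {
    cx <- 10 + (t - 1) * v_px
    gx <- exp(-0.5 * ((seq_len(W) - cx) / sigma)^2)
    gy <- exp(-0.5 * ((seq_len(H) - y0) / sigma)^2)
    frames[, , t] <- 0.8 - 0.5 * outer(gy, gx)
  }
  frame_stack(frames, fps = fps, um_per_px = um_per_px)
}
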