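#' Rigid translation registration of a dynamic series
#'
#' Registers each frame of a DCE series by translation only, maximizing the
#' normalized cross-correlation (NCC) against a running reference that is
#' updated Kalman-style as frames are aligned (the reference is the
#' filtered mean of previously registered frames, which tracks the slow
#' enhancement drift instead of anchoring on a single frame). Frames are
#' visited outward from `reference_frame`. Integer-pixel search over
#' `search_px` is refined by parabolic interpolation of the NCC surface
#' when `subpixel = TRUE`. Estimated shifts smaller than `min_shift_px`
#' are treated as zero and the frame is left untouched (no resampling), so
#' a motion-free series passes through content-identical.
#'
#' @param series A `dce_series`.
#' @param reference_frame 1-based index of the anchor frame.
#' @param search_px Integer search radius in pixels.
#' @param subpixel Refine shifts by parabolic interpolation of the NCC peak.
#' @param min_shift_px Shifts with absolute value below this (pixels) are
#'   zeroed.
#' @param gain Reference update gain in (0, 1]; the running reference is
#'   `ref + gain * (frame - ref)` after each alignment.
#'
#' @return A list: `series` (registered `dce_series`), `shifts` (frames x 2
#'   matrix of applied corrections, mm), `flagged` (logical per frame; TRUE
#'   where registration was skipped, e.g. an all-zero frame).
#' @export
register_series <- function(series, reference_frame = 1L, search_px = 3L,
                            subpixel = TRUE, min_shift_px = 0.1, gain = 0.25) {
  validate_series(series)
  d <- dim(series$data)
  nf <- d[4]
  if (nf < 2) stop("registration requires at least 2 frames")
  if (reference_frame < 1 || reference_frame > nf)
    stop("'reference_frame' out of range")
  px <- series$pixel_size %||% series$protocol$pixel_size

  shifts <- matrix(0, nf, 2)
  flagged <- logical(nf)
  out <- series
  order_frames <- order(abs(seq_len(nf) - reference_frame))

  for (sl in seq_len(d[1])) {
    ref <- out$data[sl, , , reference_frame]
    if (all(ref == 0)) {
      flagged[reference_frame] <- TRUE
      next
    }
    for (f in order_frames) {
      if (f == reference_frame) next
      frame <- out$data[sl, , , f]
      if (all(frame == 0) || stats::sd(frame) == 0) {
        flagged[f] <- TRUE
        next
      }
      sh <- best_shift(frame, ref, search_px, subpixel)
      sh[abs(sh) < min_shift_px] <- 0
      if (any(sh != 0)) {
        frame <- shift_image(frame, sh[1], sh[2])
        out$data[sl, , , f] <- frame
      }
      shifts[f, ] <- shifts[f, ] + sh * px / d[1]  # averaged over slices
      ref <- ref + gain * (frame - ref)
    }
  }
  list(series = out, shifts = shifts, flagged = flagged)
}

# Gradient magnitude (central differences); contrast enhancement changes
# tissue intensities drastically between frames, but boundary edges stay
# put, so NCC is computed on edge maps rather than raw intensities.
grad_mag <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]
  gy <- img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]
  sqrt(gx^2 + gy^2)
}

# Translation (dx, dy) in pixels that best aligns img to ref. The NCC is
# computed on gradient-magnitude images (boundary edges persist while
# tissue intensities change drastically with enhancement), over a central
# crop that excludes the zero-filled border introduced by shifting.
# Integer-pixel search is refined on successively finer grids (0.25 then
# 0.125 px) of actually-resampled candidates.
best_shift <- function(img, ref, search_px, subpixel) {
  m <- search_px + 2L
  nr <- nrow(img); nc <- ncol(img)
  if (nr <= 2 * m + 2 || nc <= 2 * m + 2)
    stop("image too small for the requested search radius")
  crop <- function(x) x[(m + 1):(nr - m), (m + 1):(nc - m)]
  refc <- as.vector(crop(grad_mag(ref)))
  if (stats::sd(refc) == 0) return(c(0, 0))
  score <- function(dx, dy) {
    cand <- as.vector(crop(grad_mag(shift_image(img, dx, dy))))
    if (stats::sd(cand) == 0) return(-Inf)
    stats::cor(cand, refc)
  }
  search_grid <- function(cx, cy, offs) {
    best <- c(cx, cy); best_s <- -Inf
    for (dy in offs) {
      for (dx in offs) {
        s <- score(cx + dx, cy + dy)
        if (s > best_s) {
          best_s <- s
          best <- c(cx + dx, cy + dy)
        }
      }
    }
    best
  }
  sh <- search_grid(0, 0, -search_px:search_px)
  if (subpixel) {
    sh <- search_grid(sh[1], sh[2], seq(-0.75, 0.75, by = 0.25))
    sh <- search_grid(sh[1], sh[2], seq(-0.125, 0.125, by = 0.125))
  }
  sh
}
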