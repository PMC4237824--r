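#' Simulate a dynamic contrast-enhanced image series from a phantom
#'
#' Forward-models the DCE acquisition: per-pixel tissue concentration
#' follows the Patlak model
#' \deqn{C_t(t) = K^{trans} \int_0^t C_p(\tau)\,d\tau + v_p C_p(t)}
#' (trapezoidal integral on the frame times, Ktrans in 1/min),
#' concentration is mapped to signal through the spoiled gradient echo
#' steady-state equation using the phantom's T10/M0/r1 maps, and the series
#' is optionally corrupted by per-frame rigid translation and additive
#' zero-mean Gaussian noise. Identical seeds give identical output.
#'
#' @param phantom A [build_phantom()] object.
#' @param aif An [generate_aif()] curve sampled on the protocol frame times.
#' @param protocol An [acq_protocol()].
#' @param noise_sd Additive Gaussian noise SD, signal units (>= 0).
#' @param motion_amplitude Maximum per-frame rigid translation, mm (>= 0);
#'   per-frame displacements are drawn uniformly in
#'   `[-motion_amplitude, motion_amplitude]` per axis.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG.
#'
#' @return An object of class `dce_series`: list with `data`, a
#'   slices x rows x cols x frames array (one slice here), `protocol`,
#'   `frame_times` (s), and `motion_true` (frames x 2 matrix of applied
#'   shifts, mm).
#' @export
#' @examples
#' pr <- acq_protocol("GE")
#' ph <- build_phantom(pr)
#' ser <- simulate_series(ph, generate_aif(pr), pr, seed = 1)
#' dim(ser$data)
simulate_series <- function(phantom, aif, protocol,
                            noise_sd = 0, motion_amplitude = 0, seed = NULL) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  validate_aif(aif, protocol)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (motion_amplitude < 0) stop("'motion_amplitude' must be >= 0")

  times <- aif$times
  nf <- length(times)
  n <- phantom$grid_size
  cum_cp_min <- cumtrapz(times, aif$cp) / 60   # mmol/L * min

  k <- as.vector(phantom$ktrans_true)
  v <- as.vector(phantom$vp_true)
  conc <- outer(k, cum_cp_min) + outer(v, aif$cp)   # (npix x nf)

  t10v <- as.vector(phantom$t10)
  sig <- spgr_signal(conc, phantom$m0, t10v, protocol$tr,
                     protocol$flip_angle, phantom$r1)

  with_seed(seed, {
    motion <- matrix(0, nf, 2)
    if (motion_amplitude > 0) {
      motion <- matrix(stats::runif(2 * nf, -motion_amplitude, motion_amplitude), nf, 2)
    }
    arr <- array(0, dim = c(1L, n, n, nf))
    for (f in seq_len(nf)) {
      frame <- matrix(sig[, f], n, n)
      if (motion_amplitude > 0 && any(motion[f, ] != 0)) {
        frame <- shift_image(frame, motion[f, 1] / phantom$pixel_size,
                             motion[f, 2] / phantom$pixel_size)
      }
      arr[1L, , , f] <- frame
    }
    if (noise_sd > 0) {
      arr <- arr + stats::rnorm(length(arr), sd = noise_sd)
    }
    structure(list(
      data = arr,
      protocol = protocol,
      frame_times = times,
      motion_true = motion,
      pixel_size = phantom$pixel_size
    ), class = "dce_series")
  })
}

validate_series <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  d <- dim(series$data)
  if (length(d) != 4L) stop("series data must be a 4D slices x rows x cols x frames array")
  if (d[4] != length(series$frame_times)) stop("frame count does not match frame_times")
  if (any(diff(series$frame_times) <= 0)) stop("frame_times must be strictly increasing")
  invisible(series)
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DCE series: %d slice(s), %dx%d px, %d frames (%.0f s interval, %s)\n",
              d[1], d[2], d[3], d[4], mean(diff(x$frame_times)), x$protocol$vendor))
  invisible(x)
}
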