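#' Pixel-wise Patlak model fit
#'
#' Fits the two-parameter Patlak model
#' \deqn{C_t(t_k) = K^{trans} \int_0^{t_k} C_p(\tau)\,d\tau + v_p C_p(t_k)}
#' by ordinary least squares at every pixel, with the plasma integral
#' computed by the trapezoidal rule on the frame times and
#' \eqn{K^{trans}} reported in 1/min. The design matrix is shared across
#' pixels, so all fits reduce to one linear solve. Raw (unclamped)
#' estimates are stored; clamping to display ranges happens only at
#' rendering. Pixels whose concentration curves contain non-finite values,
#' or all pixels when the design is singular (e.g. an identically zero
#' AIF), are flagged invalid.
#'
#' @param conc A `conc_series`.
#' @param aif An `aif_curve` on the same frame times.
#' @param fit_frames Indices of frames entering the fit; default all
#'   frames (pre-injection frames have \eqn{C_p = 0} and stabilize the
#'   intercept-free model).
#' @param slice Slice index to fit.
#'
#' @return An object of class `kinetic_map`: `ktrans` (1/min), `vp`
#'   (unitless), `fit_residual` (RMS, concentration units), `valid_mask`
#'   (logical), all rows x cols matrices, plus `pixel_size`.
#' @export
#' @examples
#' # see vignette for an end-to-end phantom example
patlak_fit <- function(conc, aif, fit_frames = NULL, slice = 1L) {
  stopifnot(inherits(conc, "conc_series"))
  validate_aif(aif)
  d <- dim(conc$conc)
  nf <- d[4]
  if (length(aif$cp) != nf) stop("AIF frame count does not match the series")
  if (max(abs(aif$times - conc$frame_times)) > 1e-9)
    stop("AIF and series frame times differ")
  if (is.null(fit_frames)) fit_frames <- seq_len(nf)
  post_inj <- sum(aif$cp[fit_frames] > 0)
  if (length(fit_frames) < 3 || post_inj < 2)
    stop("need >= 3 fit frames including >= 2 with non-zero AIF")

  cum_cp_min <- cumtrapz(conc$frame_times, aif$cp) / 60
  X <- cbind(cum_cp_min[fit_frames], aif$cp[fit_frames])

  nr <- d[2]; nc <- d[3]
  Y <- t(matrix(aperm(conc$conc[slice, , , , drop = FALSE], c(4, 2, 3, 1)),
                nf, nr * nc))            # pixels x frames
  Y <- Y[, fit_frames, drop = FALSE]
  finite_pix <- rowSums(!is.finite(Y)) == 0

  ktrans <- matrix(NA_real_, nr, nc)
  vp <- matrix(NA_real_, nr, nc)
  rms <- matrix(NA_real_, nr, nc)
  valid <- matrix(FALSE, nr, nc)

  qrX <- qr(X)
  if (qrX$rank < 2L) {
    warning("singular Patlak design (AIF constant or zero); all pixels flagged invalid")
  } else if (any(finite_pix)) {
    B <- qr.coef(qrX, t(Y[finite_pix, , drop = FALSE]))  # 2 x npix_ok
    res <- t(Y[finite_pix, , drop = FALSE]) - X %*% B
    ktrans[finite_pix] <- B[1, ]
    vp[finite_pix] <- B[2, ]
    rms[finite_pix] <- sqrt(colMeans(res^2))
    valid[finite_pix] <- TRUE
  }

  structure(list(
    ktrans = ktrans,
    vp = vp,
    fit_residual = rms,
    valid_mask = valid,
    pixel_size = conc$pixel_size
  ), class = "kinetic_map")
}

#' @export
print.kinetic_map <- function(x, ...) {
  ok <- x$valid_mask
  cat(sprintf("Kinetic map: %dx%d px, %d valid; Ktrans median %.4g 1/min, vp median %.4g\n",
              nrow(x$ktrans), ncol(x$ktrans), sum(ok),
              stats::median(x$ktrans[ok]), stats::median(x$vp[ok])))
  invisible(x)
}

#' Render a vasa-vasorum (V-V) parametric image
#'
#' Encodes the kinetic map as an RGB image with the transfer constant in
#' the green channel (clamped to `[0, ktrans_max]`, default 0-0.2 1/min)
#' and fractional plasma volume in the red channel (clamped to
#' `[0, vp_max]`, default 0-1); the blue channel is zero. A single channel
#' can be selected for display. Invalid pixels render black.
#'
#' @param map A `kinetic_map`.
#' @param ktrans_max,vp_max Display ranges.
#' @param channel `"both"`, `"ktrans"` or `"vp"`.
#' @return A rows x cols x 3 numeric array in `[0, 1]`.
#' @export
render_vv_image <- function(map, ktrans_max = 0.2, vp_max = 1,
                            channel = c("both", "ktrans", "vp")) {
  stopifnot(inherits(map, "kinetic_map"))
  channel <- match.arg(channel)
  clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
  g <- clamp01(map$ktrans / ktrans_max)
  r <- clamp01(map$vp / vp_max)
  g[!map$valid_mask | !is.finite(g)] <- 0
  r[!map$valid_mask | !is.finite(r)] <- 0
  if (channel == "ktrans") r[] <- 0
  if (channel == "vp") g[] <- 0
  out <- array(0, dim = c(nrow(g), ncol(g), 3L))
  out[, , 1] <- r
  out[, , 2] <- g
  out
}

#' Write a V-V image to PNG
#'
#' @param map A `kinetic_map`.
#' @param path Output PNG path.
#' @param ... Passed to [render_vv_image()].
#' @return The path, invisibly.
#' @export
write_vv_png <- function(map, path, ...) {
  img <- render_vv_image(map, ...)
  png::writePNG(img, path)
  invisible(path)
}
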