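#' Convert a DCE signal series to contrast concentration
#'
#' Estimates the per-pixel equilibrium scale M0 from the mean of the
#' pre-injection baseline frames (where concentration is zero by design),
#' then inverts the spoiled gradient echo signal equation frame by frame to
#' recover T1(t), and maps the T1 change to gadolinium concentration via
#' the relaxivity relation \eqn{C(t) = (1/T_1(t) - 1/T_{10}) / r_1}.
#' Signals outside the invertible range of the SPGR curve are flagged
#' invalid (`NA`) rather than extrapolated.
#'
#' @param series A `dce_series`.
#' @param t10 Baseline T1 in ms: a scalar, or a rows x cols matrix applied
#'   to every slice (e.g. blood vs wall values from a phantom).
#' @param r1 Relaxivity, L/(mmol s).
#' @param baseline_frames Indices of pre-contrast frames; default all
#'   frames before the protocol's injection frame.
#'
#' @return An object of class `conc_series`: list with `conc` (same shape
#'   as the signal data, mmol/L, `NA` where not invertible),
#'   `baseline_frames`, `frame_times`, `protocol`, `pixel_size` and
#'   `valid_mask` (per-pixel, TRUE when every frame inverted).
#' @export
signal_to_concentration <- function(series, t10, r1 = 4.5,
                                    baseline_frames = NULL) {
  validate_series(series)
  pr <- series$protocol
  if (is.null(baseline_frames)) baseline_frames <- seq_len(pr$injection_frame - 1L)
  if (length(baseline_frames) < 1) stop("at least one baseline frame is required")
  if (any(t10 <= 0)) stop("'t10' must be > 0")
  d <- dim(series$data)
  nf <- d[4]
  npix <- d[1] * d[2] * d[3]
  sig <- matrix(series$data, npix, nf)

  t10v <- if (length(t10) == 1L) rep(t10, npix) else {
    if (!identical(dim(as.matrix(t10)), d[2:3]))
      stop("'t10' matrix must be rows x cols of the series")
    rep(as.vector(t10), each = d[1])
  }

  a <- pr$flip_angle * pi / 180
  E10 <- exp(-(pr$tr / 1000) * (1000 / t10v))
  base_gain <- sin(a) * (1 - E10) / (1 - cos(a) * E10)
  s_base <- rowMeans(sig[, baseline_frames, drop = FALSE])
  m0 <- s_base / base_gain

  conc <- spgr_concentration(sig, m0, t10v, pr$tr, pr$flip_angle, r1)
  conc <- matrix(conc, npix, nf)
  valid <- rowSums(!is.finite(conc)) == 0 & is.finite(m0) & m0 > 0
  structure(list(
    conc = array(conc, dim = d),
    baseline_frames = baseline_frames,
    frame_times = series$frame_times,
    protocol = pr,
    pixel_size = series$pixel_size %||% pr$pixel_size,
    valid_mask = array(valid, dim = d[1:3])
  ), class = "conc_series")
}

#' Extract the arterial input function from lumen concentrations
#'
#' Takes the blood concentration per frame as the mean over the
#' top-quartile enhancing pixels inside the lumen contour (ranked by mean
#' post-baseline concentration), and converts blood to plasma
#' concentration by \eqn{C_p = C_{blood} / (1 - Hct)}. Negative values
#' (noise on baseline frames) are clamped to zero.
#'
#' @param conc A `conc_series`.
#' @param lumen_contour Two-column matrix of lumen polygon vertices, mm.
#' @param hematocrit Hematocrit fraction in `[0, 1)`; use 0 when the lumen
#'   signal already represents plasma concentration (as in the phantom
#'   simulator, whose lumen has vp = 1).
#' @param top_fraction Fraction of most-enhancing lumen pixels averaged.
#' @param slice Slice index used for extraction.
#'
#' @return An `aif_curve` with `times` and `cp` (mmol/L).
#' @export
extract_aif <- function(conc, lumen_contour, hematocrit = 0.42,
                        top_fraction = 0.25, slice = 1L) {
  stopifnot(inherits(conc, "conc_series"))
  if (hematocrit < 0 || hematocrit >= 1) stop("'hematocrit' must be in [0, 1)")
  d <- dim(conc$conc)
  ctr <- pixel_centers(d[2], d[3], conc$pixel_size)
  inside <- point_in_polygon(as.vector(ctr$x), as.vector(ctr$y), lumen_contour)
  inside <- matrix(inside, d[2], d[3])
  valid <- conc$valid_mask[slice, , ]
  idx <- which(inside & valid)
  if (length(idx) == 0) stop("lumen ROI is empty: cannot extract an AIF")
  if (length(idx) < 10)
    warning("lumen ROI has fewer than 10 pixels; AIF may be unreliable")

  nf <- d[4]
  curves <- matrix(NA_real_, length(idx), nf)
  for (f in seq_len(nf)) {
    fr <- conc$conc[slice, , , f]
    curves[, f] <- fr[idx]
  }
  post <- setdiff(seq_len(nf), conc$baseline_frames)
  score <- rowMeans(curves[, post, drop = FALSE])
  n_top <- max(1L, ceiling(top_fraction * length(idx)))
  top <- order(score, decreasing = TRUE)[seq_len(n_top)]
  blood <- colMeans(curves[top, , drop = FALSE])
  cp <- pmax(0, blood / (1 - hematocrit))
  structure(list(times = conc$frame_times, cp = cp), class = "aif_curve")
}
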