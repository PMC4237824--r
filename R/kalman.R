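#' Temporal Kalman smoothing of per-pixel enhancement curves
#'
#' Applies a fixed-interval (Rauch-Tung-Striebel) Kalman smoother to every
#' pixel time curve under a random-walk state model
#' \eqn{x_t = x_{t-1} + w_t}, \eqn{y_t = x_t + v_t} with process variance
#' `process_var` and observation variance `obs_var`. Because the variances
#' are shared across pixels, the gain sequence is scalar and the smoother
#' is fully vectorized over pixels. In the perfect-observation limit
#' `obs_var = 0` the smoother is the identity; for white-noise input with
#' `obs_var >> process_var` it strictly reduces temporal variance.
#'
#' @param series A `dce_series`.
#' @param process_var Random-walk process variance, signal units squared
#'   (> 0).
#' @param obs_var Observation noise variance, signal units squared (>= 0);
#'   `NULL` estimates it from second temporal differences
#'   (\eqn{E[\Delta^2 y]^2 = 6\sigma^2} for white noise on a
#'   slowly-varying curve).
#'
#' @return A `dce_series` with smoothed data; the estimated/used `obs_var`
#'   is attached as attribute `"obs_var"`.
#' @export
kalman_smooth <- function(series, process_var, obs_var = NULL) {
  validate_series(series)
  if (process_var <= 0) stop("'process_var' must be > 0")
  d <- dim(series$data)
  nf <- d[4]
  npix <- d[1] * d[2] * d[3]
  y <- matrix(series$data, npix, nf)   # pixels x frames

  if (is.null(obs_var)) {
    d2 <- y[, -c(1, 2), drop = FALSE] - 2 * y[, -c(1, nf), drop = FALSE] +
      y[, -c(nf - 1, nf), drop = FALSE]
    # d2 ~ N(0, 6 sigma^2) for white noise on a slowly-varying curve; the
    # median of d2^2 (robust to enhancing pixels) is 6 sigma^2 qchisq(0.5, 1)
    obs_var <- stats::median(d2^2) / (6 * stats::qchisq(0.5, 1))
  }
  if (obs_var < 0) stop("'obs_var' must be >= 0")

  if (obs_var == 0) {
    out <- series
    attr(out, "obs_var") <- 0
    return(out)
  }

  q <- process_var; r <- obs_var
  xf <- matrix(0, npix, nf)   # filtered means
  xp <- matrix(0, npix, nf)   # one-step predictions
  Pf <- numeric(nf); Pp <- numeric(nf)
  # Initialize from the first observation.
  xf[, 1] <- y[, 1]; Pf[1] <- r
  xp[, 1] <- y[, 1]; Pp[1] <- r
  for (t in 2:nf) {
    xp[, t] <- xf[, t - 1]
    Pp[t] <- Pf[t - 1] + q
    K <- Pp[t] / (Pp[t] + r)
    xf[, t] <- xp[, t] + K * (y[, t] - xp[, t])
    Pf[t] <- (1 - K) * Pp[t]
  }
  xs <- xf
  for (t in (nf - 1):1) {
    A <- Pf[t] / Pp[t + 1]
    xs[, t] <- xf[, t] + A * (xs[, t + 1] - xp[, t + 1])
  }
  out <- series
  out$data <- array(xs, dim = d)
  attr(out, "obs_var") <- obs_var
  out
}
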