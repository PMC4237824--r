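# Spoiled gradient echo steady-state signal model and its inverse.
#
# S = M0 sin(a) (1 - E) / (1 - cos(a) E),  E = exp(-TR / T1),
# 1/T1(t) = 1/T10 + r1 C(t)   (rates in 1/s, TR/T10 in ms, r1 in L/(mmol s)).

#' SPGR steady-state signal for a given contrast concentration
#'
#' @param conc Contrast concentration, mmol/L (any shape).
#' @param m0 Equilibrium signal scale (scalar or conformable array).
#' @param t10 Baseline T1, ms (scalar or conformable array).
#' @param tr Repetition time, ms.
#' @param flip_angle Flip angle, degrees.
#' @param r1 Relaxivity, L/(mmol s).
#' @return Signal of the same shape as `conc`.
#' @export
spgr_signal <- function(conc, m0, t10, tr, flip_angle, r1) {
  a <- flip_angle * pi / 180
  rate <- 1000 / t10 + r1 * conc            # 1/s
  E <- exp(-(tr / 1000) * rate)
  m0 * sin(a) * (1 - E) / (1 - cos(a) * E)
}

#' Invert the SPGR signal equation to contrast concentration
#'
#' Given the measured signal and the per-pixel equilibrium scale `m0`
#' (typically estimated from pre-contrast baseline frames), recovers
#' \eqn{E = \exp(-TR/T_1)} in closed form and converts the T1 change to
#' concentration via the relaxivity relation. Signals outside the invertible
#' range of the SPGR curve yield `NA` rather than an extrapolated value.
#'
#' @param signal Measured signal (any shape).
#' @inheritParams spgr_signal
#' @return Concentration in mmol/L, same shape as `signal`; `NA` where the
#'   signal is not invertible.
#' @export
spgr_concentration <- function(signal, m0, t10, tr, flip_angle, r1) {
  a <- flip_angle * pi / 180
  s <- signal / (m0 * sin(a))
  E <- (1 - s) / (1 - cos(a) * s)
  ok <- is.finite(E) & E > 0 & E <= 1
  rate <- rep(NA_real_, length(E))
  rate[ok] <- -log(E[ok]) / (tr / 1000)     # 1/T1 in 1/s
  conc <- (rate - 1000 / t10) / r1
  attributes(conc) <- attributes(signal)
  conc
}
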