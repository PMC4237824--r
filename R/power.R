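#' CV of a change score from the single-measurement CV
#'
#' A follow-up-minus-baseline change carries the measurement error of two
#' independent scans, so its CV (relative to the baseline mean) is the
#' single-time-point between-scan CV multiplied by \eqn{\sqrt 2}.
#'
#' @param cv_single Single-measurement between-scan CV, fraction (> 0).
#' @return `cv_single * sqrt(2)`.
#' @export
cv_of_change <- function(cv_single) {
  if (any(cv_single <= 0)) stop("'cv_single' must be > 0")
  cv_single * sqrt(2)
}

#' Power of the two-sided two-sample t-test
#'
#' Exact power via the noncentral t distribution, with noncentrality
#' \eqn{\delta / (\sigma\sqrt{2/n})} and \eqn{2n - 2} degrees of freedom
#' (n may be non-integer, as in sample-size solving).
#'
#' @param n Subjects per arm (> 1, possibly fractional).
#' @param delta True between-arm difference.
#' @param sd Common within-arm SD.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
power_two_sample_t <- function(n, delta, sd, alpha = 0.05) {
  df <- 2 * n - 2
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- delta / (sd * sqrt(2 / n))
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp = ncp)
}

#' Sample size per arm to detect a between-arm difference in % change
#'
#' Solves the two-sided unpaired t-test design for the per-arm sample size
#' needed to detect a between-arm difference `pct_diff` in % change when
#' the within-arm SD is dominated by measurement error: the SD of the
#' change score (as a fraction of the baseline mean) is
#' [cv_of_change()]`(cv_single)`. The continuous n satisfying
#' power = `power` is found from the exact noncentral-t power function and
#' converted to an integer by `rounding`: `"nearest"` (default) reports
#' the conventionally-rounded solution, `"ceiling"` the smallest integer
#' whose exact power is not below target by more than rounding of the
#' continuous solve allows.
#'
#' @param cv_single Single-measurement between-scan CV, fraction.
#' @param pct_diff Detectable between-arm difference in % change, fraction
#'   in (0, 2).
#' @param power Target power.
#' @param alpha Two-sided significance level.
#' @param rounding `"nearest"` or `"ceiling"`.
#' @param n_max Cap on the solve; exceeding it raises an error.
#' @return Integer subjects per arm.
#' @export
#' @examples
#' sample_size_per_arm(0.25, 0.20)  # 50
sample_size_per_arm <- function(cv_single, pct_diff, power = 0.80,
                                alpha = 0.05,
                                rounding = c("nearest", "ceiling"),
                                n_max = 1e7) {
  rounding <- match.arg(rounding)
  if (cv_single <= 0) stop("'cv_single' must be > 0")
  if (pct_diff <= 0 || pct_diff >= 2) stop("'pct_diff' must be in (0, 2)")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  sd <- cv_of_change(cv_single)
  f <- function(n) power_two_sample_t(n, pct_diff, sd, alpha) - power
  lo <- 1.5
  if (f(n_max) < 0)
    stop("required sample size exceeds n_max = ", format(n_max),
         "; the detectable difference is too small for this CV")
  while (f(lo) > 0 && lo > 1.0001) lo <- 1 + (lo - 1) / 2
  n_cont <- stats::uniroot(f, c(lo, n_max), tol = 1e-9)$root
  n <- switch(rounding, nearest = round(n_cont), ceiling = ceiling(n_cont))
  as.integer(max(2, n))
}

#' Sample-size curve over a grid of detectable differences
#'
#' @param cv_single Single-measurement CV, fraction.
#' @param diffs Vector of detectable % differences, fractions in (0, 2).
#' @param parameter Optional label column value.
#' @param ... Passed to [sample_size_per_arm()].
#' @return A data.frame with columns `parameter`, `pct_diff`, `n_per_arm`;
#'   `n_per_arm` is non-increasing in `pct_diff`.
#' @export
#' @examples
#' sample_size_curve(0.25, c(0.10, 0.20, 0.30))
sample_size_curve <- function(cv_single, diffs, parameter = NA_character_, ...) {
  if (length(diffs) < 1) stop("'diffs' must be non-empty")
  n <- vapply(diffs, function(d) sample_size_per_arm(cv_single, d, ...), integer(1))
  data.frame(parameter = parameter, pct_diff = diffs, n_per_arm = n,
             stringsAsFactors = FALSE)
}
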