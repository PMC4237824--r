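#' Variance components of a balanced scan-rescan table
#'
#' Fits the random-intercept model \eqn{y_{ij} = \mu + b_i + e_{ij}} to a
#' balanced two-scan table by the one-way random-effects ANOVA moment
#' estimator, which coincides with REML in this balanced design:
#' \eqn{\hat\sigma_w^2 = MSW} (within-subject mean square, here the mean
#' of \eqn{d_i^2/2} over subjects), \eqn{\hat\sigma_b^2 = \max(0, (MSB -
#' MSW)/2)}, \eqn{\hat\mu} the grand mean. Truncation of a negative
#' between-subject variance to zero is recorded.
#'
#' @param table A paired cohort data.frame with columns `subject_id`,
#'   `y1`, `y2` (complete cases, one row per subject).
#' @return An object of class `variance_components`: `grand_mean`,
#'   `sigma_b`, `sigma_w`, `msb`, `msw`, `n_subjects`, `truncated`.
#' @export
#' @examples
#' tab <- data.frame(subject_id = 1:3, vendor = "GE",
#'                   y1 = c(1, 2, 4), y2 = c(3, 2, 6))
#' fit_variance_components(tab)$sigma_w  # sqrt(4/3)
fit_variance_components <- function(table) {
  check_cohort(table)
  n <- nrow(table)
  if (n < 3) stop("need at least 3 subjects")
  y1 <- table$y1; y2 <- table$y2
  mu <- mean(c(y1, y2))
  msw <- mean((y1 - y2)^2 / 2)
  msb <- 2 * stats::var((y1 + y2) / 2)
  sb2 <- (msb - msw) / 2
  truncated <- sb2 < 0
  structure(list(
    grand_mean = mu,
    sigma_b = sqrt(max(0, sb2)),
    sigma_w = sqrt(msw),
    msb = msb,
    msw = msw,
    n_subjects = n,
    truncated = truncated
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components (n = %d): mean %.4g, sigma_b %.4g, sigma_w %.4g%s\n",
              x$n_subjects, x$grand_mean, x$sigma_b, x$sigma_w,
              if (x$truncated) " (between-subject variance truncated at 0)" else ""))
  invisible(x)
}

#' Between-scan coefficient of variation
#'
#' The between-scan SD divided by the grand mean, the relative scan-rescan
#' measurement error of a single time-point measurement.
#'
#' @param components A `variance_components` object.
#' @return CV as a fraction.
#' @export
cv_between_scan <- function(components) {
  stopifnot(inherits(components, "variance_components"))
  if (components$grand_mean <= 0)
    stop("CV undefined: grand mean must be > 0")
  components$sigma_w / components$grand_mean
}

#' Intra-class correlation from variance components
#'
#' \eqn{ICC = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}; when both
#' components are zero (constant data) the ICC is defined as 0 and flagged
#' degenerate via attribute `"degenerate"`.
#'
#' @param components A `variance_components` object.
#' @return ICC in `[0, 1]`.
#' @export
icc <- function(components) {
  stopifnot(inherits(components, "variance_components"))
  tot <- components$sigma_b^2 + components$sigma_w^2
  if (tot == 0) return(structure(0, degenerate = TRUE))
  components$sigma_b^2 / tot
}

#' Paired t-test between scan 1 and scan 2 means
#'
#' @param table A paired cohort data.frame (`y1`, `y2`).
#' @return A list: `t`, `p`, `mean1`, `mean2`, `df`; `p` is `NA` (flagged
#'   via `degenerate = TRUE`) when the differences have zero variance.
#' @export
paired_t_test <- function(table) {
  check_cohort(table)
  if (nrow(table) < 3) stop("need at least 3 subjects")
  d <- table$y1 - table$y2
  if (stats::sd(d) == 0) {
    # Identical scans: no evidence of a shift (t = 0, p = 1). A constant
    # non-zero shift has zero-variance differences: p undefined, flagged.
    if (all(d == 0)) {
      return(list(t = 0, p = 1,
                  mean1 = mean(table$y1), mean2 = mean(table$y2),
                  df = nrow(table) - 1L, degenerate = TRUE))
    }
    return(list(t = NA_real_, p = NA_real_,
                mean1 = mean(table$y1), mean2 = mean(table$y2),
                df = nrow(table) - 1L, degenerate = TRUE))
  }
  tt <- stats::t.test(table$y1, table$y2, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean1 = mean(table$y1), mean2 = mean(table$y2),
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Per-subject between-scan SD
#'
#' The two-observation sample SD, \eqn{|y_1 - y_2| / \sqrt{2}}, used to
#' relate individual measurement variability to subject means and plaque
#' size.
#'
#' @param table A paired cohort data.frame.
#' @return Numeric vector, one value per subject.
#' @export
per_subject_sd <- function(table) {
  check_cohort(table)
  abs(table$y1 - table$y2) / sqrt(2)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average ranks for ties; two-sided p-value from
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n - 2} degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 5).
#' @return A list with `rho` and `p`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant input")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Bland-Altman agreement statistics
#'
#' Differences \eqn{d_i = y_{i2} - y_{i1}} against means
#' \eqn{(y_{i1} + y_{i2})/2}; limits of agreement are
#' \eqn{\bar d \pm 2\,SD(d)} (factor 2).
#'
#' @param table A paired cohort data.frame.
#' @return A list of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, and the per-subject `diffs` and `means`.
#' @export
bland_altman <- function(table) {
  check_cohort(table)
  if (nrow(table) < 3) stop("need at least 3 subjects")
  d <- table$y2 - table$y1
  m <- (table$y1 + table$y2) / 2
  sd_d <- stats::sd(d)
  structure(list(
    mean_diff = mean(d), sd_diff = sd_d,
    loa_low = mean(d) - 2 * sd_d, loa_high = mean(d) + 2 * sd_d,
    diffs = d, means = m
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4g, limits of agreement [%.4g, %.4g]\n",
              x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of scans", ylab = "Scan 2 - Scan 1", ...) {
  graphics::plot(x$means, x$diffs, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$mean_diff, x$loa_low, x$loa_high), lty = c(1, 2, 2))
  invisible(x)
}

#' Subset a cohort to larger plaques
#'
#' Retains subjects whose smaller of the two scans' analyzed plaque areas
#' is at least `min_area` (small lesions drive poor vp reproducibility).
#'
#' @param table A paired cohort data.frame with `area1`, `area2` (mm^2).
#' @param min_area Threshold, mm^2.
#' @return The filtered table.
#' @export
subgroup_by_area <- function(table, min_area = 25) {
  if (!all(c("area1", "area2") %in% names(table)))
    stop("cohort table must carry area1/area2 columns")
  table[pmin(table$area1, table$area2) >= min_area, , drop = FALSE]
}

# Reproducibility statistic and its delta-method standard error from the
# paired observations. x_i = d_i^2/2 estimates sigma_w^2; m_i are subject
# means. Returns c(estimate, se); se is NA where no delta-method SE is
# implemented (icc).
repro_stat_se <- function(y1, y2, statistic) {
  n <- length(y1)
  x <- (y1 - y2)^2 / 2
  sw2 <- mean(x)
  sw <- sqrt(sw2)
  m <- (y1 + y2) / 2
  switch(statistic,
    sd = {
      se <- if (sw > 0) sqrt(stats::var(x) / n) / (2 * sw) else 0
      c(sw, se)
    },
    cv = {
      mu <- mean(c(y1, y2))
      if (mu <= 0) return(c(NA_real_, NA_real_))
      cv <- sw / mu
      if (sw > 0) {
        g <- c(1 / (2 * sw * mu), -sw / mu^2)
        v <- g[1]^2 * stats::var(x) / n + g[2]^2 * stats::var(m) / n +
          2 * g[1] * g[2] * stats::cov(x, m) / n
        c(cv, sqrt(max(v, 0)))
      } else c(cv, 0)
    },
    icc = {
      msb <- 2 * stats::var(m)
      sb2 <- max(0, (msb - sw2) / 2)
      tot <- sb2 + sw2
      c(if (tot == 0) 0 else sb2 / tot, NA_real_)
    })
}

#' Nonparametric bootstrap CI for a reproducibility statistic
#'
#' Resamples subjects with replacement (scan pairs kept intact) and
#' recomputes the statistic per replicate. For the variance-type
#' statistics (`"sd"`, `"cv"`) the default interval is the studentized
#' (bootstrap-t) interval with delta-method standard errors: the squared
#' per-subject differences driving \eqn{\hat\sigma_w} are scaled
#' \eqn{\chi^2_1} and hence strongly right-skewed, for which plain
#' percentile intervals undercover at cohort sizes in the tens while the
#' studentized interval restores near-nominal coverage. For `"icc"` (a
#' bounded ratio) the percentile interval is used. Replicates where the
#' statistic is undefined are dropped; if they exceed 10% the interval is
#' flagged unstable. Degenerate tables (zero variance) fall back to the
#' percentile interval.
#'
#' @param table A paired cohort data.frame.
#' @param statistic `"sd"` (between-scan SD), `"cv"` or `"icc"`.
#' @param B Number of bootstrap replicates (>= 200).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @param method `"studentized"` or `"percentile"`; default studentized
#'   for sd/cv, percentile for icc.
#' @return Numeric `c(lower, upper)` with attributes `B_used` and
#'   `unstable`.
#' @export
bootstrap_ci <- function(table, statistic = c("sd", "cv", "icc"),
                         B = 2000L, seed = NULL, conf = 0.95,
                         method = NULL) {
  statistic <- match.arg(statistic)
  check_cohort(table)
  n <- nrow(table)
  if (B < 200) stop("'B' must be >= 200")
  if (n < 5) stop("need at least 5 subjects for the bootstrap")
  if (is.null(method)) {
    method <- if (statistic == "icc") "percentile" else "studentized"
  }
  method <- match.arg(method, c("studentized", "percentile"))
  est <- repro_stat_se(table$y1, table$y2, statistic)
  theta <- est[1]
  se <- est[2]
  if (method == "studentized" && (!is.finite(se) || se <= 0 || theta <= 0)) {
    method <- "percentile"   # degenerate or unstudentizable table
  }
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    reps <- vapply(seq_len(B), function(b) {
      i <- idx[, b]
      repro_stat_se(table$y1[i], table$y2[i], statistic)
    }, numeric(2))
    if (method == "percentile") {
      vals <- reps[1, ]
      ok <- is.finite(vals)
      if (!any(ok)) stop("statistic undefined in every bootstrap replicate")
      ci <- unname(stats::quantile(vals[ok], c(alpha, 1 - alpha)))
    } else {
      tstar <- (reps[1, ] - theta) / reps[2, ]
      ok <- is.finite(tstar)
      if (!any(ok)) stop("statistic undefined in every bootstrap replicate")
      q <- unname(stats::quantile(tstar[ok], c(alpha, 1 - alpha)))
      ci <- c(theta - q[2] * se, theta - q[1] * se)
    }
    if (statistic %in% c("sd", "cv")) ci[1] <- max(ci[1], 0)
    if (statistic == "icc") ci <- pmin(1, pmax(0, ci))
    structure(ci, B_used = sum(ok), unstable = mean(!ok) > 0.10,
              method = method)
  })
}

#' Vendor comparison of means and between-scan SDs
#'
#' Tests the vendor difference in means with the mixed model's balanced
#' fast path (a two-sample t-test on subject means, equivalent to a vendor
#' fixed effect in the random-intercept model for this balanced design)
#' and the vendor difference in between-scan SDs with a permutation test:
#' vendor labels are permuted across subjects, the statistic is
#' \eqn{|\hat\sigma_w(\mathrm{GE}) - \hat\sigma_w(\mathrm{Philips})|}, and
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (n_{perm} + 1)}.
#'
#' @param table A paired cohort data.frame with a `vendor` column holding
#'   exactly two levels, each with at least 2 subjects.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A list: `p_mean`, `p_sd`, `sd_by_vendor`, `mean_by_vendor`,
#'   `observed_sd_diff`.
#' @export
vendor_compare <- function(table, n_perm = 10000L, seed = NULL) {
  check_cohort(table)
  v <- as.character(table$vendor)
  lev <- unique(v)
  if (length(lev) != 2) stop("vendor comparison requires exactly 2 vendors")
  if (min(table(v)) < 2) stop("each vendor needs at least 2 subjects")

  subj_mean <- (table$y1 + table$y2) / 2
  tt <- stats::t.test(subj_mean[v == lev[1]], subj_mean[v == lev[2]],
                      var.equal = TRUE)
  d2h <- (table$y1 - table$y2)^2 / 2       # per-subject d_i^2 / 2
  sw <- function(g) sqrt(mean(d2h[g]))
  g1 <- v == lev[1]
  obs <- abs(sw(g1) - sw(!g1))
  n1 <- sum(g1)
  n <- length(v)

  with_seed(seed, {
    perm_stat <- vapply(seq_len(n_perm), function(b) {
      pg <- logical(n)
      pg[sample.int(n, n1)] <- TRUE
      abs(sw(pg) - sw(!pg))
    }, numeric(1))
    p_sd <- (1 + sum(perm_stat >= obs)) / (n_perm + 1)
    list(
      p_mean = tt$p.value,
      p_sd = p_sd,
      mean_by_vendor = stats::setNames(c(mean(subj_mean[g1]), mean(subj_mean[!g1])), lev),
      sd_by_vendor = stats::setNames(c(sw(g1), sw(!g1)), lev),
      observed_sd_diff = obs,
      n_perm = n_perm
    )
  })
}
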