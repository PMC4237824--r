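#' Fit a scan-rescan reproducibility model to a paired cohort
#'
#' The central model of the package: the random-intercept model
#' \eqn{y_{ij} = \mu + b_i + e_{ij}} fitted to a balanced two-scan cohort
#' (see [fit_variance_components()]), summarized by the between-scan SD,
#' the between-scan CV (\eqn{\sigma_w/\mu}) and the ICC
#' (\eqn{\sigma_b^2/(\sigma_b^2+\sigma_w^2)}), with subject-level
#' nonparametric bootstrap percentile confidence intervals, a paired
#' t-test of the scan means, and Bland-Altman agreement statistics.
#'
#' @param table A paired cohort data.frame with columns `subject_id`,
#'   `vendor`, `y1`, `y2` and optionally `area1`, `area2`.
#' @param B Bootstrap replicates for the confidence intervals.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @param parameter Optional label (e.g. `"ktrans"`) carried into output.
#'
#' @return An object of class `repro_fit` with components `components`
#'   (a `variance_components`), `cv`, `icc`, `ci` (list with `sd`, `cv`,
#'   `icc` intervals), `paired_t`, `bland_altman`, `n_subjects`, `table`,
#'   `parameter`, `call`. Methods: `print`, `summary`, `coef`, `confint`,
#'   `simulate`, `residuals`, `plot`.
#' @export
#' @examples
#' tab <- generate_measurement_cohort(
#'   cohort_spec(35, 0.062, cv = 0.25, icc = 0.65), seed = 7)
#' fit <- fit_reproducibility(tab, B = 500, seed = 1)
#' fit
#' coef(fit)
fit_reproducibility <- function(table, B = 2000L, conf = 0.95, seed = NULL,
                                parameter = NULL) {
  check_cohort(table)
  comp <- fit_variance_components(table)
  fit <- structure(list(
    components = comp,
    cv = cv_between_scan(comp),
    icc = icc(comp),
    ci = list(
      sd = bootstrap_ci(table, "sd", B = B, seed = seed, conf = conf),
      cv = bootstrap_ci(table, "cv", B = B,
                        seed = if (is.null(seed)) NULL else seed + 1L, conf = conf),
      icc = bootstrap_ci(table, "icc", B = B,
                         seed = if (is.null(seed)) NULL else seed + 2L, conf = conf)
    ),
    paired_t = paired_t_test(table),
    bland_altman = bland_altman(table),
    n_subjects = comp$n_subjects,
    conf = conf,
    table = table,
    parameter = parameter,
    call = match.call()
  ), class = "repro_fit")
  fit
}

#' @export
print.repro_fit <- function(x, ...) {
  lab <- if (is.null(x$parameter)) "" else paste0(" [", x$parameter, "]")
  cat(sprintf("Scan-rescan reproducibility fit%s (n = %d subjects)\n", lab, x$n_subjects))
  cat(sprintf("  grand mean      %.4g\n", x$components$grand_mean))
  cat(sprintf("  between-scan SD %.4g  (%.0f%% CI %.4g-%.4g)\n",
              x$components$sigma_w, 100 * x$conf, x$ci$sd[1], x$ci$sd[2]))
  cat(sprintf("  between-scan CV %.1f%%  (%.0f%% CI %.1f%%-%.1f%%)\n",
              100 * x$cv, 100 * x$conf, 100 * x$ci$cv[1], 100 * x$ci$cv[2]))
  cat(sprintf("  ICC             %.2f  (%.0f%% CI %.2f-%.2f)\n",
              x$icc, 100 * x$conf, x$ci$icc[1], x$ci$icc[2]))
  invisible(x)
}

#' @export
summary.repro_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.repro_fit")
}

#' @export
print.summary.repro_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  scan means      %.4g vs %.4g (paired t = %.3g, p = %.2g)\n",
              f$paired_t$mean1, f$paired_t$mean2, f$paired_t$t, f$paired_t$p))
  cat(sprintf("  Bland-Altman    mean diff %.4g, LoA [%.4g, %.4g]\n",
              f$bland_altman$mean_diff, f$bland_altman$loa_low, f$bland_altman$loa_high))
  if (f$components$truncated)
    cat("  note: between-subject variance truncated at 0\n")
  invisible(x)
}

#' @export
coef.repro_fit <- function(object, ...) {
  c(grand_mean = object$components$grand_mean,
    sigma_b = object$components$sigma_b,
    sigma_w = object$components$sigma_w)
}

#' @export
confint.repro_fit <- function(object, parm = c("sd", "cv", "icc"), ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  out <- t(vapply(parm, function(p) as.numeric(object$ci[[p]]), numeric(2)))
  colnames(out) <- sprintf("%g %%", 100 * c((1 - object$conf) / 2,
                                            1 - (1 - object$conf) / 2))
  out
}

#' @export
residuals.repro_fit <- function(object, ...) {
  # Within-subject residuals about the subject means.
  d <- (object$table$y1 - object$table$y2) / 2
  cbind(scan1 = d, scan2 = -d)
}

#' Simulate new cohorts from a fitted reproducibility model
#'
#' Draws `nsim` paired cohorts from the random-intercept model at the
#' fitted variance components, preserving the observed vendor labels.
#'
#' @param object A `repro_fit`.
#' @param nsim Number of cohorts.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of cohort data.frames (length `nsim`), or a single
#'   data.frame when `nsim = 1`.
#' @export
simulate.repro_fit <- function(object, nsim = 1, seed = NULL, ...) {
  comp <- object$components
  spec <- cohort_spec(
    n_subjects = object$n_subjects,
    grand_mean = comp$grand_mean,
    between_scan_sd = comp$sigma_w,
    between_subject_sd = comp$sigma_b,
    vendor_split = table(object$table$vendor)
  )
  sims <- with_seed(seed, lapply(seq_len(nsim), function(i)
    generate_measurement_cohort(spec, vendor = object$table$vendor,
                                subject_id = object$table$subject_id)))
  if (nsim == 1) sims[[1]] else sims
}

#' @export
plot.repro_fit <- function(x, ...) {
  plot(x$bland_altman,
       main = if (is.null(x$parameter)) "Bland-Altman" else
         paste("Bland-Altman:", x$parameter), ...)
  invisible(x)
}
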