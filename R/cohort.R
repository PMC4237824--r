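#' Specification of a simulated scan-rescan measurement cohort
#'
#' Describes the variance structure of a paired (two-scan) cohort under the
#' random-intercept model \eqn{y_{ij} = \mu + b_i + e_{ij}} with
#' \eqn{b_i \sim N(0, \sigma_b^2)} (between-subject) and
#' \eqn{e_{ij} \sim N(0, \sigma_w^2)} (between-scan). The variance
#' components may be given directly or through the derived quantities
#' CV \eqn{= \sigma_w/\mu} and ICC
#' \eqn{= \sigma_b^2/(\sigma_b^2 + \sigma_w^2)}.
#' Plaque areas are lognormal per subject with a small between-scan jitter.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param grand_mean Population mean of the measurement, parameter units.
#' @param between_scan_sd,between_subject_sd Variance components
#'   \eqn{\sigma_w > 0}, \eqn{\sigma_b \ge 0}; alternatively supply `cv`
#'   and `icc`.
#' @param cv,icc Target between-scan CV (fraction) and ICC, used to derive
#'   the SDs when those are not given.
#' @param vendor_split Named integer vector of subjects per vendor; must
#'   sum to `n_subjects`.
#' @param area_log_mean,area_log_sd Lognormal parameters for per-subject
#'   plaque areas, mm^2 on the log scale.
#' @param area_scan_jitter Lognormal SD of the per-scan area perturbation.
#'
#' @return A `cohort_spec` list.
#' @export
#' @examples
#' sp <- cohort_spec(35, grand_mean = 0.062, cv = 0.25, icc = 0.65)
#' sp$between_scan_sd
cohort_spec <- function(n_subjects = 35L,
                        grand_mean = 0.062,
                        between_scan_sd = NULL,
                        between_subject_sd = NULL,
                        cv = NULL, icc = NULL,
                        vendor_split = c(GE = 20L, Philips = 15L),
                        area_log_mean = log(27),
                        area_log_sd = 0.7,
                        area_scan_jitter = 0.1) {
  if (n_subjects < 2) stop("'n_subjects' must be >= 2")
  if (is.null(between_scan_sd)) {
    if (is.null(cv)) stop("supply 'between_scan_sd' or 'cv'")
    if (cv < 0) stop("'cv' must be >= 0")
    between_scan_sd <- cv * grand_mean
  }
  if (is.null(between_subject_sd)) {
    if (is.null(icc)) stop("supply 'between_subject_sd' or 'icc'")
    if (icc < 0 || icc >= 1) stop("'icc' must be in [0, 1)")
    if (between_scan_sd == 0) stop("icc-based spec requires between_scan_sd > 0")
    between_subject_sd <- between_scan_sd * sqrt(icc / (1 - icc))
  }
  if (between_scan_sd < 0) stop("between-scan SD must be >= 0")
  if (between_subject_sd < 0) stop("between-subject SD must be >= 0")
  if (grand_mean <= 0) stop("'grand_mean' must be > 0")
  vendor_split <- as.integer(round(vendor_split))
  names(vendor_split) <- names(vendor_split) %||% c("GE", "Philips")[seq_along(vendor_split)]
  if (sum(vendor_split) != n_subjects)
    stop("'vendor_split' must sum to n_subjects")
  structure(list(
    n_subjects = as.integer(n_subjects),
    grand_mean = grand_mean,
    between_scan_sd = between_scan_sd,
    between_subject_sd = between_subject_sd,
    vendor_split = vendor_split,
    area_log_mean = area_log_mean,
    area_log_sd = area_log_sd,
    area_scan_jitter = area_scan_jitter
  ), class = "cohort_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a paired scan-rescan measurement cohort
#'
#' Draws one measurement table from the random-intercept model described in
#' [cohort_spec()]: per-subject intercepts and per-scan errors are Gaussian,
#' plaque areas are lognormal with small between-scan jitter, and vendors
#' are assigned per the split. Reproducible under `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; `NULL` uses the current RNG.
#' @param vendor Optional explicit per-subject vendor vector (overrides the
#'   split; length `n_subjects`).
#' @param subject_id Optional subject identifiers.
#'
#' @return A data.frame with one row per subject and columns `subject_id`,
#'   `vendor`, `y1`, `y2`, `area1`, `area2` (mm^2).
#' @export
#' @examples
#' tab <- generate_measurement_cohort(cohort_spec(35, 0.062, cv = 0.25, icc = 0.65), seed = 1)
#' head(tab)
generate_measurement_cohort <- function(spec, seed = NULL, vendor = NULL,
                                        subject_id = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  if (is.null(vendor)) {
    vendor <- rep(names(spec$vendor_split), times = spec$vendor_split)
  }
  if (length(vendor) != n) stop("vendor vector length must equal n_subjects")
  if (is.null(subject_id)) subject_id <- sprintf("S%02d", seq_len(n))

  with_seed(seed, {
    b <- stats::rnorm(n, 0, spec$between_subject_sd)
    e <- matrix(stats::rnorm(2 * n, 0, spec$between_scan_sd), n, 2)
    y <- spec$grand_mean + b + e
    area_subj <- stats::rlnorm(n, spec$area_log_mean, spec$area_log_sd)
    jit <- matrix(stats::rlnorm(2 * n, 0, spec$area_scan_jitter), n, 2)
    data.frame(
      subject_id = subject_id,
      vendor = vendor,
      y1 = y[, 1],
      y2 = y[, 2],
      area1 = area_subj * jit[, 1],
      area2 = area_subj * jit[, 2],
      stringsAsFactors = FALSE
    )
  })
}

# Validate a paired cohort table: one row per subject, both scans present.
check_cohort <- function(table) {
  req <- c("subject_id", "vendor", "y1", "y2")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(table$subject_id))
    stop("cohort table must have one row per subject")
  if (any(!is.finite(table$y1)) || any(!is.finite(table$y2)))
    stop("cohort table has non-finite measurements (complete cases required)")
  invisible(table)
}
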