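# Shared fixtures, built in code at test time.

ge_protocol <- function(...) acq_protocol("GE", ...)

# Small phantom that keeps image tests fast; geometry fits a 16 px grid.
small_phantom <- function(protocol = ge_protocol(), grid_size = 16L,
                          lumen_radius = 1.5, wall_thickness = 1.0,
                          plaque_bulge = 0.8, ...) {
  build_phantom(protocol, lumen_radius = lumen_radius,
                wall_thickness = wall_thickness, plaque_bulge = plaque_bulge,
                grid_size = grid_size, ...)
}

# Default study-condition cohort spec (carotid Ktrans magnitudes); vendor
# split keeps the 20:15 GE:Philips proportion.
ktrans_spec <- function(n = 35L) {
  n_ge <- as.integer(ceiling(n * 4 / 7))
  cohort_spec(n, grand_mean = 0.062, cv = 0.25, icc = 0.65,
              vendor_split = c(GE = n_ge, Philips = n - n_ge))
}

# Hand-rolled cohort table for exact-arithmetic fixtures.
fixture_table <- function(y1, y2, vendor = "GE", area1 = 30, area2 = 30) {
  data.frame(subject_id = sprintf("S%02d", seq_along(y1)),
             vendor = rep_len(vendor, length(y1)),
             y1 = y1, y2 = y2,
             area1 = rep_len(area1, length(y1)),
             area2 = rep_len(area2, length(y1)),
             stringsAsFactors = FALSE)
}

# Brute-force REML for the balanced two-scan random-intercept model:
# generic 2-parameter optimization of the REML objective expressed through
# the per-subject mean/difference decomposition (means ~ N(mu, sb2 + sw2/2),
# differences ~ N(0, 2 sw2); REML drops mu via the usual adjustment).
brute_force_reml <- function(y1, y2) {
  n <- length(y1)
  m <- (y1 + y2) / 2
  ssm <- sum((m - mean(m))^2)
  ssd <- sum((y1 - y2)^2)
  crit <- function(par) {
    sb2 <- exp(par[1]); sw2 <- exp(par[2])
    v1 <- sb2 + sw2 / 2
    n * log(sw2) + ssd / (2 * sw2) +
      (n - 1) * log(v1) + ssm / v1
  }
  s2 <- stats::var(c(y1, y2))
  fit <- stats::nlminb(log(c(s2 / 2 + 1e-8, s2 / 2 + 1e-8)), crit,
                       control = list(rel.tol = 1e-14, eval.max = 2000,
                                      iter.max = 1000))
  # polish: Nelder-Mead from the nlminb optimum to tighten the stationary point
  fit2 <- stats::optim(fit$par, crit, method = "Nelder-Mead",
                       control = list(reltol = 1e-16, maxit = 5000))
  par <- if (fit2$value <= fit$objective) fit2$par else fit$par
  list(sigma_b = sqrt(exp(par[1])), sigma_w = sqrt(exp(par[2])))
}
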