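test_that("variance components match the hand-worked ANOVA fixture", {
  tab <- fixture_table(y1 = c(1, 2, 4), y2 = c(3, 2, 6))
  vc <- fit_variance_components(tab)
  expect_equal(vc$msw, 4 / 3)
  expect_equal(vc$sigma_w, sqrt(4 / 3))
  expect_equal(vc$grand_mean, 3)
  # subject means (2, 2, 5): MSB = 2 * var = 6; sb2 = (6 - 4/3)/2
  expect_equal(vc$msb, 6)
  expect_equal(vc$sigma_b, sqrt((6 - 4 / 3) / 2))
  expect_false(vc$truncated)
})

test_that("pure subject effect gives sigma_w = 0 and ICC 1; constant data gives ICC 0", {
  pure <- fixture_table(y1 = c(1, 5, 9, 2), y2 = c(1, 5, 9, 2))
  vc <- fit_variance_components(pure)
  expect_equal(vc$sigma_w, 0)
  expect_equal(icc(vc), 1)

  flat <- fixture_table(y1 = rep(3, 4), y2 = rep(3, 4))
  vcf <- fit_variance_components(flat)
  expect_equal(vcf$sigma_b, 0)
  expect_equal(vcf$sigma_w, 0)
  expect_equal(as.numeric(icc(vcf)), 0)
  expect_true(isTRUE(attr(icc(vcf), "degenerate")))
})

test_that("the ANOVA estimator agrees with REML (lme4 cross-check)", {
  skip_if_not_installed("lme4")
  tab <- generate_measurement_cohort(ktrans_spec(), seed = 31)
  vc <- fit_variance_components(tab)
  long <- data.frame(y = c(tab$y1, tab$y2),
                     subject = rep(tab$subject_id, 2))
  fit <- lme4::lmer(y ~ 1 + (1 | subject), data = long, REML = TRUE)
  vcs <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(vc$sigma_b, vcs$sdcor[vcs$grp == "subject"], tolerance = 1e-6)
  expect_equal(vc$sigma_w, vcs$sdcor[vcs$grp == "Residual"], tolerance = 1e-6)
})

test_that("CV and ICC follow their definitions and scale invariance", {
  comp <- structure(list(grand_mean = 0.062, sigma_b = 0.0155, sigma_w = 0.0155,
                         msb = NA, msw = NA, n_subjects = 35L, truncated = FALSE),
                    class = "variance_components")
  expect_equal(cv_between_scan(comp), 0.25)
  expect_equal(icc(comp), 0.5)

  tab <- generate_measurement_cohort(ktrans_spec(), seed = 5)
  vc1 <- fit_variance_components(tab)
  tab2 <- tab; tab2$y1 <- 10 * tab$y1; tab2$y2 <- 10 * tab$y2
  vc2 <- fit_variance_components(tab2)
  expect_equal(cv_between_scan(vc2), cv_between_scan(vc1), tolerance = 1e-12)
  expect_equal(icc(vc2), icc(vc1), tolerance = 1e-12)

  bad <- comp; bad$grand_mean <- -1
  expect_error(cv_between_scan(bad), "grand mean")
})

test_that("paired t-test matches hand computation and handles degenerate input", {
  same <- fixture_table(y1 = c(1, 2, 3), y2 = c(1, 2, 3))
  res <- paired_t_test(same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_true(res$degenerate)

  tab <- fixture_table(y1 = c(2, 4, 6), y2 = c(1, 2, 3))  # d = (1, 2, 3)
  r <- paired_t_test(tab)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$p, 2 * stats::pt(-abs(r$t), df = 2), tolerance = 1e-12)

  set.seed(1)
  shift <- fixture_table(y1 = 1:10 + 0.5, y2 = (1:10) * 1.0)
  shift$y2 <- shift$y1 - 0.5 + rnorm(10, 0, 1e-3)
  rs <- paired_t_test(shift)
  expect_gt(rs$t, 0)
  expect_lt(rs$p, 1e-6)
})

test_that("per-subject SD is the two-point sample SD and is homogeneous", {
  tab <- fixture_table(y1 = c(5, 1), y2 = c(5, 3))
  expect_equal(per_subject_sd(tab), c(0, 2 / sqrt(2)))
  tab3 <- tab; tab3$y1 <- -3 * tab$y1; tab3$y2 <- -3 * tab$y2
  expect_equal(per_subject_sd(tab3), 3 * per_subject_sd(tab))
})

test_that("Spearman correlation handles monotone, reversed and tied data", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_test(x, x^3)$rho, 1)
  expect_equal(spearman_test(x, -x)$rho, -1)
  expect_equal(spearman_test(x, rev(x))$p, 0)

  # tie fixture: hand-assigned average ranks
  xt <- c(1, 2, 3, 4, 5)
  yt <- c(10, 20, 20, 40, 50)
  rx <- 1:5
  ry <- c(1, 2.5, 2.5, 4, 5)
  rho_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  st <- spearman_test(xt, yt)
  expect_equal(st$rho, rho_hand, tolerance = 1e-12)
  t_hand <- rho_hand * sqrt(3 / (1 - rho_hand^2))
  expect_equal(st$p, 2 * stats::pt(-abs(t_hand), 3), tolerance = 1e-12)

  expect_error(spearman_test(rep(1, 6), x), "constant")
})

test_that("Bland-Altman limits use the 2-SD convention and translate correctly", {
  tab <- fixture_table(y1 = c(1, 1, 1), y2 = c(0, 1, 2))  # d = (-1, 0, 1)
  ba <- bland_altman(tab)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_low, -2)
  expect_equal(ba$loa_high, 2)

  tab2 <- tab; tab2$y2 <- tab$y2 + 0.7
  ba2 <- bland_altman(tab2)
  expect_equal(ba2$mean_diff, ba$mean_diff + 0.7)
  expect_equal(ba2$loa_high - ba2$loa_low, ba$loa_high - ba$loa_low)

  zero <- fixture_table(y1 = c(2, 3, 4), y2 = c(2, 3, 4))
  baz <- bland_altman(zero)
  expect_equal(c(baz$loa_low, baz$loa_high), c(0, 0))
})

test_that("area subgroup filter uses the smaller of the two scans", {
  tab <- fixture_table(y1 = 1:3, y2 = 1:3)
  tab$area1 <- c(26, 24, 30)
  tab$area2 <- c(30, 40, 10)
  kept <- subgroup_by_area(tab, 25)
  expect_equal(kept$subject_id, "S01")
  expect_equal(nrow(subgroup_by_area(tab, 0)), 3L)
})

test_that("bootstrap intervals are seed-deterministic, ordered and cover the estimate", {
  tab <- generate_measurement_cohort(ktrans_spec(), seed = 13)
  ci_a <- bootstrap_ci(tab, "cv", B = 500, seed = 3)
  ci_b <- bootstrap_ci(tab, "cv", B = 500, seed = 3)
  expect_identical(ci_a, ci_b)
  vc <- fit_variance_components(tab)
  expect_lte(ci_a[1], cv_between_scan(vc))
  expect_gte(ci_a[2], cv_between_scan(vc))
  # narrower nominal level nests inside the wider one
  ci90 <- bootstrap_ci(tab, "cv", B = 500, seed = 3, conf = 0.90)
  expect_gte(ci90[1], ci_a[1] - 1e-12)
  expect_lte(ci90[2], ci_a[2] + 1e-12)
  # degenerate table: all equal -> [0, 0] for the SD
  flat <- fixture_table(y1 = rep(2, 6), y2 = rep(2, 6))
  expect_equal(as.numeric(bootstrap_ci(flat, "sd", B = 200, seed = 1)), c(0, 0))
})

test_that("vendor comparison degenerates correctly and bounds its p-values", {
  tab <- generate_measurement_cohort(ktrans_spec(20), seed = 17)
  res <- vendor_compare(tab, n_perm = 499, seed = 2)
  expect_gte(res$p_sd, 1 / 500)
  expect_lte(res$p_sd, 1)
  expect_identical(res$p_sd, vendor_compare(tab, n_perm = 499, seed = 2)$p_sd)

  # mirrored table: identical values in both vendors -> observed diff 0, p 1
  half <- generate_measurement_cohort(
    cohort_spec(10, 0.062, cv = 0.25, icc = 0.65,
                vendor_split = c(GE = 10)), seed = 3)
  mirror <- rbind(half, transform(half, vendor = "Philips",
                                  subject_id = paste0(subject_id, "b")))
  resm <- vendor_compare(mirror, n_perm = 199, seed = 1)
  expect_equal(resm$observed_sd_diff, 0)
  expect_equal(resm$p_sd, 1)

  one <- half
  expect_error(vendor_compare(one, n_perm = 99), "2 vendors")
  tiny <- rbind(half[1:5, ], transform(half[6, ], vendor = "Philips"))
  expect_error(vendor_compare(tiny, n_perm = 99), "at least 2 subjects")
})

test_that("the repro_fit object exposes the standard modelling methods", {
  tab <- generate_measurement_cohort(ktrans_spec(), seed = 23)
  fit <- fit_reproducibility(tab, B = 300, seed = 1, parameter = "ktrans")
  expect_s3_class(fit, "repro_fit")
  expect_named(coef(fit), c("grand_mean", "sigma_b", "sigma_w"))
  ci <- confint(fit)
  expect_equal(dim(ci), c(3L, 2L))
  expect_true(all(ci[, 1] <= ci[, 2]))
  expect_output(print(fit), "between-scan CV")
  expect_output(print(summary(fit)), "Bland-Altman")
  res <- residuals(fit)
  expect_equal(rowSums(res), rep(0, nrow(tab)))
  sim <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sim, 2L)
  expect_equal(sim[[1]]$vendor, tab$vendor)
  expect_false(identical(sim[[1]]$y1, sim[[2]]$y1))
})
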