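circle_poly <- function(cx, cy, r, n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

test_that("concentric-circle wall mask with 1 mm exclusion matches the analytic area", {
  px <- 0.625
  n <- 32L
  # generic center: the grid symmetry point is a degenerate alignment where
  # both the 4 and 5 mm radii graze whole rings of pixel centers at once
  c0 <- n * px / 2 + c(0.2, 0.1)
  lumen <- circle_poly(c0[1], c0[2], 3)
  outer <- circle_poly(c0[1], c0[2], 5)
  m <- wall_mask_with_exclusion(lumen, outer, dim = c(n, n), pixel_size = px,
                                exclusion_mm = 1)
  expect_equal(sum(m) * px^2, pi * (5^2 - 4^2), tolerance = 0.05)
})

test_that("zero exclusion retains the full wall annulus", {
  px <- 0.625
  n <- 32L
  c0 <- n * px / 2 + c(0.2, 0.1)
  lumen <- circle_poly(c0[1], c0[2], 3)
  outer <- circle_poly(c0[1], c0[2], 5)
  m0 <- wall_mask_with_exclusion(lumen, outer, dim = c(n, n), pixel_size = px,
                                 exclusion_mm = 0)
  expect_equal(sum(m0) * px^2, pi * (5^2 - 3^2), tolerance = 0.05)
})

test_that("increasing the exclusion ring never adds pixels", {
  px <- 0.625
  n <- 32L
  c0 <- n * px / 2
  lumen <- circle_poly(c0, c0, 3)
  outer <- circle_poly(c0, c0, 5)
  prev <- NULL
  for (ex in c(0, 0.5, 1, 1.5, 2.5)) {
    m <- wall_mask_with_exclusion(lumen, outer, dim = c(n, n), pixel_size = px,
                                  exclusion_mm = ex)
    if (!is.null(prev)) expect_true(all(m <= prev))
    prev <- m
  }
})

test_that("a wall thinner than the exclusion gives an empty mask and a missing measurement", {
  px <- 0.625
  n <- 32L
  c0 <- n * px / 2
  lumen <- circle_poly(c0, c0, 3)
  outer <- circle_poly(c0, c0, 3.6)   # 0.6 mm wall < 1 mm exclusion
  m <- wall_mask_with_exclusion(lumen, outer, dim = c(n, n), pixel_size = px)
  expect_equal(sum(m), 0L)
  map <- structure(list(ktrans = matrix(0.05, n, n), vp = matrix(0.05, n, n),
                        fit_residual = matrix(0, n, n),
                        valid_mask = matrix(TRUE, n, n), pixel_size = px),
                   class = "kinetic_map")
  meas <- measure_plaque(map, m)
  expect_true(meas$missing)
  expect_true(is.na(meas$mean_ktrans))
})

test_that("crossing contours are rejected", {
  px <- 0.625
  n <- 32L
  c0 <- n * px / 2
  lumen <- circle_poly(c0, c0, 5)
  outer <- circle_poly(c0 + 4, c0, 5)
  expect_error(wall_mask_with_exclusion(lumen, outer, dim = c(n, n),
                                        pixel_size = px), "cross")
})

test_that("plaque means and areas follow the arithmetic contract", {
  n <- 16L
  px <- 0.625
  mk_map <- function(kt, vp) structure(list(
    ktrans = kt, vp = vp, fit_residual = matrix(0, n, n),
    valid_mask = matrix(TRUE, n, n), pixel_size = px), class = "kinetic_map")

  uni <- mk_map(matrix(0.05, n, n), matrix(0.1, n, n))
  mask64 <- matrix(FALSE, n, n); mask64[1:8, 1:8] <- TRUE
  meas <- measure_plaque(uni, mask64)
  expect_identical(meas$mean_ktrans, 0.05)
  expect_identical(meas$analyzed_area, 64 * 0.625^2)  # 25.0 mm^2
  expect_identical(meas$analyzed_area, 25.0)

  half <- matrix(0.02, n, n); half[1:8, ] <- 0.10
  mh <- measure_plaque(mk_map(half, half), matrix(TRUE, n, n))
  expect_equal(mh$mean_ktrans, 0.06)
})

test_that("inclusion threshold is a strict inequality", {
  meas <- data.frame(subject_id = c("a", "b", "c"),
                     max_wall_thickness = c(1.0, 1.1, 0.5))
  kept <- apply_inclusion(meas, 1.0)
  expect_equal(kept$subject_id, "b")
  expect_equal(nrow(apply_inclusion(meas[0, ], 1.0)), 0L)
})
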