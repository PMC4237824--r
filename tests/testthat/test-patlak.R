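test_that("zero concentration yields zero kinetic estimates", {
  pr <- ge_protocol()
  ph <- small_phantom(ktrans_wall = 0, vp_wall = 0)
  aif <- generate_aif(pr)
  ser <- simulate_series(ph, aif, pr, seed = 1)
  conc <- signal_to_concentration(ser, t10 = ph$t10)
  map <- patlak_fit(conc, aif)
  w <- ph$wall_mask
  expect_lt(max(abs(map$ktrans[w])), 1e-10)
  expect_lt(max(abs(map$vp[w])), 1e-10)
})

test_that("noise-free phantom kinetics are recovered exactly", {
  pr <- ge_protocol()
  ph <- small_phantom(ktrans_wall = 0.062, vp_wall = 0.067)
  aif <- generate_aif(pr)
  ser <- simulate_series(ph, aif, pr, seed = 1)
  conc <- signal_to_concentration(ser, t10 = ph$t10)
  map <- patlak_fit(conc, aif)
  w <- ph$wall_mask
  expect_lt(max(abs(map$ktrans[w] - 0.062)) / 0.062, 1e-8)
  expect_lt(max(abs(map$vp[w] - 0.067)) / 0.067, 1e-8)
  expect_lt(max(map$fit_residual[w]), 1e-10)
})

test_that("a pure plasma-volume curve fits with zero transfer constant", {
  pr <- ge_protocol()
  aif <- generate_aif(pr)
  nf <- pr$n_frames
  v <- 0.15
  conc_mat <- matrix(rep(v * aif$cp, each = 16), 16, nf)
  conc <- structure(list(
    conc = array(rep(conc_mat, 1), dim = c(1L, 4L, 4L, nf)),
    baseline_frames = 1:2,
    frame_times = aif$times,
    protocol = pr,
    pixel_size = pr$pixel_size,
    valid_mask = array(TRUE, dim = c(1L, 4L, 4L))
  ), class = "conc_series")
  map <- patlak_fit(conc, aif)
  expect_lt(max(abs(map$vp - v)), 1e-10)
  expect_lt(max(abs(map$ktrans)), 1e-10)
})

test_that("the shared-design OLS equals brute-force normal equations per pixel", {
  pr <- ge_protocol()
  ph <- small_phantom(grid_size = 16L)
  aif <- generate_aif(pr)
  ser <- simulate_series(ph, aif, pr, noise_sd = 3, seed = 11)
  conc <- signal_to_concentration(ser, t10 = ph$t10)
  map <- patlak_fit(conc, aif)

  X <- cbind(dcerepro:::cumtrapz(aif$times, aif$cp) / 60, aif$cp)
  xtx <- crossprod(X)
  det_x <- xtx[1, 1] * xtx[2, 2] - xtx[1, 2]^2
  for (i in seq_len(16)) {
    for (j in seq_len(16)) {
      if (!map$valid_mask[i, j]) next
      y <- conc$conc[1, i, j, ]
      xty <- crossprod(X, y)
      k_hat <- (xtx[2, 2] * xty[1] - xtx[1, 2] * xty[2]) / det_x  # Cramer
      v_hat <- (xtx[1, 1] * xty[2] - xtx[1, 2] * xty[1]) / det_x
      expect_equal(map$ktrans[i, j], as.numeric(k_hat), tolerance = 1e-10)
      expect_equal(map$vp[i, j], as.numeric(v_hat), tolerance = 1e-10)
    }
  }
})

test_that("a singular design flags all pixels invalid", {
  pr <- ge_protocol()
  ph <- small_phantom()
  aif <- generate_aif(pr)
  ser <- simulate_series(ph, aif, pr, seed = 1)
  conc <- signal_to_concentration(ser, t10 = ph$t10)
  zero_aif <- structure(list(times = aif$times, cp = rep(0, length(aif$cp))),
                        class = "aif_curve")
  expect_error(patlak_fit(conc, zero_aif), "non-zero AIF")
})

test_that("V-V rendering clamps to the display ranges and is idempotent", {
  map <- structure(list(
    ktrans = matrix(c(0.2, 0, 0.4, 0.1), 2, 2),
    vp = matrix(c(0, 0, 0.5, 2), 2, 2),
    fit_residual = matrix(0, 2, 2),
    valid_mask = matrix(TRUE, 2, 2),
    pixel_size = 0.625
  ), class = "kinetic_map")
  img <- render_vv_image(map)
  # Ktrans 0.2, vp 0 -> saturated green
  expect_equal(img[1, 1, ], c(0, 1, 0))
  # zero map -> black
  expect_equal(img[2, 1, ], c(0, 0, 0))
  # clamping above range
  expect_equal(img[1, 2, ], c(0.5, 1, 0))
  expect_equal(img[2, 2, 1], 1)
  # idempotent on already-clamped inputs: re-rendering from clamped values
  map2 <- map
  map2$ktrans <- pmin(map$ktrans, 0.2)
  map2$vp <- pmin(map$vp, 1)
  img2 <- render_vv_image(map2)
  expect_equal(img2, img)
  # single-channel display
  expect_true(all(render_vv_image(map, channel = "ktrans")[, , 1] == 0))
  expect_true(all(render_vv_image(map, channel = "vp")[, , 2] == 0))
})
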