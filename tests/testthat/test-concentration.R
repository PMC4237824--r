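test_that("a baseline-only series maps to zero concentration", {
  pr <- ge_protocol()
  ph <- small_phantom(ktrans_wall = 0, vp_wall = 0)
  # no enhancement anywhere outside the lumen; check wall pixels
  ser <- simulate_series(ph, generate_aif(pr), pr, seed = 1)
  conc <- signal_to_concentration(ser, t10 = ph$t10)
  w <- which(ph$wall_mask)
  for (f in c(1, 9, 18)) {
    expect_lt(max(abs(conc$conc[1, , , f][w])), 1e-8)
  }
})

test_that("forward-inverse concentration round trip is exact at noise zero", {
  pr <- ge_protocol()
  ph <- small_phantom()
  aif <- generate_aif(pr)
  ser <- simulate_series(ph, aif, pr, seed = 1)
  conc <- signal_to_concentration(ser, t10 = ph$t10)
  cum_min <- dcerepro:::cumtrapz(aif$times, aif$cp) / 60
  truth <- outer(as.vector(ph$ktrans_true), cum_min) +
    outer(as.vector(ph$vp_true), aif$cp)
  est <- matrix(conc$conc[1, , , ], ncol = pr$n_frames)
  expect_lt(max(abs(est - truth)), 1e-6)
})

test_that("doubling the relaxivity halves the estimated concentration", {
  pr <- ge_protocol()
  ph <- small_phantom()
  ser <- simulate_series(ph, generate_aif(pr), pr, seed = 1)
  c1 <- signal_to_concentration(ser, t10 = ph$t10, r1 = 4.5)
  c2 <- signal_to_concentration(ser, t10 = ph$t10, r1 = 9.0)
  expect_equal(c2$conc, c1$conc / 2, tolerance = 1e-10)
})

test_that("signals outside the invertible SPGR range are flagged, not extrapolated", {
  pr <- ge_protocol()
  ph <- small_phantom(ktrans_wall = 0, vp_wall = 0)
  ser <- simulate_series(ph, generate_aif(pr), pr, seed = 1)
  # push one pixel's late frames above the SPGR ceiling
  ser$data[1, 8, 8, 10:18] <- ser$data[1, 8, 8, 1] * 50
  conc <- signal_to_concentration(ser, t10 = ph$t10)
  expect_true(any(is.na(conc$conc[1, 8, 8, ])))
  expect_false(conc$valid_mask[1, 8, 8])
})

test_that("AIF extraction recovers the generating curve on a clean phantom", {
  pr <- ge_protocol()
  ph <- small_phantom(grid_size = 24L, lumen_radius = 2.2, wall_thickness = 1,
                      plaque_bulge = 0.5)
  aif <- generate_aif(pr)
  ser <- simulate_series(ph, aif, pr, seed = 1)
  conc <- signal_to_concentration(ser, t10 = ph$t10)
  rec <- extract_aif(conc, ph$lumen_contour, hematocrit = 0)
  post <- aif$cp > 0
  expect_lt(max(abs(rec$cp[post] - aif$cp[post]) / aif$cp[post]), 0.02)
  expect_equal(rec$cp[1:2], c(0, 0), tolerance = 1e-9)
})

test_that("hematocrit scales plasma concentration as 1/(1-Hct)", {
  pr <- ge_protocol()
  ph <- small_phantom(grid_size = 24L, lumen_radius = 2.2, wall_thickness = 1,
                      plaque_bulge = 0.5)
  ser <- simulate_series(ph, generate_aif(pr), pr, seed = 1)
  conc <- signal_to_concentration(ser, t10 = ph$t10)
  a0 <- extract_aif(conc, ph$lumen_contour, hematocrit = 0)
  a42 <- extract_aif(conc, ph$lumen_contour, hematocrit = 0.42)
  expect_equal(a42$cp, a0$cp / (1 - 0.42), tolerance = 1e-12)
})

test_that("a flat lumen yields a zero AIF and an empty ROI errors", {
  pr <- ge_protocol()
  ph <- small_phantom(grid_size = 24L, lumen_radius = 2.2, wall_thickness = 1,
                      plaque_bulge = 0.5, ktrans_wall = 0, vp_wall = 0)
  ser <- simulate_series(ph, generate_aif(pr), pr, seed = 1)
  # overwrite the lumen with its baseline value -> no enhancement at all
  base <- ser$data[1, , , 1]
  for (f in 2:pr$n_frames) ser$data[1, , , f] <- base
  conc <- signal_to_concentration(ser, t10 = ph$t10)
  flat <- extract_aif(conc, ph$lumen_contour, hematocrit = 0)
  expect_lt(max(abs(flat$cp)), 1e-10)

  far <- cbind(c(0.1, 0.2, 0.2, 0.1), c(0.1, 0.1, 0.2, 0.2))
  expect_error(extract_aif(conc, far, hematocrit = 0), "empty")
})
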