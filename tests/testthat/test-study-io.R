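small_config <- function(seed = 1L) {
  study_config(seed = seed, bootstrap_B = 300L, n_perm = 300L)
}

test_that("the study pipeline reproduces the exclusion cascade and is deterministic", {
  rep1 <- suppressMessages(run_study(small_config()))
  expect_equal(unname(rep1$cascade), c(51L, 10L, 6L, 35L))
  expect_equal(rep1$cascade[["enrolled"]],
               rep1$cascade[["protocol_excluded"]] +
                 rep1$cascade[["quality_excluded"]] + rep1$cascade[["analyzed"]])
  rep2 <- suppressMessages(run_study(small_config()))
  expect_equal(rep1$fits$ktrans$cv, rep2$fits$ktrans$cv)
  expect_equal(rep1$power_table, rep2$power_table)
  expect_identical(rep1$cohorts, rep2$cohorts)

  # estimated statistics live near the generating study conditions
  expect_lt(abs(rep1$fits$ktrans$cv - 0.25), 0.10)
  expect_lt(abs(rep1$fits$vp$cv - 0.62), 0.25)
  expect_output(print(rep1), "analyzed 35")
})

test_that("cohort CSV round trip is lossless and schema violations are named", {
  tab <- generate_measurement_cohort(ktrans_spec(), seed = 2)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(tab, path)
  back <- read_cohort_csv(path)
  expect_equal(back, tab)

  bad <- tab; bad$vendor <- NULL
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_cohort_csv(path2), "vendor")
})

test_that("NIfTI series round trip preserves data and metadata", {
  pr <- ge_protocol()
  ph <- small_phantom()
  ser <- simulate_series(ph, generate_aif(pr), pr, noise_sd = 1, seed = 5)
  path <- tempfile(fileext = ".nii.gz")
  write_series(ser, path)
  back <- read_series(path)
  expect_equal(back$data, ser$data, tolerance = 1e-6)   # float32 storage
  expect_equal(back$frame_times, ser$frame_times)
  expect_equal(back$protocol$tr, pr$tr)
  expect_equal(back$protocol$vendor, "GE")
})

test_that("contour and roster CSV round trips preserve structure", {
  ph <- small_phantom()
  path <- tempfile(fileext = ".csv")
  write_contours_csv(list(lumen = ph$lumen_contour, outer = ph$outer_contour), path)
  back <- read_contours_csv(path)
  expect_equal(sort(names(back)), c("lumen", "outer"))
  expect_equal(unname(back$lumen[, 1]), unname(ph$lumen_contour[, 1]))

  r <- generate_roster(4)
  rp <- tempfile(fileext = ".csv")
  write_roster_csv(r, rp)
  expect_equal(read_roster_csv(rp), r)
})

test_that("study reports serialize to JSON with the vendor-stratified block", {
  rep1 <- suppressMessages(run_study(small_config()))
  path <- tempfile(fileext = ".json")
  txt <- tempfile(fileext = ".txt")
  write_report(rep1, path, text_path = txt)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(out$cascade$analyzed, 35)
  expect_true(all(c("ktrans", "vp") %in% names(out$fits)))
  expect_true(all(c("GE", "Philips") %in% names(out$by_vendor$ktrans)))
  expect_equal(out$fits$ktrans$cv, rep1$fits$ktrans$cv, tolerance = 1e-12)
  expect_true(any(grepl("Sample size", readLines(txt))))
})

test_that("YAML configuration drives a reproducible run", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "bootstrap_B: 300", "n_perm: 300"), path)
  cfg <- read_config_yaml(path)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$bootstrap_B, 300L)
  expect_equal(cfg$parameters$ktrans$grand_mean, 0.062)
})

test_that("V-V images write as PNG files", {
  pr <- ge_protocol()
  ph <- small_phantom()
  aif <- generate_aif(pr)
  ser <- simulate_series(ph, aif, pr, seed = 1)
  conc <- signal_to_concentration(ser, t10 = ph$t10)
  map <- patlak_fit(conc, aif)
  path <- tempfile(fileext = ".png")
  write_vv_png(map, path)
  expect_true(file.exists(path))
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], base::dim(map$ktrans))
})
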