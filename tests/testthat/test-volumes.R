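test_that("volume construction enforces its invariants", {
  expect_error(scalar_volume(array(1, c(2, 2)), c(1, 1, 1)), "3-D")
  expect_error(scalar_volume(array(1, c(1, 4, 4)), c(1, 1, 1)),
               "at least 2 voxels")
  expect_error(scalar_volume(array(1, c(4, 4, 4)), c(1, -1, 1)), "positive")
  bad <- array(1, c(3, 3, 3)); bad[2, 2, 2] <- NA
  expect_error(scalar_volume(bad, c(1, 1, 1)), "finite")
})

test_that("SUV conversion reproduces the unit case and decay doubling", {
  act <- scalar_volume(array(1000, c(4, 4, 4)), c(4, 4, 4), unit = "Bq/mL")
  meta0 <- acquisition_meta(70, 70e6, 0, 0)
  expect_equal(compute_suv(act, meta0)$values,
               array(1, c(4, 4, 4)), tolerance = 1e-12)
  meta1 <- acquisition_meta(70, 70e6, 0, 6586.2)
  expect_equal(compute_suv(act, meta1)$values,
               array(2, c(4, 4, 4)), tolerance = 1e-12)
  zero <- scalar_volume(array(0, c(4, 4, 4)), c(4, 4, 4), unit = "Bq/mL")
  expect_true(all(compute_suv(zero, meta0)$values == 0))
})

test_that("SUV conversion is linear in activity and monotone in uptake time", {
  set.seed(7)
  act <- scalar_volume(array(runif(64, 0, 5000), c(4, 4, 4)), c(4, 4, 5),
                       unit = "Bq/mL")
  meta <- acquisition_meta(80, 300e6, 0, 3000)
  base <- compute_suv(act, meta)$values
  for (k in c(0, 0.5, 2, 10)) {
    scaled <- act; scaled$values <- k * act$values
    expect_equal(compute_suv(scaled, meta)$values, k * base,
                 tolerance = 1e-12)
  }
  dts <- c(0, 600, 3000, 6586.2, 10000)
  suvs <- sapply(dts, function(dt)
    compute_suv(act, acquisition_meta(80, 300e6, 0, dt))$values[1])
  expect_true(all(diff(suvs) > 0))
})

test_that("acquisition metadata rejects impossible values", {
  expect_error(acquisition_meta(0, 1e6), "weight")
  expect_error(acquisition_meta(70, -1), "dose")
  expect_error(acquisition_meta(70, 1e6, 100, 0), "precedes")
  m <- acquisition_meta(70, 1e6, as.POSIXct("2020-01-01 10:00:00", tz = "UTC"),
                        as.POSIXct("2020-01-01 11:00:00", tz = "UTC"))
  expect_equal(m$uptake_time_s, 3600)
})

test_that("phantom roundtrip through disk preserves geometry and SUV", {
  ph <- generate_phantom(small_spec())
  dir <- withr::local_tempdir()
  paths <- write_phantom_series(ph, dir)
  sc <- read_pet_scan(paths[["pet"]])
  expect_equal(sc$volume$spacing, ph$pet$spacing, tolerance = 1e-6)
  expect_equal(sc$volume$origin, ph$pet$origin)
  expect_equal(sc$meta$patient_weight_kg, ph$meta$patient_weight_kg)
  expect_equal(sc$meta$injected_dose_bq, ph$meta$injected_dose_bq)
  expect_equal(sc$meta$uptake_time_s, ph$meta$uptake_time_s)
  suv <- compute_suv(sc$volume, sc$meta)
  expect_equal(suv$values, ph$pet$values, tolerance = 1e-5)
  ct <- read_ct_scan(paths[["ct"]])
  expect_equal(ct$values, ph$ct$values, tolerance = 1e-5)
  expect_equal(ct$spacing, ph$ct$spacing, tolerance = 1e-6)
})

test_that("missing sidecar metadata raises an error naming the field", {
  ph <- generate_phantom(small_spec())
  dir <- withr::local_tempdir()
  paths <- write_phantom_series(ph, dir)
  sc <- jsonlite::read_json(paths[["pet_sidecar"]], simplifyVector = TRUE)
  sc$patient_weight_kg <- NULL
  jsonlite::write_json(sc, paths[["pet_sidecar"]], auto_unbox = TRUE)
  expect_error(read_pet_scan(paths[["pet"]]), "patient_weight")
  expect_error(read_pet_scan(file.path(dir, "nope.nii.gz")), "not found")
})
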