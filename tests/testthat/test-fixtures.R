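test_that("single-cohort fixtures carry the canonical densities and LAI 6", {
  dens <- c(early = 0.0851, mid = 0.0587, late = 0.0682)
  for (lab in names(dens)) {
    cn <- make_single_cohort_canopy(lab)
    expect_length(cn$cohorts, 1)
    co <- cn$cohorts[[1]]
    expect_equal(co$stem_density, unname(dens[lab]))
    expect_equal(co$dbh, 25)
    expect_equal(cohort_lai_of(co), 6)
  }
  expect_equal(make_single_cohort_canopy("early")$soil_albedo_par, 0.25)
  expect_equal(make_single_cohort_canopy("early")$soil_albedo_nir, 0.39)
  expect_error(make_single_cohort_canopy("shrub"), "unknown")
})

test_that("mixed canopies have per-cohort LAI 2 and the named height orders", {
  eml <- make_mixed_canopy("EML")
  expect_equal(sum(vapply(eml$cohorts, cohort_lai_of, numeric(1))), 6)
  expect_equal(vapply(eml$cohorts, function(co) co$stem_density, numeric(1)),
               c(0.0284, 0.0196, 0.0227))
  expect_true(all(vapply(eml$cohorts, function(co) co$dbh, numeric(1)) == 25))
  mle <- make_mixed_canopy("MLE")
  expect_equal(mle$cohorts[[1]]$dbh, 20)        # early cohort reduced
  expect_equal(mle$cohorts[[2]]$dbh, 25)
  expect_error(make_mixed_canopy("LEM"), "arg")
})

test_that("the bundled inventory has 18 stems on a 20 m radius plot", {
  cn <- load_willow_creek()
  labs <- vapply(cn$cohorts, function(co) co$pft$pft_label, character(1))
  expect_length(cn$cohorts, 18)
  expect_equal(sum(labs == "late"), 16)
  expect_equal(sum(labs == "early"), 2)
  expect_equal(cn$cohorts[[1]]$dbh, 23.5)
  expect_equal(cn$cohorts[[1]]$pft$pft_label, "late")
  expect_equal(cn$cohorts[[1]]$stem_density, 1 / (pi * 400),
               tolerance = 1e-12)
  expect_equal(cn$plot_area, pi * 400)
  # every cohort passes the invariants and the canopy solves energy-closed
  f <- noon_snapshot()
  rad <- canopy_radiation(cn, f$direct_par, f$diffuse_par, f$direct_nir,
                          f$diffuse_nir, f$cos_zenith)
  expect_lt(closure_residual(rad$result_par), 1e-12)
  # inventory round-trips through the canopy CSV bit-identically
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_canopy_csv(cn, f1)
  write_canopy_csv(read_canopy_csv(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("random canopies are reproducible and valid", {
  a <- generate_random_canopy(3, seed = 7)
  b <- generate_random_canopy(3, seed = 7)
  expect_equal(a, b)
  one <- generate_random_canopy(1, seed = 99)
  expect_length(one$cohorts, 1)
  expect_true(one$cohorts[[1]]$dbh >= 5 && one$cohorts[[1]]$dbh <= 40)
  # a deep canopy still solves energy-closed
  big <- generate_random_canopy(50, seed = 1)
  res <- solve_canopy_band(big, band_forcing("par", 200, 100, 0.8))
  expect_lt(closure_residual(res), 1e-12)
})

test_that("synthetic forcing has clean solar geometry", {
  f <- synthetic_forcing(day_of_year = 172, n_steps = 48)
  expect_identical(f, synthetic_forcing(day_of_year = 172, n_steps = 48))
  night <- f$cos_zenith <= 0
  expect_true(any(night))
  expect_true(all(f$direct_par[night] == 0))
  expect_true(all(f$direct_nir[night] == 0))
  expect_true(all(f$diffuse_par >= 0 & f$diffuse_nir >= 0))
  # solar-noon elevation: cos(lat - declination) near the solstice
  expect_equal(max(f$cos_zenith), cos((45.8059 - 23.44) * pi / 180),
               tolerance = 2e-3)
  expect_equal(max(f$cos_zenith), 0.925, tolerance = 2e-3)
  # cloud noise: seeded, reproducible, and only attenuates
  fc <- synthetic_forcing(172, 48, seed = 3)
  expect_identical(fc, synthetic_forcing(172, 48, seed = 3))
  tot <- function(x) x$direct_par + x$diffuse_par + x$direct_nir +
    x$diffuse_nir
  expect_true(all(tot(fc) <= tot(f) + 1e-9))
  # PAR:NIR and direct:diffuse partitions hold where the sun is up
  day <- f$cos_zenith > 0
  expect_equal(f$direct_par[day] + f$diffuse_par[day],
               f$direct_nir[day] + f$diffuse_nir[day], tolerance = 1e-12)
  expect_equal(f$direct_par[day] / (f$direct_par[day] + f$diffuse_par[day]),
               rep(0.7, sum(day)), tolerance = 1e-12)
})

test_that("noon snapshot is the maximum-elevation row", {
  f <- noon_snapshot(172)
  expect_equal(nrow(f), 1)
  expect_gt(f$cos_zenith, 0.92)
  expect_gt(f$direct_par, 0)
})

test_that("forcing CSVs round-trip and reject inconsistent beam rows", {
  f <- synthetic_forcing(200, 12)
  p <- withr::local_tempfile(fileext = ".csv")
  write_forcing_csv(f, p)
  back <- read_forcing_csv(p)
  expect_equal(back$direct_par, f$direct_par, tolerance = 1e-9)
  bad <- f
  bad$direct_par[1] <- 10  # midnight beam
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_forcing_csv(bad, p2)
  expect_error(read_forcing_csv(p2), "cos_zenith")
})
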