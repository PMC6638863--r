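test_that("scattering coefficient is the sum of transmittance and reflectance", {
  expect_equal(scattering_coefficient(0, 0), 0)
  expect_equal(scattering_coefficient(0.05, 0.08), 0.13)
  expect_equal(scattering_coefficient(0.25, 0.35), 0.6)
  expect_error(scattering_coefficient(0.5, 0.5), "< 1")
})

test_that("backscattering coefficient matches its closed form", {
  expect_equal(backscattering_coefficient(0.05, 0.05, 0), 0.5)
  expect_equal(backscattering_coefficient(0.05, 0.05, -1), 0)
  expect_equal(backscattering_coefficient(0.05, 0.08, 0), 0.1225 / 0.26,
               tolerance = 1e-12)
  # sign-convention switch flips the (t - r) term
  expect_equal(backscattering_coefficient(0.05, 0.08, 0, "literature"),
               (0.13 + 0.0075) / 0.26, tolerance = 1e-12)
  # black element: isotropic convention with a warning
  expect_warning(b0 <- backscattering_coefficient(0, 0, 0), "isotropic")
  expect_equal(b0, 0.25)
})

test_that("beam extinction follows the leaf-projection G function", {
  expect_equal(beam_extinction(0, 1), 0.5)
  expect_equal(beam_extinction(0, 0.5), 1)
  expect_equal(beam_extinction(0.5, 1), 0.80095, tolerance = 2e-3)
  expect_error(beam_extinction(0, 0), "cos_zenith")
  # spherical orientation: G constant, mu_bar = 1
  expect_equal(mu_bar(0), 1, tolerance = 1e-9)
  # projection polynomial warns outside its nominal range
  expect_warning(g_function(-0.45, 1), "nominal")
})

test_that("layer optics mix leaf and wood by area", {
  # leaf-only layer: coefficients equal leaf coefficients
  p <- test_pft(clumping = 1, wai_b1 = 0)
  co <- cohort(p, 25, 0.05, lai = 3)
  lo <- build_layer_optics(co, "par", 0.9)
  expect_equal(lo$scatter,
               scattering_coefficient(p$leaf_t_par, p$leaf_r_par))
  expect_equal(lo$backscatter,
               backscattering_coefficient(p$leaf_t_par, p$leaf_r_par,
                                          p$orientation))
  # wood-only layer
  co_w <- cohort(test_pft(clumping = 1, wai_b1 = 0.0096), 25, 0.05, lai = 0)
  lo_w <- build_layer_optics(co_w, "nir", 0.9)
  expect_equal(lo_w$scatter,
               scattering_coefficient(p$wood_t_nir, p$wood_r_nir))
  # equal areas: arithmetic mean of the scattering coefficients
  # choose wai allometry so WAI = eLAI = 1
  p_eq <- test_pft(clumping = 1, wai_b1 = 1 / (0.05 * 25^2), wai_b2 = 2,
                   leaf_r_par = 0.06, leaf_t_par = 0.04,
                   wood_r_par = 0.2, wood_t_par = 0.1)
  co_eq <- cohort(p_eq, 25, 0.05, lai = 1)
  lo_eq <- build_layer_optics(co_eq, "par", 0.9)
  expect_equal(lo_eq$tai, 2, tolerance = 1e-12)
  expect_equal(lo_eq$scatter, (0.1 + 0.3) / 2, tolerance = 1e-12)
})

test_that("empty canopy reflects with the soil albedo", {
  for (soil in c(0.25, 0.39)) {
    res <- solve_profile(list(), band_forcing("par", 0, 100), soil)
    expect_equal(res$albedo, soil)
    expect_equal(res$soil_absorbed, (1 - soil) * 100)
    expect_equal(closure_residual(res), 0, tolerance = 1e-12)
  }
})

test_that("a black optically thick layer absorbs everything", {
  lay <- list(make_layer(tai = 50, scatter = 0, backscatter = 0.5,
                         k_direct = 1))
  res <- solve_profile(lay, band_forcing("par", 200, 100, 0.8), 0.25)
  expect_lt(res$albedo, 1e-9)
  expect_equal(res$absorbed_per_layer[1], 300, tolerance = 1e-6)
})

test_that("zero incident flux yields zero fluxes and the diffuse-limit albedo", {
  lay <- list(make_layer(2, 0.2, 0.5, 0.6))
  res <- solve_profile(lay, band_forcing("par", 0, 0), 0.25)
  expect_equal(res$absorbed_per_layer, 0)
  expect_equal(res$incident, 0)
  ref <- solve_profile(lay, band_forcing("par", 0, 1), 0.25)
  expect_equal(res$albedo, ref$albedo)
})

test_that("single reflecting slab matches the geometric-series closed form", {
  tai <- 1.3; s <- 0.4; rho <- 0.3
  f <- 1 - exp(-tai)           # mu_bar = 1
  r1 <- f * s                  # backscatter = 1: all scattering reflects
  t1 <- 1 - f
  closed <- r1 + t1^2 * rho / (1 - rho * r1)
  lay <- list(make_layer(tai, s, backscatter = 1))
  for (solver in c("lin", "neu")) {
    res <- if (solver == "lin") {
      solve_profile(lay, band_forcing("par", 0, 50), rho)
    } else {
      solve_profile_neumann(lay, band_forcing("par", 0, 50), rho, tol = 1e-14)
    }
    expect_equal(res$albedo, closed, tolerance = 1e-10)
  }
})

test_that("the two solvers agree on randomized canopies and energy closes", {
  worst <- 0
  for (sd in 1:25) {
    cn <- generate_random_canopy(1 + sd %% 5, seed = sd)
    for (band in c("par", "nir")) {
      bf <- band_forcing(band, 230, 120, 0.75)
      a <- solve_canopy_band(cn, bf, solver = "linear")
      b <- solve_canopy_band(cn, bf, solver = "neumann")
      worst <- max(worst, solver_discrepancy(a, b))
      expect_lt(closure_residual(a), 1e-12)
      expect_true(all(a$absorbed_per_layer >= -1e-10 * a$incident))
      expect_true(a$albedo >= 0 && a$albedo <= 1)
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("empty canopy solvers agree exactly", {
  a <- solve_profile(list(), band_forcing("nir", 120, 60, 0.9), 0.39)
  b <- solve_profile_neumann(list(), band_forcing("nir", 120, 60, 0.9), 0.39)
  expect_equal(a$albedo, b$albedo, tolerance = 1e-14)
  expect_equal(a$soil_absorbed, b$soil_absorbed, tolerance = 1e-14)
})

test_that("optical limits: transparent canopy -> soil albedo; thick dark canopy -> 0", {
  thin <- list(make_layer(1e-9, 0.3, 0.5, 0.6))
  res <- solve_profile(thin, band_forcing("par", 100, 50, 0.8), 0.25)
  expect_equal(res$albedo, 0.25, tolerance = 1e-6)
  thick <- list(make_layer(500, 1e-4, 0.5, 0.6))
  res2 <- solve_profile(thick, band_forcing("par", 100, 50, 0.8), 0.25)
  expect_lt(res2$albedo, 1e-3)
})

test_that("permuting optically distinct layers changes absorption, not closure", {
  l1 <- make_layer(1.5, 0.1, 0.6, 0.7)
  l2 <- make_layer(0.8, 0.5, 0.4, 0.7)
  bf <- band_forcing("par", 150, 80, 0.8)
  a <- solve_profile(list(l1, l2), bf, 0.25)
  b <- solve_profile(list(l2, l1), bf, 0.25)
  expect_false(isTRUE(all.equal(a$absorbed_per_layer,
                                rev(b$absorbed_per_layer))))
  expect_lt(closure_residual(a), 1e-12)
  expect_lt(closure_residual(b), 1e-12)
})

test_that("total albedo is the incident-weighted band mean", {
  rp <- structure(list(band = "par", albedo = 0.3, incident = 120),
                  class = "rtm_result")
  rn <- structure(list(band = "nir", albedo = 0.3, incident = 480),
                  class = "rtm_result")
  expect_equal(canopy_albedo_total(rp, rn), 0.3)
  rn$albedo <- 0.5
  expect_equal(canopy_albedo_total(rp, rn), (0.3 * 120 + 0.5 * 480) / 600)
  rn$incident <- 0
  expect_equal(canopy_albedo_total(rp, rn), 0.3)
  # empty canopy, 50/50 split of the dry-soil albedos
  e <- canopy()
  rad <- canopy_radiation(e, 0, 100, 0, 100)
  expect_equal(rad$albedo_total, (0.25 + 0.39) / 2)
})

test_that("fAPAR closes the PAR energy budget and responds with the right sign", {
  cn <- make_single_cohort_canopy("early")
  f <- noon_snapshot()
  rad <- canopy_radiation(cn, f$direct_par, f$diffuse_par, f$direct_nir,
                          f$diffuse_nir, f$cos_zenith)
  p <- rad$result_par
  expect_equal(sum(rad$fapar_cohort) + p$soil_absorbed / p$incident +
                 p$albedo, 1, tolerance = 1e-9)
  # optically thick black cohort absorbs ~everything
  thick <- list(make_layer(60, 0.001, 0.5, 0.6))
  res <- solve_profile(thick, band_forcing("par", 100, 50, 0.8), 0.25)
  expect_gt(fapar_per_cohort(res)[1], 0.999)
  # +0.01 leaf PAR reflectance strictly decreases total fAPAR
  cn2 <- make_single_cohort_canopy(
    "early", pfts_with(leaf_r_par = default_pfts()$early$leaf_r_par + 0.01))
  rad2 <- canopy_radiation(cn2, f$direct_par, f$diffuse_par, f$direct_nir,
                           f$diffuse_nir, f$cos_zenith)
  expect_lt(rad2$fapar_total, rad$fapar_total)
})
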