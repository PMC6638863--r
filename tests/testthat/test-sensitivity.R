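# a toy deterministic "model" over parameter sets for sweep-machinery tests
toy_model <- function(pset) {
  v <- pset$early
  c(lin = 3 * v[["cf"]],
    quad = v[["cf"]]^2,
    const = 1.5,
    nir_only = 2 * v[["LR_NIR"]])
}

toy_priors <- function() {
  list(cf = prior_spec("cf", "uniform", 0.4, 0.98),
       LR_NIR = prior_spec("LR_NIR", "lognormal", -1.3402, 0.2096))
}

test_that("univariate sweeps vary one parameter and reuse the baseline", {
  pr <- toy_priors()
  pset <- median_parameter_set(pr, "early")
  sw <- univariate_sweep(toy_model, pset, "cf", "early", pr$cf)
  expect_equal(nrow(sw$outputs), 5)
  expect_identical(sw$outputs[3, ], sw$baseline)       # bit-identical middle
  expect_equal(sw$outputs[, "lin"], 3 * quantile_grid(pr$cf),
               ignore_attr = TRUE)
  # an output that ignores the swept parameter is constant
  expect_equal(unname(sw$outputs[, "nir_only"]),
               rep(sw$baseline[["nir_only"]], 5))
  # a NIR-band albedo ignores a PAR-only parameter in the real model
  cn <- make_single_cohort_canopy("early")
  priors <- default_priors()
  f <- noon_snapshot()
  model <- function(ps) {
    c2 <- apply_parameter_set(cn, ps)
    radiation_outputs(canopy_radiation(c2, f$direct_par, f$diffuse_par,
                                       f$direct_nir, f$diffuse_nir,
                                       f$cos_zenith))
  }
  swp <- univariate_sweep(model, median_parameter_set(priors, "early"),
                          "LT_PAR", "early", priors$LT_PAR)
  expect_equal(unname(swp$outputs[, "albedo_nir"]),
               rep(swp$baseline[["albedo_nir"]], 5))
  expect_false(all(swp$outputs[, "albedo_par"] ==
                     swp$baseline[["albedo_par"]]))
})

test_that("the spline emulator interpolates exactly and handles linear data", {
  x <- c(0, 0.25, 0.5, 0.75, 1)
  lin <- fit_emulator(x, y = 2 * x + 1)
  xs <- seq(-0.5, 1.5, by = 0.01)
  expect_lt(max(abs(lin(xs) - (2 * xs + 1))), 1e-12)
  quad <- fit_emulator(x, y = x^2)
  expect_equal(quad(x), x^2, tolerance = 1e-12)      # exact at the knots
  # away from the natural-spline boundary the error on the unit interval is
  # below 5e-3 (f has unit scale)
  mids <- seq(0.25, 0.75, by = 0.005)
  expect_lt(max(abs(quad(mids) - mids^2)), 5e-3)
  expect_error(fit_emulator(c(1, 1, 2, 3, 4), y = 1:5), "distinct")
})

test_that("elasticity has its closed-form values", {
  pr <- toy_priors()$cf
  m <- prior_median(pr)
  x <- as.numeric(quantile_grid(pr))
  expect_equal(elasticity(fit_emulator(x, y = 7 * x), pr), 1,
               tolerance = 1e-9)
  expect_equal(elasticity(fit_emulator(x, y = rep(4, 5)), pr), 0)
  expect_equal(elasticity(fit_emulator(x, y = x^2), pr), 2, tolerance = 1e-6)
  zero <- elasticity(fit_emulator(x, y = rep(0, 5)), pr)
  expect_true(is.na(zero) && attr(zero, "undefined"))
})

test_that("partial variance matches the closed form for linear responses", {
  a <- 0.4; b <- 0.98; cc <- 3
  pr <- prior_spec("cf", "uniform", a, b)
  x <- as.numeric(quantile_grid(pr))
  em <- fit_emulator(x, y = cc * x)
  n <- 1e5
  pv <- variance_decomposition(em, pr, n, seed = 11)
  true_var <- cc^2 * (b - a)^2 / 12
  # standard error of the sample variance of a uniform: sqrt((m4 - s^4)/n)
  m4 <- cc^4 * (b - a)^4 / 80
  se <- sqrt((m4 - true_var^2) / n)
  expect_lt(abs(pv - true_var), 3 * se)
  # normalized SD of a proportional response equals the prior CV
  nsd <- sqrt(pv) / abs(cc * (a + b) / 2)
  expect_equal(nsd, coefficient_of_variation(pr), tolerance = 0.01)
  expect_equal(variance_decomposition(fit_emulator(x, y = rep(2, 5)), pr,
                                      1000, 1), 0)
})

test_that("partial variance is seed-stable and converges with n", {
  pr <- toy_priors()$LR_NIR
  x <- as.numeric(quantile_grid(pr))
  em <- fit_emulator(x, y = 0.3 * x + x^2)
  expect_identical(variance_decomposition(em, pr, 5000, 3),
                   variance_decomposition(em, pr, 5000, 3))
  n <- 2e4
  pv1 <- variance_decomposition(em, pr, n, 5)
  pv2 <- variance_decomposition(em, pr, 2L * n, 6)
  d1 <- em(sample_prior(pr, n, 5)); d2 <- em(sample_prior(pr, 2L * n, 6))
  se <- function(d) {
    v <- stats::var(d); sqrt((mean((d - mean(d))^4) - v^2) / length(d))
  }
  expect_lt(abs(pv1 - pv2), 3 * (se(d1) + se(d2)))
})

test_that("normalized SD is invariant to output rescaling", {
  pr <- toy_priors()$cf
  x <- as.numeric(quantile_grid(pr))
  y <- 0.1 + 0.5 * x - 0.2 * x^2
  for (k in c(1, 10, 250)) {
    em <- fit_emulator(x, y = k * y)
    pv <- variance_decomposition(em, pr, 2e4, 9)
    base <- em(prior_median(pr))
    if (k == 1) ref <- sqrt(pv) / abs(base)
    expect_equal(sqrt(pv) / abs(base), ref, tolerance = 1e-10)
  }
})

test_that("the full SA table is complete, sorted and deterministic", {
  cn <- make_single_cohort_canopy("early")
  sa1 <- suppressWarnings(run_full_sa(cn, n_mc = 2000, seed = 4))
  sa2 <- suppressWarnings(run_full_sa(cn, n_mc = 2000, seed = 4))
  expect_identical(sa1, sa2)
  # 10 parameters x 1 PFT x (4 + 1 cohort) outputs
  expect_equal(nrow(sa1), 10 * 1 * 5)
  # sorted by normalized_sd within output
  for (out in unique(sa1$output)) {
    nsd <- sa1$normalized_sd[sa1$output == out]
    expect_true(all(diff(nsd) <= 0))
  }
  # elasticity sign equals the monotone sweep trend for reflectance params
  alb <- sa1[sa1$output == "albedo_nir" & sa1$parameter == "LR_NIR", ]
  expect_gt(alb$elasticity, 0)
})

test_that("mixed-canopy SA covers every PFT and series mode aggregates", {
  cn <- make_mixed_canopy("EML")
  sa <- suppressWarnings(
    run_full_sa(cn, outputs = c("albedo_total", "fapar_total"),
                n_mc = 1000, seed = 2))
  expect_equal(nrow(sa), 10 * 3 * 2)
  expect_setequal(unique(sa$pft), c("early", "mid", "late"))
  f <- synthetic_forcing(day_of_year = 200, n_steps = 8)
  sa_series <- suppressWarnings(
    run_full_sa(cn, forcing = f, outputs = "albedo_total", n_mc = 1000,
                seed = 2, forcing_mode = "series"))
  expect_equal(nrow(sa_series), 30)
  expect_true(all(is.finite(sa_series$baseline)))
})
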