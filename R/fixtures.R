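#' Canonical single-cohort canopy fixtures
#'
#' One cohort with LAI 6 and DBH 25 cm; stem densities are the canonical
#' values that yield LAI 6 for each PFT's foliage allometry: 0.0851 (early),
#' 0.0587 (mid) and 0.0682 (late) stems per m2.  Soil albedos are the dry
#' values 0.25 (PAR) and 0.39 (NIR).
#'
#' @param pft_label `"early"`, `"mid"` or `"late"`.
#' @param pfts PFT parameter list (defaults to the bundled config).
#' @return a `canopy` with one cohort.
#' @export
make_single_cohort_canopy <- function(pft_label, pfts = default_pfts()) {
  dens <- c(early = 0.0851, mid = 0.0587, late = 0.0682)
  if (!pft_label %in% names(dens)) {
    stop("unknown PFT label '", pft_label, "'", call. = FALSE)
  }
  canopy(list(cohort(pfts[[pft_label]], dbh = 25,
                     stem_density = dens[[pft_label]], lai = 6)))
}

#' Mixed three-cohort canopy fixtures
#'
#' Early, Mid and Late Hardwood cohorts each contributing LAI 2 (total LAI
#' 6), with stem densities 0.0284, 0.0196 and 0.0227 stems per m2
#' respectively.  In the `"EML"` variant all cohorts have DBH 25 cm and the
#' height order from tallest to shortest is Early, Mid, Late; in `"MLE"` the
#' Early cohort DBH is reduced to 20 cm, forcing the order Mid, Late, Early.
#'
#' @param order `"EML"` or `"MLE"`.
#' @param pfts PFT parameter list.
#' @return a `canopy` with three cohorts (in input order early, mid, late).
#' @export
make_mixed_canopy <- function(order = c("EML", "MLE"), pfts = default_pfts()) {
  order <- match.arg(order)
  early_dbh <- if (order == "EML") 25 else 20
  canopy(list(
    cohort(pfts$early, dbh = early_dbh, stem_density = 0.0284, lai = 2),
    cohort(pfts$mid, dbh = 25, stem_density = 0.0196, lai = 2),
    cohort(pfts$late, dbh = 25, stem_density = 0.0227, lai = 2)
  ))
}

#' Bundled Willow Creek forest inventory canopy
#'
#' Loads the packaged 18-stem inventory (2 early- and 16 late-successional
#' hardwoods) from a circular plot of radius 20 m; each inventoried tree
#' becomes one cohort with stem density `1 / (pi * 20^2)` per m2 and leaf
#' biomass from the PFT allometry.
#'
#' @param pfts PFT parameter list.
#' @return a `canopy` with 18 cohorts and `plot_area` set.
#' @export
load_willow_creek <- function(pfts = default_pfts()) {
  path <- system.file("extdata", "willow_creek_inventory.csv",
                      package = "canopyrt", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  area <- pi * 20^2
  cohorts <- lapply(seq_len(nrow(df)), function(i) {
    p <- pfts[[df$pft[i]]]
    cohort(p, dbh = df$dbh_cm[i], stem_density = 1 / area,
           leaf_biomass = p$bleaf_b1 * df$dbh_cm[i]^p$bleaf_b2)
  })
  canopy(cohorts, plot_area = area)
}

#' Random canopy generator for property tests
#'
#' Seeded draws of DBH in `[5, 40]` cm and direct LAI in `[0.5, 3]` per
#' cohort, PFT labels drawn from `pft_pool`, stem density in
#' `[0.01, 0.1]` stems per m2.
#'
#' @param n_cohorts number of cohorts (>= 1).
#' @param seed integer seed.
#' @param pft_pool labels to draw from.
#' @param pfts PFT parameter list.
#' @return a `canopy`.
#' @export
generate_random_canopy <- function(n_cohorts, seed,
                                   pft_pool = c("early", "mid", "late"),
                                   pfts = default_pfts()) {
  stopifnot(n_cohorts >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  labels <- sample(pft_pool, n_cohorts, replace = TRUE)
  cohorts <- lapply(seq_len(n_cohorts), function(i) {
    cohort(pfts[[labels[i]]],
           dbh = stats::runif(1, 5, 40),
           stem_density = stats::runif(1, 0.01, 0.1),
           lai = stats::runif(1, 0.5, 3))
  })
  canopy(cohorts)
}

#' Synthetic diurnal shortwave forcing
#'
#' Generates a clear-sky growing-season diurnal cycle for the Willow Creek
#' latitude (45.8059 N): the solar position follows the standard
#' declination/hour-angle geometry, the top-of-canopy shortwave is
#' `S0 * tau * cos_zenith` with `S0 = 1361` W/m2 and clear-sky transmittance
#' `tau = 0.75`, partitioned into PAR:NIR and direct:diffuse fractions.
#' Nighttime steps (`cos_zenith <= 0`) carry zero direct flux.  Without a
#' seed the series is deterministic; with a seed a smooth multiplicative
#' cloudiness factor (0.4-1.0) modulates the total flux.
#'
#' @param day_of_year day of year (default 172, near solstice in the
#'   June-October leaf-on window).
#' @param n_steps number of equally spaced steps over the 24 h day.
#' @param seed optional integer seed enabling cloud noise.
#' @param latitude site latitude, degrees north.
#' @param par_frac PAR fraction of total shortwave (default 0.5).
#' @param direct_frac direct (beam) fraction of each band (default 0.7).
#' @return forcing data frame with columns `time` (hours), `direct_par`,
#'   `diffuse_par`, `direct_nir`, `diffuse_nir`, `cos_zenith`.
#' @export
synthetic_forcing <- function(day_of_year = 172, n_steps = 48, seed = NULL,
                              latitude = 45.8059, par_frac = 0.5,
                              direct_frac = 0.7) {
  stopifnot(n_steps >= 1)
  hours <- seq(0, 24, length.out = n_steps + 1)[seq_len(n_steps)]
  decl <- 23.44 * sin(2 * pi * (284 + day_of_year) / 365)
  lat_r <- latitude * pi / 180
  dec_r <- decl * pi / 180
  hour_angle <- (hours - 12) * 15 * pi / 180
  mu <- sin(lat_r) * sin(dec_r) + cos(lat_r) * cos(dec_r) * cos(hour_angle)
  sw <- 1361 * 0.75 * pmax(mu, 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    # smooth cloudiness: random low-order Fourier series squashed into
    # [0.4, 1]
    a <- stats::rnorm(3, 0, 1)
    ph <- stats::runif(3, 0, 2 * pi)
    wob <- rowSums(vapply(1:3, function(k) {
      a[k] * sin(2 * pi * k * hours / 24 + ph[k])
    }, numeric(length(hours))))
    cloud <- 0.4 + 0.6 * stats::plogis(wob)
    sw <- sw * cloud
  }
  dirf <- ifelse(mu > 0, direct_frac, 0)
  data.frame(
    time = hours,
    direct_par = sw * par_frac * dirf,
    diffuse_par = sw * par_frac * (1 - dirf),
    direct_nir = sw * (1 - par_frac) * dirf,
    diffuse_nir = sw * (1 - par_frac) * (1 - dirf),
    cos_zenith = mu
  )
}

#' Solar-noon snapshot of the synthetic forcing
#'
#' Convenience wrapper returning the single forcing row with the largest
#' cosine of solar zenith; the default evaluation condition of the
#' sensitivity analysis.
#'
#' @inheritParams synthetic_forcing
#' @return one-row forcing data frame.
#' @export
noon_snapshot <- function(day_of_year = 172, latitude = 45.8059,
                          par_frac = 0.5, direct_frac = 0.7) {
  f <- synthetic_forcing(day_of_year, n_steps = 96, latitude = latitude,
                         par_frac = par_frac, direct_frac = direct_frac)
  f[which.max(f$cos_zenith), , drop = FALSE]
}
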