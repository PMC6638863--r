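#' Band forcing
#'
#' Incident shortwave forcing for one broadband channel: beam (direct) and
#' diffuse irradiance at the canopy top and the cosine of the solar zenith.
#'
#' @param band `"par"` or `"nir"`.
#' @param direct_flux beam irradiance at the canopy top, W/m2.
#' @param diffuse_flux diffuse irradiance, W/m2.
#' @param cos_zenith cosine of the solar zenith, in `(0, 1]`; may be `NA` if
#'   `direct_flux` is zero.
#' @return a `band_forcing` object.
#' @export
band_forcing <- function(band = c("par", "nir"), direct_flux, diffuse_flux,
                         cos_zenith = NA) {
  band <- match.arg(band)
  if (direct_flux < 0 || diffuse_flux < 0) {
    stop("fluxes must be >= 0", call. = FALSE)
  }
  if (direct_flux > 0 && (is.na(cos_zenith) || cos_zenith <= 0 ||
                          cos_zenith > 1)) {
    stop("direct flux requires cos_zenith in (0, 1]; zero the beam when the ",
         "sun is below the horizon", call. = FALSE)
  }
  structure(list(band = band, direct_flux = direct_flux,
                 diffuse_flux = diffuse_flux, cos_zenith = cos_zenith),
            class = "band_forcing")
}

# Per-layer single-interaction quantities used by both solvers:
# f_dif   diffuse interception 1 - exp(-TAI / mu_bar)
# f_beam  beam interception    1 - exp(-k_direct * TAI)
.layer_interception <- function(ly, need_beam) {
  f_dif <- if (ly$tai > 0) 1 - exp(-ly$tai / ly$mu_bar) else 0
  f_beam <- if (need_beam && ly$tai > 0) {
    if (is.na(ly$k_direct)) {
      stop("layer has no beam extinction but direct flux is present",
           call. = FALSE)
    }
    1 - exp(-ly$k_direct * ly$tai)
  } else 0
  list(f_dif = f_dif, f_beam = f_beam)
}

#' Solve the layered two-stream radiation profile
#'
#' Propagates direct and diffuse flux of one band through height-ordered
#' canopy layers.  The unintercepted beam attenuates as
#' `exp(-k_direct * TAI)` per layer and acts as a source of scattered flux;
#' the upward/downward diffuse fluxes at the layer interfaces satisfy a
#' linear system (interception, forward scattering and backscattering per
#' layer; soil reflectance at the bottom; incident diffuse at the top) which
#' is solved by direct factorization.
#'
#' Per-layer absorption is the net flux divergence of the layer; the albedo
#' is the upward flux at the canopy top over total incident.  When the
#' incident flux is zero the absorbed fluxes are all zero and the albedo is
#' reported as the diffuse-illumination limit computed with unit incident
#' flux.
#'
#' @param layers list of `layer_optics` (see [build_layer_optics()]), ordered
#'   tallest first.
#' @param forcing a [band_forcing()].
#' @param soil_albedo soil reflectance for this band, fraction.
#' @return an `rtm_result`: list with `band`, `albedo`, `absorbed_per_layer`
#'   (W/m2, aligned with `layers`), `soil_absorbed`, `reflected`, `incident`.
#' @seealso [solve_profile_neumann()] for the independent verification solver.
#' @export
solve_profile <- function(layers, forcing, soil_albedo) {
  stopifnot(inherits(forcing, "band_forcing"),
            soil_albedo >= 0, soil_albedo <= 1)
  incident <- forcing$direct_flux + forcing$diffuse_flux
  if (incident == 0) {
    unit <- band_forcing(forcing$band, 0, 1, forcing$cos_zenith)
    ref <- solve_profile(layers, unit, soil_albedo)
    return(structure(list(band = forcing$band, albedo = ref$albedo,
                          absorbed_per_layer = numeric(length(layers)),
                          soil_absorbed = 0, reflected = 0, incident = 0),
                     class = "rtm_result"))
  }
  L <- length(layers)
  need_beam <- forcing$direct_flux > 0
  icpt <- lapply(layers, .layer_interception, need_beam = need_beam)
  f <- vapply(icpt, `[[`, numeric(1), "f_dif")
  s <- vapply(layers, `[[`, numeric(1), "scatter")
  b <- vapply(layers, `[[`, numeric(1), "backscatter")
  Tm <- (1 - f) + f * s * (1 - b)        # diffuse transmission per layer
  Rm <- f * s * b                        # diffuse reflection per layer

  # beam profile: S[i] is the unintercepted beam below layer i (S[1] = top)
  S <- numeric(L + 1)
  S[1] <- forcing$direct_flux
  if (L > 0) {
    fb <- vapply(icpt, `[[`, numeric(1), "f_beam")
    for (i in seq_len(L)) S[i + 1] <- S[i] * (1 - fb[i])
  }
  Bint <- if (L > 0) S[seq_len(L)] - S[seq_len(L) + 1] else numeric(0)
  Sdn <- Bint * s * (1 - b)
  Sup <- Bint * s * b

  # unknowns: d_0..d_L then u_0..u_L (interface 0 = canopy top, L = soil)
  n <- 2L * (L + 1L)
  di <- function(i) i + 1L
  ui <- function(i) L + 2L + i
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, di(0)] <- 1; rhs[1] <- forcing$diffuse_flux
  for (i in seq_len(L)) {
    r <- 1L + i                          # downward equation of layer i
    A[r, di(i)] <- 1
    A[r, di(i - 1)] <- -Tm[i]
    A[r, ui(i)] <- -Rm[i]
    rhs[r] <- Sdn[i]
    r <- L + 1L + i                      # upward equation of layer i
    A[r, ui(i - 1)] <- 1
    A[r, ui(i)] <- -Tm[i]
    A[r, di(i - 1)] <- -Rm[i]
    rhs[r] <- Sup[i]
  }
  A[n, ui(L)] <- 1
  A[n, di(L)] <- -soil_albedo
  rhs[n] <- soil_albedo * S[L + 1]

  x <- tryCatch(solve(A, rhs), error = function(e) {
    stop("two-stream interface system is singular (non-physical layer ",
         "coefficients?): ", conditionMessage(e), call. = FALSE)
  })
  d <- x[seq_len(L + 1)]
  u <- x[L + 1 + seq_len(L + 1)]

  # net flux divergence: the scattered beam fractions leave through the
  # diffuse source terms already embedded in d and u, so the whole
  # intercepted beam Bint enters the balance
  absorbed <- if (L > 0) {
    (d[seq_len(L)] - d[seq_len(L) + 1]) +
      (u[seq_len(L) + 1] - u[seq_len(L)]) + Bint
  } else numeric(0)
  soil_absorbed <- (1 - soil_albedo) * (d[L + 1] + S[L + 1])
  structure(list(band = forcing$band, albedo = u[1] / incident,
                 absorbed_per_layer = absorbed,
                 soil_absorbed = soil_absorbed,
                 reflected = u[1], incident = incident),
            class = "rtm_result")
}

#' Successive-orders-of-scattering solver (verification oracle)
#'
#' Computes the same radiation profile as [solve_profile()] by explicitly
#' tracking flux bundles through successive scattering orders: at each layer
#' interaction the intercepted fraction `scatter` is re-emitted, of which
#' `backscatter` reverses direction; the soil reflects by `soil_albedo`;
#' iteration stops when the circulating (not yet absorbed or escaped)
#' scattered flux falls below `tol * incident`.
#'
#' @inheritParams solve_profile
#' @param tol convergence tolerance relative to the incident flux.
#' @param max_orders iteration cap; exceeding it signals a non-physical
#'   configuration upstream.
#' @return an `rtm_result` (see [solve_profile()]).
#' @export
solve_profile_neumann <- function(layers, forcing, soil_albedo, tol = 1e-12,
                                  max_orders = 10000L) {
  stopifnot(inherits(forcing, "band_forcing"), tol > 0,
            soil_albedo >= 0, soil_albedo <= 1)
  incident <- forcing$direct_flux + forcing$diffuse_flux
  if (incident == 0) {
    unit <- band_forcing(forcing$band, 0, 1, forcing$cos_zenith)
    ref <- solve_profile_neumann(layers, unit, soil_albedo, tol, max_orders)
    return(structure(list(band = forcing$band, albedo = ref$albedo,
                          absorbed_per_layer = numeric(length(layers)),
                          soil_absorbed = 0, reflected = 0, incident = 0),
                     class = "rtm_result"))
  }
  L <- length(layers)
  need_beam <- forcing$direct_flux > 0
  icpt <- lapply(layers, .layer_interception, need_beam = need_beam)
  f <- vapply(icpt, `[[`, numeric(1), "f_dif")
  s <- vapply(layers, `[[`, numeric(1), "scatter")
  b <- vapply(layers, `[[`, numeric(1), "backscatter")

  absorbed <- numeric(L)
  soil_absorbed <- 0
  reflected <- 0
  # dn[i]: diffuse flux arriving downward at the top of layer i; dn[L+1] is
  # flux arriving at the soil.  up[i+1]: flux arriving upward at the bottom
  # of layer i; flux leaving layer 1 upward escapes to the sky (reflected).
  dn <- numeric(L + 1)
  up <- numeric(L + 1)

  # first order: the direct beam attenuates and converts to diffuse sources
  if (need_beam) {
    fb <- vapply(icpt, `[[`, numeric(1), "f_beam")
    S <- forcing$direct_flux
    for (i in seq_len(L)) {
      B <- S * fb[i]
      absorbed[i] <- absorbed[i] + B * (1 - s[i])
      dn[i + 1] <- dn[i + 1] + B * s[i] * (1 - b[i])
      if (i == 1) reflected <- reflected + B * s[i] * b[i]
      else up[i] <- up[i] + B * s[i] * b[i]       # into layer i-1: up[(i-1)+1]
      S <- S - B
    }
    soil_absorbed <- soil_absorbed + (1 - soil_albedo) * S
    if (L == 0) reflected <- reflected + soil_albedo * S
    else up[L + 1] <- up[L + 1] + soil_albedo * S
  }
  dn[1] <- dn[1] + forcing$diffuse_flux

  for (order in seq_len(max_orders)) {
    new_dn <- numeric(L + 1)
    new_up <- numeric(L + 1)
    dsoil <- dn[L + 1]
    if (dsoil > 0) {
      soil_absorbed <- soil_absorbed + (1 - soil_albedo) * dsoil
      if (L == 0) reflected <- reflected + soil_albedo * dsoil
      else new_up[L + 1] <- new_up[L + 1] + soil_albedo * dsoil
    }
    for (i in seq_len(L)) {
      dni <- dn[i]
      if (dni > 0) {
        icp <- dni * f[i]
        absorbed[i] <- absorbed[i] + icp * (1 - s[i])
        fwd <- dni - icp + icp * s[i] * (1 - b[i])
        bwd <- icp * s[i] * b[i]
        new_dn[i + 1] <- new_dn[i + 1] + fwd
        if (i == 1) reflected <- reflected + bwd
        else new_up[i] <- new_up[i] + bwd
      }
      upi <- up[i + 1]
      if (upi > 0) {
        icp <- upi * f[i]
        absorbed[i] <- absorbed[i] + icp * (1 - s[i])
        fwd <- upi - icp + icp * s[i] * (1 - b[i])
        bwd <- icp * s[i] * b[i]
        if (i == 1) reflected <- reflected + fwd
        else new_up[i] <- new_up[i] + fwd
        if (i == L) new_dn[L + 1] <- new_dn[L + 1] + bwd
        else new_dn[i + 1] <- new_dn[i + 1] + bwd
      }
    }
    dn <- new_dn
    up <- new_up
    circulating <- sum(dn) + sum(up)
    if (circulating < tol * incident) break
    if (order == max_orders) {
      stop("successive-orders solver did not converge within ", max_orders,
           " orders; scattering coefficient >= 1 upstream?", call. = FALSE)
    }
  }
  structure(list(band = forcing$band, albedo = reflected / incident,
                 absorbed_per_layer = absorbed,
                 soil_absorbed = soil_absorbed,
                 reflected = reflected, incident = incident),
            class = "rtm_result")
}

#' @export
print.rtm_result <- function(x, ...) {
  cat("<rtm_result>", x$band, " incident", signif(x$incident, 6), "W/m2\n")
  cat("  albedo", signif(x$albedo, 6), " soil", signif(x$soil_absorbed, 6),
      " layers:", paste(signif(x$absorbed_per_layer, 5), collapse = " "), "\n")
  invisible(x)
}

#' Broadband canopy albedo
#'
#' Total shortwave albedo as the incident-flux-weighted mean of the PAR and
#' NIR band albedos.  If both bands carry zero incident flux, the albedos are
#' combined with the configured partition weights instead.
#'
#' @param result_par,result_nir `rtm_result` objects for the two bands.
#' @param par_frac PAR fraction used only in the zero-incident limit.
#' @return total albedo, fraction.
#' @export
canopy_albedo_total <- function(result_par, result_nir, par_frac = 0.5) {
  tot <- result_par$incident + result_nir$incident
  if (tot == 0) {
    return(par_frac * result_par$albedo + (1 - par_frac) * result_nir$albedo)
  }
  (result_par$albedo * result_par$incident +
     result_nir$albedo * result_nir$incident) / tot
}

#' Fraction of absorbed PAR per canopy layer
#'
#' Per-layer absorbed PAR over incident PAR; together with the soil fraction
#' and the albedo these close the energy budget to within solver tolerance.
#'
#' @param result_par an `rtm_result` for the PAR band.
#' @return numeric vector aligned with the solver's layer order.
#' @export
fapar_per_cohort <- function(result_par) {
  if (result_par$incident == 0) {
    return(numeric(length(result_par$absorbed_per_layer)))
  }
  result_par$absorbed_per_layer / result_par$incident
}
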