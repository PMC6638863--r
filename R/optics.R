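#' Single scattering coefficient
#'
#' The fraction of intercepted radiation scattered (rather than absorbed) by a
#' canopy element is the sum of its transmittance and reflectance:
#' `a = t + r`.
#'
#' @param t transmittance fraction in `[0, 1)`.
#' @param r reflectance fraction in `[0, 1)`.
#' @return scattering coefficient, fraction in `[0, 1)`.
#' @export
scattering_coefficient <- function(t, r) {
  if (t < 0 || r < 0 || t >= 1 || r >= 1) {
    stop("t and r must lie in [0, 1)", call. = FALSE)
  }
  if (t + r >= 1) {
    stop("t + r must be < 1 (element would be fully scattering)",
         call. = FALSE)
  }
  t + r
}

#' Backscattering coefficient
#'
#' Fraction of the scattered radiation redirected backwards (towards the side
#' the flux came from):
#' `beta = (a + 0.25 * (t - r)) * (1 + a_orient)^2 / (2 * a)`, with
#' `a = t + r`.  `sign` selects the sign convention of the `0.25 * (t - r)`
#' term; much of the two-stream literature uses `(r - t)` instead, available
#' as `sign = "literature"`.
#'
#' For a perfectly black element (`a = 0`) the ratio is undefined; the
#' isotropic convention `0.5 * (1 + a_orient)^2 / 2` is returned with a
#' warning.
#'
#' Note the returned value can exceed 1 for strongly horizontal leaves
#' (`a_orient` near 1); layer assembly clamps it into `[0, 1]`
#' (see [build_layer_optics()]).
#'
#' @param t,r transmittance and reflectance fractions.
#' @param a_orient orientation factor in `[-1, 1]`.
#' @param sign `"as_printed"` (default) uses `(t - r)`; `"literature"` uses
#'   `(r - t)`.
#' @return backscatter fraction (unclamped).
#' @export
backscattering_coefficient <- function(t, r, a_orient,
                                       sign = c("as_printed", "literature")) {
  sign <- match.arg(sign)
  if (a_orient < -1 || a_orient > 1) {
    stop("a_orient must lie in [-1, 1]", call. = FALSE)
  }
  orient_term <- (1 + a_orient)^2
  a <- t + r
  if (a == 0) {
    warning("backscattering_coefficient: t + r = 0; using isotropic convention",
            call. = FALSE)
    return(0.5 * orient_term / 2)
  }
  diff <- if (sign == "as_printed") t - r else r - t
  (a + 0.25 * diff) * orient_term / (2 * a)
}

#' Leaf-angle projection function and derived extinction
#'
#' `g_function()` is the standard two-parameter approximation of the projected
#' leaf area in the beam direction: `G(mu) = phi1 + phi2 * mu` with
#' `phi1 = 0.5 - 0.633 * chi - 0.33 * chi^2` and
#' `phi2 = 0.877 * (1 - 2 * phi1)`, `chi` the orientation factor.
#' The polynomial is nominally valid for `chi` in `[-0.4, 0.6]`; outside that
#' range a warning is issued and the value evaluated as-is.
#'
#' `beam_extinction()` is the direct-beam extinction per unit total area
#' index, `k = G(mu) / mu`.
#'
#' `mu_bar()` is the average inverse diffuse optical depth,
#' `integral of mu' / G(mu') over mu' in (0, 1]`, computed by numerical
#' quadrature; the diffuse interception of a layer of thickness TAI is
#' `1 - exp(-TAI / mu_bar)`.
#'
#' @param a_orient orientation factor `chi` in `[-1, 1]`.
#' @param cos_zenith cosine of the solar zenith angle, in `(0, 1]`.
#' @return `g_function()`: projection (dimensionless); `beam_extinction()`:
#'   extinction per unit TAI; `mu_bar()`: dimensionless optical-depth scale.
#' @export
g_function <- function(a_orient, cos_zenith) {
  if (a_orient < -1 || a_orient > 1) {
    stop("a_orient must lie in [-1, 1]", call. = FALSE)
  }
  if (a_orient < -0.4 || a_orient > 0.6) {
    warning("orientation factor ", signif(a_orient, 4),
            " outside the nominal [-0.4, 0.6] range of the projection ",
            "polynomial; evaluating as-is", call. = FALSE)
  }
  phi1 <- 0.5 - 0.633 * a_orient - 0.33 * a_orient^2
  phi2 <- 0.877 * (1 - 2 * phi1)
  phi1 + phi2 * cos_zenith
}

#' @rdname g_function
#' @export
beam_extinction <- function(a_orient, cos_zenith) {
  if (cos_zenith <= 0 || cos_zenith > 1) {
    stop("cos_zenith must lie in (0, 1] (sun above the horizon)",
         call. = FALSE)
  }
  k <- g_function(a_orient, cos_zenith) / cos_zenith
  if (k <= 0) stop("non-positive beam extinction (invalid projection)",
                   call. = FALSE)
  k
}

#' @rdname g_function
#' @export
mu_bar <- function(a_orient) {
  f <- function(mu) {
    phi1 <- 0.5 - 0.633 * a_orient - 0.33 * a_orient^2
    phi2 <- 0.877 * (1 - 2 * phi1)
    mu / (phi1 + phi2 * mu)
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}

#' Assemble the optical description of a canopy layer
#'
#' Combines a cohort's leaf and wood optical properties into the per-band
#' coefficients the solver needs.  Scattering mixes by area:
#' `a = (eLAI * a_leaf + WAI * a_wood) / TAI`; backscatter mixes weighted by
#' scattered flux: `beta = (eLAI * a_leaf * beta_leaf + WAI * a_wood *
#' beta_wood) / (eLAI * a_leaf + WAI * a_wood)`.  The mixed backscatter is
#' clamped into `[0, 1]`.
#'
#' A zero-TAI layer is returned as perfectly transparent (zero interception).
#'
#' @param co a `cohort`.
#' @param band `"par"` or `"nir"`.
#' @param cos_zenith cosine of solar zenith for the beam extinction; may be
#'   `NA` for diffuse-only forcing (beam extinction then unset).
#' @param backscatter_sign passed to [backscattering_coefficient()].
#' @return a `layer_optics` list with fields `tai`, `scatter`, `backscatter`,
#'   `orientation`, `k_direct`, `mu_bar`.
#' @export
build_layer_optics <- function(co, band = c("par", "nir"), cos_zenith = NA,
                               backscatter_sign = c("as_printed",
                                                    "literature")) {
  band <- match.arg(band)
  backscatter_sign <- match.arg(backscatter_sign)
  stopifnot(inherits(co, "cohort"))
  ai <- cohort_area_indices(co)
  chi <- co$pft$orientation

  lr <- co$pft[[paste0("leaf_r_", band)]]
  lt <- co$pft[[paste0("leaf_t_", band)]]
  wr <- co$pft[[paste0("wood_r_", band)]]
  wt <- co$pft[[paste0("wood_t_", band)]]

  a_leaf <- scattering_coefficient(lt, lr)
  a_wood <- scattering_coefficient(wt, wr)
  b_leaf <- if (a_leaf > 0) {
    backscattering_coefficient(lt, lr, chi, backscatter_sign)
  } else 0.5 * (1 + chi)^2 / 2    # isotropic convention for black tissue
  b_wood <- if (a_wood > 0) {
    backscattering_coefficient(wt, wr, chi, backscatter_sign)
  } else 0.5 * (1 + chi)^2 / 2

  if (ai$tai <= 0) {
    scatter <- 0
    backscatter <- 0.5
  } else {
    scatter <- (ai$elai * a_leaf + ai$wai * a_wood) / ai$tai
    sw <- ai$elai * a_leaf + ai$wai * a_wood
    backscatter <- if (sw > 0) {
      (ai$elai * a_leaf * b_leaf + ai$wai * a_wood * b_wood) / sw
    } else 0.5
    backscatter <- min(1, max(0, backscatter))
  }

  structure(list(
    tai = ai$tai,
    scatter = scatter,
    backscatter = backscatter,
    orientation = chi,
    k_direct = if (is.na(cos_zenith)) NA_real_
               else beam_extinction(chi, cos_zenith),
    mu_bar = mu_bar(chi)
  ), class = "layer_optics")
}
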