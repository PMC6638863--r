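#' Plant functional type parameter sets
#'
#' A `pft_params` object bundles every per-PFT constant the radiative transfer
#' scheme needs: allometric coefficients (specific leaf area, leaf-biomass,
#' wood-area and height allometries) and the radiative parameters (clumping,
#' leaf orientation, and reflectance/transmittance of leaf and wood in the PAR
#' and NIR bands).
#'
#' @param pft_label one of `"early"`, `"mid"`, `"late"` (successional temperate
#'   hardwood PFTs).
#' @param sla specific leaf area, m2 of leaf per kg of leaf biomass.
#' @param bleaf_b1,bleaf_b2 leaf-biomass allometry `B_leaf = b1 * DBH^b2`
#'   (kg per stem, DBH in cm).
#' @param wai_b1,wai_b2 wood-area-index allometry coefficients (see
#'   [cohort_wai()]).
#' @param href reference height, m.
#' @param height_b1 asymptotic height increment above `href`, m.
#' @param height_b2 height-curvature coefficient, 1/cm; negative values give a
#'   saturating height curve (see [cohort_height()]).
#' @param clumping canopy clumping factor in `[0, 1]`; 1 means homogeneously
#'   distributed foliage, smaller values mean tighter aggregation.
#' @param orientation leaf orientation factor in `[-1, 1]`; -1 leaves parallel
#'   to the beam, +1 perpendicular.
#' @param leaf_r_par,leaf_t_par,leaf_r_nir,leaf_t_nir leaf reflectance and
#'   transmittance per band, fractions in `[0, 1)` with `r + t < 1`.
#' @param wood_r_par,wood_t_par,wood_r_nir,wood_t_nir wood reflectance and
#'   transmittance per band, same constraints.
#' @return an object of class `pft_params`.
#' @seealso [default_pfts()], [read_pft_config()]
#' @export
pft_params <- function(pft_label, sla, bleaf_b1, bleaf_b2, wai_b1, wai_b2,
                       href, height_b1, height_b2,
                       clumping, orientation,
                       leaf_r_par, leaf_t_par, leaf_r_nir, leaf_t_nir,
                       wood_r_par, wood_t_par, wood_r_nir, wood_t_nir) {
  pft_label <- match.arg(pft_label, c("early", "mid", "late"))
  x <- list(
    pft_label = pft_label, sla = sla,
    bleaf_b1 = bleaf_b1, bleaf_b2 = bleaf_b2,
    wai_b1 = wai_b1, wai_b2 = wai_b2,
    href = href, height_b1 = height_b1, height_b2 = height_b2,
    clumping = clumping, orientation = orientation,
    leaf_r_par = leaf_r_par, leaf_t_par = leaf_t_par,
    leaf_r_nir = leaf_r_nir, leaf_t_nir = leaf_t_nir,
    wood_r_par = wood_r_par, wood_t_par = wood_t_par,
    wood_r_nir = wood_r_nir, wood_t_nir = wood_t_nir
  )
  class(x) <- "pft_params"
  validate_pft_params(x)
}

validate_pft_params <- function(x) {
  stopifnot(inherits(x, "pft_params"))
  num <- setdiff(names(x), "pft_label")
  for (f in num) {
    if (!is.numeric(x[[f]]) || length(x[[f]]) != 1L || !is.finite(x[[f]])) {
      stop("pft_params field '", f, "' must be a finite numeric scalar",
           call. = FALSE)
    }
  }
  if (x$clumping < 0 || x$clumping > 1) {
    stop("clumping must lie in [0, 1]", call. = FALSE)
  }
  if (x$orientation < -1 || x$orientation > 1) {
    stop("orientation must lie in [-1, 1]", call. = FALSE)
  }
  for (tissue in c("leaf", "wood")) {
    for (band in c("par", "nir")) {
      r <- x[[paste0(tissue, "_r_", band)]]
      t <- x[[paste0(tissue, "_t_", band)]]
      if (r < 0 || r >= 1 || t < 0 || t >= 1) {
        stop(tissue, " ", band, " optical coefficients must lie in [0, 1)",
             call. = FALSE)
      }
      if (r + t >= 1) {
        stop(tissue, " ", band, " reflectance + transmittance must be < 1 ",
             "(absorptance must be positive)", call. = FALSE)
      }
    }
  }
  x
}

#' @export
print.pft_params <- function(x, ...) {
  cat("<pft_params>", x$pft_label, "\n")
  cat("  SLA:", x$sla, "m2/kg; height: href", x$href, "+", x$height_b1,
      "* (1 - exp(", x$height_b2, "* DBH))\n")
  cat("  clumping:", x$clumping, " orientation:", x$orientation, "\n")
  cat(sprintf("  leaf r/t PAR %.4f/%.4f NIR %.4f/%.4f\n",
              x$leaf_r_par, x$leaf_t_par, x$leaf_r_nir, x$leaf_t_nir))
  cat(sprintf("  wood r/t PAR %.4f/%.4f NIR %.4f/%.4f\n",
              x$wood_r_par, x$wood_t_par, x$wood_r_nir, x$wood_t_nir))
  invisible(x)
}

#' Read a PFT parameter configuration file
#'
#' The configuration is a YAML document mapping PFT labels to the fields of
#' [pft_params()]; it round-trips through [write_pft_config()].
#'
#' @param path path to a YAML file.
#' @return a named list of `pft_params`, keyed by PFT label.
#' @export
read_pft_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(rec) do.call(pft_params, rec))
  names(out) <- vapply(out, function(p) p$pft_label, character(1))
  out
}

#' Write a PFT parameter configuration file
#'
#' @param pfts a named list of `pft_params` (as from [read_pft_config()]).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_pft_config <- function(pfts, path) {
  raw <- lapply(pfts, function(p) unclass(p))
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Bundled default PFT parameter sets
#'
#' Returns the packaged early/mid/late-successional temperate hardwood
#' parameter sets.  The radiative fields default to the medians of the bundled
#' priors ([default_priors()]); the allometric fields are documented, editable
#' placeholders chosen so that the canonical mixed-canopy height orderings and
#' LAI magnitudes are reproduced.
#'
#' @return a named list of `pft_params` with elements `early`, `mid`, `late`.
#' @export
default_pfts <- function() {
  path <- system.file("extdata", "pft_params.yaml", package = "canopyrt",
                      mustWork = TRUE)
  read_pft_config(path)
}
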