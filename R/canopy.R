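#' Cohorts and canopies
#'
#' A cohort is a group of trees of similar size and PFT, represented as one
#' idealized canopy layer.  A canopy is an ordered collection of cohorts above
#' a soil with fixed per-band albedos.
#'
#' Exactly one of `lai` and `leaf_biomass` must be given: either the cohort
#' leaf area index is prescribed directly, or it is derived from per-stem leaf
#' biomass through [cohort_lai()].
#'
#' @param pft a `pft_params` object (see [pft_params()]).
#' @param dbh trunk diameter at breast height, cm; must be positive.
#' @param stem_density stems per m2 of ground.
#' @param lai optional direct cohort leaf area index (m2/m2), bypassing the
#'   biomass allometry.
#' @param leaf_biomass optional leaf biomass per stem, kg.
#' @return an object of class `cohort`.
#' @export
cohort <- function(pft, dbh, stem_density, lai = NULL, leaf_biomass = NULL) {
  stopifnot(inherits(pft, "pft_params"))
  if (!is.numeric(dbh) || length(dbh) != 1L || !is.finite(dbh) || dbh <= 0) {
    stop("dbh must be a positive scalar (cm)", call. = FALSE)
  }
  if (!is.numeric(stem_density) || stem_density < 0) {
    stop("stem_density must be >= 0", call. = FALSE)
  }
  if (is.null(lai) == is.null(leaf_biomass)) {
    stop("provide exactly one of `lai` and `leaf_biomass`", call. = FALSE)
  }
  if (!is.null(lai) && lai < 0) stop("lai must be >= 0", call. = FALSE)
  if (!is.null(leaf_biomass) && leaf_biomass < 0) {
    stop("leaf_biomass must be >= 0", call. = FALSE)
  }
  structure(list(pft = pft, dbh = dbh, stem_density = stem_density,
                 lai_override = lai, leaf_biomass = leaf_biomass),
            class = "cohort")
}

#' @param cohorts list of `cohort` objects (may be empty).
#' @param soil_albedo_par,soil_albedo_nir per-band soil albedo fractions;
#'   defaults are the dry-soil values 0.25 (PAR) and 0.39 (NIR).
#' @param plot_area plot area in m2 (metadata only).
#' @rdname cohort
#' @export
canopy <- function(cohorts = list(), soil_albedo_par = 0.25,
                   soil_albedo_nir = 0.39, plot_area = NA_real_) {
  stopifnot(is.list(cohorts),
            all(vapply(cohorts, inherits, logical(1), "cohort")))
  for (a in c(soil_albedo_par, soil_albedo_nir)) {
    if (!is.numeric(a) || a < 0 || a > 1) {
      stop("soil albedos must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(cohorts = cohorts,
                 soil_albedo_par = soil_albedo_par,
                 soil_albedo_nir = soil_albedo_nir,
                 plot_area = plot_area),
            class = "canopy")
}

#' @export
print.canopy <- function(x, ...) {
  cat("<canopy>", length(x$cohorts), "cohort(s); soil albedo PAR",
      x$soil_albedo_par, "/ NIR", x$soil_albedo_nir, "\n")
  if (length(x$cohorts)) {
    h <- vapply(x$cohorts, cohort_height_of, numeric(1))
    for (i in seq_along(x$cohorts)) {
      co <- x$cohorts[[i]]
      cat(sprintf("  [%d] %-5s dbh %5.1f cm  density %.4g /m2  height %5.2f m  LAI %.3f\n",
                  i, co$pft$pft_label, co$dbh, co$stem_density, h[i],
                  cohort_lai_of(co)))
    }
  }
  invisible(x)
}

# ---- geometric primitives -------------------------------------------------

#' Cohort leaf area index from biomass
#'
#' `LAI = SLA * N * B_leaf`: the one-sided leaf area per unit ground equals
#' specific leaf area times stem density times per-stem leaf biomass.
#'
#' @param sla specific leaf area, m2/kg.
#' @param stem_density stems per m2.
#' @param leaf_biomass leaf biomass per stem, kg.
#' @return leaf area index, m2/m2.
#' @export
cohort_lai <- function(sla, stem_density, leaf_biomass) {
  if (any(c(sla, stem_density, leaf_biomass) < 0)) {
    stop("cohort_lai: all inputs must be >= 0", call. = FALSE)
  }
  sla * stem_density * leaf_biomass
}

#' Cohort wood area index from the DBH allometry
#'
#' `WAI = N * b1 * DBH^b2`.
#'
#' @param stem_density stems per m2.
#' @param wai_b1,wai_b2 allometry coefficients.
#' @param dbh diameter at breast height, cm; must be positive.
#' @return wood area index, m2/m2.
#' @export
cohort_wai <- function(stem_density, wai_b1, wai_b2, dbh) {
  if (dbh <= 0) stop("cohort_wai: dbh must be > 0", call. = FALSE)
  if (stem_density < 0) stop("cohort_wai: stem_density must be >= 0",
                             call. = FALSE)
  stem_density * wai_b1 * dbh^wai_b2
}

#' Effective (clumping-weighted) leaf area index
#'
#' `eLAI = clumping * LAI`.  The clumping factor applies to leaves only; wood
#' area is not de-clumped.
#'
#' @param clumping clumping factor in `[0, 1]`.
#' @param lai leaf area index, m2/m2.
#' @return effective LAI, m2/m2.
#' @export
effective_lai <- function(clumping, lai) {
  if (clumping < 0 || clumping > 1) {
    stop("effective_lai: clumping must lie in [0, 1]", call. = FALSE)
  }
  if (lai < 0) stop("effective_lai: lai must be >= 0", call. = FALSE)
  clumping * lai
}

#' Total area index
#'
#' `TAI = eLAI + WAI`: the optical thickness of a layer combines
#' clumping-weighted leaf area with (un-clumped) wood area.
#'
#' @param elai effective leaf area index, m2/m2.
#' @param wai wood area index, m2/m2.
#' @return total area index, m2/m2.
#' @export
total_area_index <- function(elai, wai) {
  if (elai < 0 || wai < 0) {
    stop("total_area_index: inputs must be >= 0", call. = FALSE)
  }
  elai + wai
}

#' Cohort height from the DBH allometry
#'
#' `h = href + b1 * (1 - exp(b2 * DBH))`.  With `b2 < 0` this saturates
#' towards `href + b1` for large trees.
#'
#' @param href reference height, m.
#' @param height_b1 asymptotic height increment, m.
#' @param height_b2 curvature coefficient, 1/cm.
#' @param dbh diameter at breast height, cm.
#' @return height, m.
#' @export
cohort_height <- function(href, height_b1, height_b2, dbh) {
  if (dbh < 0) stop("cohort_height: dbh must be >= 0", call. = FALSE)
  href + height_b1 * (1 - exp(height_b2 * dbh))
}

# ---- cohort-level accessors ----------------------------------------------

#' Derived per-cohort quantities
#'
#' `cohort_lai_of()`, `cohort_wai_of()`, `cohort_height_of()` and
#' `cohort_area_indices()` evaluate the allometric primitives on a `cohort`
#' object using its PFT constants.  `cohort_area_indices()` returns LAI,
#' effective LAI, WAI and TAI together.
#'
#' @param co a `cohort`.
#' @return a numeric scalar, or for `cohort_area_indices()` a named list with
#'   `lai`, `elai`, `wai`, `tai`.
#' @export
cohort_lai_of <- function(co) {
  if (!is.null(co$lai_override)) return(co$lai_override)
  cohort_lai(co$pft$sla, co$stem_density,
             if (!is.null(co$leaf_biomass)) co$leaf_biomass
             else co$pft$bleaf_b1 * co$dbh^co$pft$bleaf_b2)
}

#' @rdname cohort_lai_of
#' @export
cohort_wai_of <- function(co) {
  cohort_wai(co$stem_density, co$pft$wai_b1, co$pft$wai_b2, co$dbh)
}

#' @rdname cohort_lai_of
#' @export
cohort_height_of <- function(co) {
  cohort_height(co$pft$href, co$pft$height_b1, co$pft$height_b2, co$dbh)
}

#' @rdname cohort_lai_of
#' @export
cohort_area_indices <- function(co) {
  lai <- cohort_lai_of(co)
  elai <- effective_lai(co$pft$clumping, lai)
  wai <- cohort_wai_of(co)
  list(lai = lai, elai = elai, wai = wai, tai = total_area_index(elai, wai))
}

#' Order canopy cohorts into radiative layers
#'
#' Cohorts interact with radiation in layers from the tallest cohort to the
#' shortest; the whole cohort occupies a single layer.  Height ties preserve
#' the input cohort order (stable sort).
#'
#' @param cnpy a `canopy`.
#' @return a list with `cohorts` (tallest first), `heights` (matching vector,
#'   m) and `order` (the permutation of input indices applied).
#' @export
order_layers <- function(cnpy) {
  stopifnot(inherits(cnpy, "canopy"))
  n <- length(cnpy$cohorts)
  if (n == 0L) {
    return(list(cohorts = list(), heights = numeric(0), order = integer(0)))
  }
  h <- vapply(cnpy$cohorts, cohort_height_of, numeric(1))
  idx <- order(-h)              # base::order is stable: ties keep input order
  list(cohorts = cnpy$cohorts[idx], heights = h[idx], order = idx)
}

# ---- CSV interface --------------------------------------------------------

#' Read and write canopy description CSVs
#'
#' The canopy CSV has header `pft,dbh_cm,stem_density,lai`; `lai` may be blank
#' for biomass-derived cohorts.  Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param pfts named list of `pft_params` to resolve labels against.
#' @param soil_albedo_par,soil_albedo_nir soil albedos for the returned canopy.
#' @return `read_canopy_csv()` returns a `canopy`; `write_canopy_csv()`
#'   returns `path` invisibly.
#' @export
read_canopy_csv <- function(path, pfts = default_pfts(),
                            soil_albedo_par = 0.25, soil_albedo_nir = 0.39) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pft", "dbh_cm", "stem_density", "lai")
  if (!all(need %in% names(df))) {
    stop("canopy CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  cohorts <- lapply(seq_len(nrow(df)), function(i) {
    lab <- df$pft[i]
    if (!lab %in% names(pfts)) {
      stop("unknown PFT label '", lab, "' in ", path, call. = FALSE)
    }
    lai <- df$lai[i]
    if (is.na(lai)) {
      p <- pfts[[lab]]
      cohort(p, df$dbh_cm[i], df$stem_density[i],
             leaf_biomass = p$bleaf_b1 * df$dbh_cm[i]^p$bleaf_b2)
    } else {
      cohort(pfts[[lab]], df$dbh_cm[i], df$stem_density[i], lai = lai)
    }
  })
  canopy(cohorts, soil_albedo_par, soil_albedo_nir)
}

#' @param cnpy a `canopy` to write.
#' @rdname read_canopy_csv
#' @export
write_canopy_csv <- function(cnpy, path) {
  stopifnot(inherits(cnpy, "canopy"))
  df <- data.frame(
    pft = vapply(cnpy$cohorts, function(co) co$pft$pft_label, character(1)),
    dbh_cm = vapply(cnpy$cohorts, function(co) co$dbh, numeric(1)),
    stem_density = vapply(cnpy$cohorts, function(co) co$stem_density,
                          numeric(1)),
    lai = vapply(cnpy$cohorts, function(co) {
      if (is.null(co$lai_override)) NA_real_ else co$lai_override
    }, numeric(1))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
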