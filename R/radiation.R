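#' Solve one band for a whole canopy
#'
#' Orders the canopy into layers (tallest first), builds per-layer optics and
#' runs [solve_profile()].
#'
#' @param cnpy a `canopy`.
#' @param forcing a [band_forcing()].
#' @param backscatter_sign passed to [build_layer_optics()].
#' @param solver `"linear"` (direct solve, default) or `"neumann"` (the
#'   successive-orders verification solver).
#' @return an `rtm_result` with an additional `layer_order` field: the input
#'   cohort index of each solver layer.
#' @export
solve_canopy_band <- function(cnpy, forcing,
                              backscatter_sign = c("as_printed", "literature"),
                              solver = c("linear", "neumann")) {
  backscatter_sign <- match.arg(backscatter_sign)
  solver <- match.arg(solver)
  stopifnot(inherits(cnpy, "canopy"))
  soil <- if (forcing$band == "par") cnpy$soil_albedo_par else
    cnpy$soil_albedo_nir
  lay <- order_layers(cnpy)
  optics <- lapply(lay$cohorts, build_layer_optics, band = forcing$band,
                   cos_zenith = forcing$cos_zenith,
                   backscatter_sign = backscatter_sign)
  res <- if (solver == "linear") {
    solve_profile(optics, forcing, soil)
  } else {
    solve_profile_neumann(optics, forcing, soil)
  }
  res$layer_order <- lay$order
  res
}

#' Canopy radiation summary for one forcing condition
#'
#' Solves both bands and returns the quantities the uncertainty analysis
#' works with: per-band and total albedo, total fraction of absorbed PAR, and
#' fAPAR per cohort (reported in the canopy's input cohort order).
#'
#' @param cnpy a `canopy`.
#' @param direct_par,diffuse_par,direct_nir,diffuse_nir incident fluxes,
#'   W/m2.
#' @param cos_zenith cosine of solar zenith (needed when any direct flux is
#'   positive).
#' @param backscatter_sign passed to [build_layer_optics()].
#' @return a list with `albedo_par`, `albedo_nir`, `albedo_total`,
#'   `fapar_total`, `fapar_cohort` (named vector, input order), and the two
#'   `rtm_result` objects (`result_par`, `result_nir`).
#' @export
canopy_radiation <- function(cnpy, direct_par, diffuse_par, direct_nir,
                             diffuse_nir, cos_zenith = NA,
                             backscatter_sign = c("as_printed",
                                                  "literature")) {
  backscatter_sign <- match.arg(backscatter_sign)
  fp <- band_forcing("par", direct_par, diffuse_par, cos_zenith)
  fn <- band_forcing("nir", direct_nir, diffuse_nir, cos_zenith)
  rp <- solve_canopy_band(cnpy, fp, backscatter_sign)
  rn <- solve_canopy_band(cnpy, fn, backscatter_sign)
  fap_layer <- fapar_per_cohort(rp)
  fap <- numeric(length(fap_layer))
  fap[rp$layer_order] <- fap_layer      # back to input cohort order
  names(fap) <- if (length(fap)) paste0("fapar_cohort_", seq_along(fap))
  list(albedo_par = rp$albedo,
       albedo_nir = rn$albedo,
       albedo_total = canopy_albedo_total(rp, rn),
       fapar_total = sum(fap_layer),
       fapar_cohort = fap,
       result_par = rp, result_nir = rn)
}

#' Flatten a radiation summary into named outputs
#'
#' Helper used by the sweep machinery: one named numeric vector with
#' `albedo_par`, `albedo_nir`, `albedo_total`, `fapar_total` and one
#' `fapar_cohort_i` per cohort.
#'
#' @param rad result of [canopy_radiation()].
#' @return named numeric vector.
#' @export
radiation_outputs <- function(rad) {
  c(albedo_par = rad$albedo_par, albedo_nir = rad$albedo_nir,
    albedo_total = rad$albedo_total, fapar_total = rad$fapar_total,
    rad$fapar_cohort)
}

#' Evaluate canopy radiation over a forcing series
#'
#' Solves every row of a forcing table and returns one result row per time
#' step plus flux-weighted aggregate outputs.  Rows with zero total incident
#' flux (night) contribute zero weight to the aggregates.
#'
#' @param cnpy a `canopy`.
#' @param forcing data frame with columns `time`, `direct_par`,
#'   `diffuse_par`, `direct_nir`, `diffuse_nir`, `cos_zenith` (see
#'   [synthetic_forcing()] / [read_forcing_csv()]).
#' @param backscatter_sign passed down.
#' @return list with `per_step` (data frame of outputs per time) and
#'   `aggregate` (named vector: incident-weighted means).
#' @export
canopy_radiation_series <- function(cnpy, forcing,
                                    backscatter_sign = c("as_printed",
                                                         "literature")) {
  backscatter_sign <- match.arg(backscatter_sign)
  rows <- lapply(seq_len(nrow(forcing)), function(i) {
    fr <- forcing[i, ]
    rad <- canopy_radiation(cnpy, fr$direct_par, fr$diffuse_par,
                            fr$direct_nir, fr$diffuse_nir,
                            if (fr$cos_zenith > 0) fr$cos_zenith else NA,
                            backscatter_sign)
    out <- radiation_outputs(rad)
    c(time = fr$time,
      incident = fr$direct_par + fr$diffuse_par + fr$direct_nir +
        fr$diffuse_nir,
      incident_par = fr$direct_par + fr$diffuse_par, out)
  })
  per_step <- as.data.frame(do.call(rbind, rows))
  w <- per_step$incident
  wp <- per_step$incident_par
  out_cols <- setdiff(names(per_step), c("time", "incident", "incident_par"))
  agg <- vapply(out_cols, function(cn) {
    wt <- if (startsWith(cn, "fapar")) wp else w
    if (sum(wt) == 0) 0 else sum(per_step[[cn]] * wt) / sum(wt)
  }, numeric(1))
  list(per_step = per_step, aggregate = agg)
}

#' Read and write radiation forcing CSVs
#'
#' Columns: `time`, `direct_par`, `diffuse_par`, `direct_nir`, `diffuse_nir`
#' (W/m2) and `cos_zenith` (dimensionless).  `#` comment lines are ignored.
#'
#' @param path file path.
#' @return `read_forcing_csv()` returns the forcing data frame;
#'   `write_forcing_csv()` returns `path` invisibly.
#' @export
read_forcing_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time", "direct_par", "diffuse_par", "direct_nir", "diffuse_nir",
            "cos_zenith")
  if (!all(need %in% names(df))) {
    stop("forcing CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (any(df$cos_zenith <= 0 & (df$direct_par > 0 | df$direct_nir > 0))) {
    stop("direct flux must be zero when cos_zenith <= 0", call. = FALSE)
  }
  df
}

#' @param forcing forcing data frame to write.
#' @rdname read_forcing_csv
#' @export
write_forcing_csv <- function(forcing, path) {
  utils::write.csv(forcing, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
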