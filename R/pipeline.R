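#' Run configuration
#'
#' Assembles and validates the settings of a pipeline run: the canopy source
#' (a fixture name or a canopy CSV path), the forcing, the priors file, and
#' the sensitivity-analysis settings.  Fixture names: `single_early`,
#' `single_mid`, `single_late`, `eml`, `mle`, `willow_creek`.
#'
#' @param canopy fixture name or path to a canopy CSV.
#' @param out_dir output directory (created if missing).
#' @param forcing_mode `"snapshot"` or `"series"`.
#' @param day_of_year,n_steps synthetic forcing settings.
#' @param forcing_csv optional path to a forcing CSV (overrides the synthetic
#'   generator).
#' @param priors_csv optional path to a priors CSV (defaults to the bundled
#'   table).
#' @param n_mc,seed sensitivity-analysis settings.
#' @param outputs output names for the SA, `NULL` for all.
#' @param backscatter_sign two-stream sign convention switch.
#' @return a validated `run_config` list.
#' @export
run_config <- function(canopy = "single_early", out_dir = ".",
                       forcing_mode = c("snapshot", "series"),
                       day_of_year = 172, n_steps = 48, forcing_csv = NULL,
                       priors_csv = NULL, n_mc = 10000L, seed = 1L,
                       outputs = NULL,
                       backscatter_sign = c("as_printed", "literature")) {
  forcing_mode <- match.arg(forcing_mode)
  backscatter_sign <- match.arg(backscatter_sign)
  fixtures <- c("single_early", "single_mid", "single_late", "eml", "mle",
                "willow_creek")
  if (!canopy %in% fixtures && !file.exists(canopy)) {
    stop("canopy must be a fixture name (", paste(fixtures, collapse = ", "),
         ") or an existing CSV path", call. = FALSE)
  }
  if (!is.null(forcing_csv) && !file.exists(forcing_csv)) {
    stop("forcing_csv does not exist: ", forcing_csv, call. = FALSE)
  }
  if (!is.null(priors_csv) && !file.exists(priors_csv)) {
    stop("priors_csv does not exist: ", priors_csv, call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0) stop("seed must be a non-negative integer",
                                    call. = FALSE)
  structure(list(canopy = canopy, out_dir = out_dir,
                 forcing_mode = forcing_mode, day_of_year = day_of_year,
                 n_steps = n_steps, forcing_csv = forcing_csv,
                 priors_csv = priors_csv, n_mc = as.integer(n_mc),
                 seed = seed, outputs = outputs,
                 backscatter_sign = backscatter_sign),
            class = "run_config")
}

config_canopy <- function(config) {
  switch(config$canopy,
         single_early = make_single_cohort_canopy("early"),
         single_mid = make_single_cohort_canopy("mid"),
         single_late = make_single_cohort_canopy("late"),
         eml = make_mixed_canopy("EML"),
         mle = make_mixed_canopy("MLE"),
         willow_creek = load_willow_creek(),
         read_canopy_csv(config$canopy))
}

config_forcing <- function(config) {
  if (!is.null(config$forcing_csv)) return(read_forcing_csv(config$forcing_csv))
  if (config$forcing_mode == "snapshot") {
    noon_snapshot(config$day_of_year)
  } else {
    synthetic_forcing(config$day_of_year, config$n_steps)
  }
}

config_priors <- function(config) {
  if (is.null(config$priors_csv)) default_priors()
  else read_priors(config$priors_csv)
}

# config hash + run metadata appended to <out_dir>/run_log.txt
log_run <- function(config, what) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  hash <- unname(tools::md5sum(tf))
  line <- sprintf("%s command=%s config_md5=%s seed=%d version=%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), what, hash,
                  config$seed,
                  as.character(utils::packageVersion("canopyrt")))
  cat(line, "\n", file = file.path(config$out_dir, "run_log.txt"),
      append = TRUE)
  invisible(hash)
}

#' Radiation pipeline: solve a configured canopy and write result CSVs
#'
#' Solves the configured canopy under the configured forcing and writes
#' `rtm_layers.csv` (one row per time step and cohort with the absorbed flux
#' per band) and `rtm_summary.csv` (per-band albedos, total albedo, soil
#' absorption and fAPAR per cohort, one row per time step).
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the two data frames and their paths.
#' @export
pipeline_rtm <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_run(config, "rtm")
  cnpy <- config_canopy(config)
  forcing <- config_forcing(config)
  n_coh <- length(cnpy$cohorts)
  layer_rows <- list()
  summary_rows <- list()
  for (i in seq_len(nrow(forcing))) {
    fr <- forcing[i, ]
    rad <- canopy_radiation(cnpy, fr$direct_par, fr$diffuse_par,
                            fr$direct_nir, fr$diffuse_nir,
                            if (fr$cos_zenith > 0) fr$cos_zenith else NA,
                            config$backscatter_sign)
    ord <- rad$result_par$layer_order
    abs_par <- abs_nir <- numeric(n_coh)
    abs_par[ord] <- rad$result_par$absorbed_per_layer
    abs_nir[ord] <- rad$result_nir$absorbed_per_layer
    if (n_coh > 0) {
      layer_rows[[i]] <- data.frame(
        time = fr$time, cohort = seq_len(n_coh),
        pft = vapply(cnpy$cohorts, function(co) co$pft$pft_label,
                     character(1)),
        absorbed_par = abs_par, absorbed_nir = abs_nir,
        fapar = as.numeric(rad$fapar_cohort))
    }
    summary_rows[[i]] <- data.frame(
      time = fr$time, albedo_par = rad$albedo_par,
      albedo_nir = rad$albedo_nir, albedo_total = rad$albedo_total,
      fapar_total = rad$fapar_total,
      soil_absorbed_par = rad$result_par$soil_absorbed,
      soil_absorbed_nir = rad$result_nir$soil_absorbed)
  }
  layers <- if (length(layer_rows)) do.call(rbind, layer_rows) else
    data.frame()
  summary <- do.call(rbind, summary_rows)
  layers_path <- file.path(config$out_dir, "rtm_layers.csv")
  summary_path <- file.path(config$out_dir, "rtm_summary.csv")
  utils::write.csv(layers, layers_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(summary, summary_path, row.names = FALSE, quote = FALSE)
  invisible(list(layers = layers, summary = summary,
                 layers_path = layers_path, summary_path = summary_path))
}

#' Sensitivity-analysis pipeline
#'
#' Runs [run_full_sa()] on the configured canopy and writes `sa_results.csv`
#' plus a human-readable `sa_ranking.txt` of parameters ranked by
#' median-normalized standard deviation per output and PFT.  Deterministic
#' for a fixed config and seed.
#'
#' @param config a [run_config()].
#' @return invisibly, the `sa_result` data frame.
#' @export
pipeline_sa <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_run(config, "sa")
  cnpy <- config_canopy(config)
  forcing <- config_forcing(config)
  res <- run_full_sa(cnpy, forcing, config_priors(config),
                     outputs = config$outputs, n_mc = config$n_mc,
                     seed = config$seed, forcing_mode = config$forcing_mode,
                     backscatter_sign = config$backscatter_sign)
  csv_path <- file.path(config$out_dir, "sa_results.csv")
  df <- as.data.frame(res)
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) signif(col, 10) else col
  })
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  txt <- file.path(config$out_dir, "sa_ranking.txt")
  con <- file(txt, "w")
  for (out in unique(res$output)) {
    for (p in unique(res$pft)) {
      sub <- res[res$output == out & res$pft == p, ]
      sub <- sub[order(-sub$normalized_sd), ]
      cat(sprintf("== %s / PFT %s ==\n", out, p), file = con)
      for (i in seq_len(nrow(sub))) {
        cat(sprintf("  %-7s normalized_sd=%.6g elasticity=%.6g\n",
                    sub$parameter[i], sub$normalized_sd[i],
                    sub$elasticity[i]), file = con)
      }
    }
  }
  close(con)
  invisible(res)
}

#' Solver cross-validation pipeline
#'
#' Runs the direct linear solver and the successive-orders oracle on the
#' configured canopy for every step of the configured forcing and both
#' bands, and reports the maximum relative discrepancy in albedo and
#' per-layer absorption.
#'
#' @param config a [run_config()].
#' @param tol failure threshold on the relative discrepancy.
#' @param corrupt internal test hook; if `TRUE`, perturbs the oracle's
#'   coefficients to exercise the failure path.
#' @return invisibly, a list with `max_discrepancy` and `ok`; signals an
#'   error when the discrepancy exceeds `tol`.
#' @export
pipeline_validate <- function(config, tol = 1e-6, corrupt = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_run(config, "validate")
  cnpy <- config_canopy(config)
  forcing <- config_forcing(config)
  max_d <- 0
  for (i in seq_len(nrow(forcing))) {
    fr <- forcing[i, ]
    for (band in c("par", "nir")) {
      dirf <- fr[[paste0("direct_", band)]]
      diff <- fr[[paste0("diffuse_", band)]]
      if (dirf + diff == 0) next
      bf <- band_forcing(band, dirf, diff,
                         if (fr$cos_zenith > 0) fr$cos_zenith else NA)
      a <- solve_canopy_band(cnpy, bf, config$backscatter_sign, "linear")
      b <- solve_canopy_band(cnpy, bf, config$backscatter_sign, "neumann")
      if (corrupt) b$albedo <- b$albedo + 1e-3
      scale <- max(a$incident, 1e-12)
      d <- max(abs(a$albedo - b$albedo),
               if (length(a$absorbed_per_layer)) {
                 max(abs(a$absorbed_per_layer - b$absorbed_per_layer)) / scale
               } else 0)
      max_d <- max(max_d, d)
    }
  }
  ok <- max_d <= tol
  cat(sprintf("max relative solver discrepancy: %.3e (%s)\n", max_d,
              if (ok) "OK" else "FAIL"))
  if (!ok) {
    stop("solver cross-validation failed: max discrepancy ",
         format(max_d, digits = 3), " > ", tol, call. = FALSE)
  }
  invisible(list(max_discrepancy = max_d, ok = ok))
}

#' Write the bundled canopy fixtures as CSVs
#'
#' Exports each named fixture canopy into `out_dir` as a canopy CSV.
#'
#' @param out_dir output directory.
#' @return invisibly, the named vector of written paths.
#' @export
write_fixture_csvs <- function(out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fixtures <- list(
    single_early = make_single_cohort_canopy("early"),
    single_mid = make_single_cohort_canopy("mid"),
    single_late = make_single_cohort_canopy("late"),
    eml = make_mixed_canopy("EML"),
    mle = make_mixed_canopy("MLE"),
    willow_creek = load_willow_creek()
  )
  paths <- vapply(names(fixtures), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_canopy_csv(fixtures[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
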