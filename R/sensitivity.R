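#' Univariate quantile sweep of a model
#'
#' Evaluates a deterministic model at the five Gaussian-SD-equivalent
#' quantiles of one parameter's prior for one PFT, holding every other
#' parameter of every PFT at its prior median.  The middle grid point is the
#' all-medians baseline and is evaluated once and reused, so it is
#' bit-identical to the baseline run.
#'
#' @param model_fn function mapping a parameter set (see
#'   [median_parameter_set()]) to a named numeric vector of outputs.
#' @param pset_median the all-medians parameter set.
#' @param target_parameter name of the swept parameter.
#' @param target_pft PFT whose parameter is varied.
#' @param prior the `prior_spec` of the swept parameter.
#' @return a `sweep_result`: list with `parameter`, `pft`, `probs`, `values`
#'   (5 parameter values), `outputs` (5 x n_outputs matrix) and `baseline`
#'   (named vector).
#' @export
univariate_sweep <- function(model_fn, pset_median, target_parameter,
                             target_pft, prior) {
  grid <- quantile_grid(prior)
  probs <- attr(grid, "probs")
  baseline <- model_fn(pset_median)
  outputs <- matrix(NA_real_, nrow = 5, ncol = length(baseline),
                    dimnames = list(names(grid), names(baseline)))
  for (i in seq_len(5)) {
    if (i == 3L) {
      outputs[i, ] <- baseline        # middle point IS the baseline
      next
    }
    pset <- pset_median
    pset[[target_pft]][[target_parameter]] <- grid[[i]]
    out <- tryCatch(model_fn(pset), error = function(e) {
      stop("model evaluation failed in sweep of ", target_parameter, " (",
           target_pft, ") at ", names(grid)[i], " = ", signif(grid[[i]], 6),
           ": ", conditionMessage(e), call. = FALSE)
    })
    outputs[i, ] <- out
  }
  structure(list(parameter = target_parameter, pft = target_pft,
                 probs = probs, values = as.numeric(grid),
                 outputs = outputs, baseline = baseline),
            class = "sweep_result")
}

#' Fit the univariate response emulator
#'
#' Natural cubic spline interpolating the five sweep points exactly;
#' evaluable anywhere on the prior support (linear extrapolation beyond the
#' grid, the natural-spline boundary behaviour).  The returned function
#' accepts a `deriv` argument (0 or 1) with an analytic first derivative.
#'
#' @param sweep a `sweep_result`, or a numeric vector of abscissae.
#' @param output which output column to emulate (name or index) when `sweep`
#'   is a `sweep_result`.
#' @param y ordinates when `sweep` is given as a numeric vector.
#' @return function `f(x, deriv = 0)`.
#' @export
fit_emulator <- function(sweep, output = 1L, y = NULL) {
  if (inherits(sweep, "sweep_result")) {
    x <- sweep$values
    y <- sweep$outputs[, output]
  } else {
    x <- as.numeric(sweep)
  }
  if (anyDuplicated(x)) {
    stop("duplicate sweep abscissae; emulator requires distinct parameter ",
         "values", call. = FALSE)
  }
  stats::splinefun(x, y, method = "natural")
}

#' Elasticity of an emulated response
#'
#' Normalized sensitivity at the prior median `m`:
#' `elasticity = f'(m) * m / f(m)`, using the spline's analytic derivative.
#' Undefined (flagged `NA`) when the baseline output is zero.
#'
#' @param emulator function from [fit_emulator()].
#' @param prior the swept parameter's `prior_spec`.
#' @param baseline_output model output at the all-medians baseline; defaults
#'   to `emulator(median)`.
#' @return dimensionless elasticity, or flagged `NA`.
#' @export
elasticity <- function(emulator, prior, baseline_output = NULL) {
  m <- prior_median(prior)
  if (is.null(baseline_output)) baseline_output <- emulator(m)
  if (baseline_output == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  emulator(m, deriv = 1) * m / baseline_output
}

#' Partial variance of the output attributable to one parameter
#'
#' The sample variance of the emulated response over `n` seeded draws from
#' the parameter's prior: the univariate (main-effect) contribution of that
#' parameter's uncertainty to output variance.
#'
#' @param emulator function from [fit_emulator()].
#' @param prior the parameter's `prior_spec`.
#' @param n number of Monte Carlo draws (>= 1000).
#' @param seed integer seed.
#' @return partial variance in squared output units.
#' @export
variance_decomposition <- function(emulator, prior, n = 10000L, seed = 1L) {
  stopifnot(n >= 1000)
  draws <- sample_prior(prior, n, seed)
  stats::var(emulator(draws))
}

#' Full sensitivity / uncertainty analysis of canopy radiation
#'
#' Runs the complete univariate uncertainty-quantification procedure on a
#' canopy: for every radiative parameter and every PFT present in the canopy,
#' sweep the parameter over its five prior quantiles (all else at medians),
#' emulate each output's response with a natural cubic spline, and report
#' sensitivity (derivative at the median), elasticity, the prior CV, partial
#' variance, and the median-normalized standard deviation
#' `sqrt(partial_variance) / |baseline|`.
#'
#' By default outputs are evaluated at a solar-noon snapshot of the synthetic
#' forcing; with `forcing_mode = "series"` they are incident-flux-weighted
#' means over a forcing time series.
#'
#' @param cnpy a `canopy`.
#' @param forcing one-row (snapshot) or multi-row (series) forcing data
#'   frame; default [noon_snapshot()].
#' @param priors named list of `prior_spec`.
#' @param outputs output names to analyze; default all of
#'   [radiation_outputs()].
#' @param n_mc Monte Carlo draws for the variance decomposition.
#' @param seed master seed; each (parameter, PFT) pair derives a fixed
#'   sub-seed, so results are reproducible.
#' @param forcing_mode `"snapshot"` or `"series"`.
#' @param backscatter_sign passed to the solver.
#' @return an `sa_result` data frame with columns `output`, `parameter`,
#'   `pft`, `sensitivity`, `elasticity`, `cv`, `partial_variance`,
#'   `normalized_sd`, `baseline`, sorted by decreasing `normalized_sd` within
#'   each output.
#' @export
run_full_sa <- function(cnpy, forcing = noon_snapshot(),
                        priors = default_priors(), outputs = NULL,
                        n_mc = 10000L, seed = 1L,
                        forcing_mode = c("snapshot", "series"),
                        backscatter_sign = c("as_printed", "literature")) {
  forcing_mode <- match.arg(forcing_mode)
  backscatter_sign <- match.arg(backscatter_sign)
  stopifnot(inherits(cnpy, "canopy"), length(cnpy$cohorts) > 0)
  pft_labels <- unique(vapply(cnpy$cohorts, function(co) co$pft$pft_label,
                              character(1)))
  if (forcing_mode == "snapshot" && nrow(forcing) != 1L) {
    forcing <- forcing[which.max(forcing$cos_zenith), , drop = FALSE]
  }

  model_fn <- function(pset) {
    cn <- apply_parameter_set(cnpy, pset)
    if (forcing_mode == "snapshot") {
      fr <- forcing[1, ]
      radiation_outputs(canopy_radiation(
        cn, fr$direct_par, fr$diffuse_par, fr$direct_nir, fr$diffuse_nir,
        if (fr$cos_zenith > 0) fr$cos_zenith else NA, backscatter_sign))
    } else {
      canopy_radiation_series(cn, forcing, backscatter_sign)$aggregate
    }
  }

  pset_median <- median_parameter_set(priors, pft_labels)
  baseline <- model_fn(pset_median)
  if (is.null(outputs)) outputs <- names(baseline)
  outputs <- intersect(outputs, names(baseline))

  rows <- list()
  k <- 0L
  for (pft in pft_labels) {
    for (pname in names(priors)) {
      k <- k + 1L
      prior <- priors[[pname]]
      sw <- univariate_sweep(model_fn, pset_median, pname, pft, prior)
      cv <- coefficient_of_variation(prior)
      m <- prior_median(prior)
      sub_seed <- (seed + 7919L * k) %% .Machine$integer.max
      for (out in outputs) {
        em <- fit_emulator(sw, out)
        pv <- variance_decomposition(em, prior, n_mc, sub_seed)
        base <- sw$baseline[[out]]
        rows[[length(rows) + 1L]] <- data.frame(
          output = out, parameter = pname, pft = pft,
          sensitivity = em(m, deriv = 1),
          elasticity = as.numeric(elasticity(em, prior, base)),
          cv = as.numeric(cv),
          partial_variance = pv,
          normalized_sd = if (base != 0) sqrt(pv) / abs(base) else NA_real_,
          baseline = base,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$output, -res$normalized_sd), ]
  rownames(res) <- NULL
  class(res) <- c("sa_result", "data.frame")
  res
}

#' @export
print.sa_result <- function(x, ...) {
  cat("<sa_result>", nrow(x), "rows;",
      length(unique(x$parameter)), "parameters x",
      length(unique(x$pft)), "PFT(s) x", length(unique(x$output)),
      "output(s)\n")
  NextMethod()
}

#' Bar-style summary plot of a sensitivity analysis
#'
#' Horizontal bars of median-normalized standard deviation per parameter,
#' one panel per PFT, for one output.  Purely diagnostic.
#'
#' @param x an `sa_result`.
#' @param output which output to plot.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the subset plotted.
#' @export
plot_sa <- function(x, output = "albedo_total", ...) {
  sub <- x[x$output == output, ]
  pfts <- unique(sub$pft)
  op <- graphics::par(mfrow = c(1, length(pfts)), mar = c(4, 6, 2, 1))
  on.exit(graphics::par(op))
  for (p in pfts) {
    s <- sub[sub$pft == p, ]
    graphics::barplot(rev(s$normalized_sd), names.arg = rev(s$parameter),
                      horiz = TRUE, las = 1, main = paste(output, "-", p),
                      xlab = "normalized SD", ...)
  }
  invisible(sub)
}
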