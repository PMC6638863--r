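#' Prior distributions for the radiative parameters
#'
#' A `prior_spec` names one of the ten radiative parameters and its prior
#' distribution: `uniform` (p1 = lower, p2 = upper) or `lognormal`
#' (p1 = log-mean, p2 = log-sd, natural-log scale).  The same priors are used
#' for every PFT.
#'
#' @param name parameter identifier; one of `cf`, `of`, `LT_PAR`, `LR_PAR`,
#'   `LT_NIR`, `LR_NIR`, `WT_PAR`, `WR_PAR`, `WT_NIR`, `WR_NIR`.
#' @param family `"uniform"` or `"lognormal"`.
#' @param p1,p2 family parameters.
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(name, family = c("uniform", "lognormal"), p1, p2) {
  family <- match.arg(family)
  name <- match.arg(name, radiative_parameter_names())
  if (family == "uniform" && !(p1 < p2)) {
    stop("uniform prior requires p1 < p2", call. = FALSE)
  }
  if (family == "lognormal" && !(p2 > 0)) {
    stop("lognormal prior requires p2 > 0", call. = FALSE)
  }
  structure(list(name = name, family = family, p1 = p1, p2 = p2),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec>", x$name, " ", x$family, "(", x$p1, ", ", x$p2, ")\n",
      sep = "")
  invisible(x)
}

#' Names of the ten radiative parameters
#'
#' `cf` clumping factor, `of` orientation factor, and reflectance (`R`) /
#' transmittance (`T`) of leaf (`L`) and wood (`W`) in the PAR and NIR bands.
#'
#' @return character vector of length 10.
#' @export
radiative_parameter_names <- function() {
  c("cf", "of", "LT_PAR", "LR_PAR", "LT_NIR", "LR_NIR",
    "WT_PAR", "WR_PAR", "WT_NIR", "WR_NIR")
}

#' Read priors from a configuration file
#'
#' The file is a CSV with columns `name,family,p1,p2` (lines starting with
#' `#` ignored); `default_priors()` loads the bundled table of the ten
#' radiative parameter priors.
#'
#' @param path CSV path.
#' @return a named list of `prior_spec`.
#' @export
read_priors <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    prior_spec(df$name[i], df$family[i], df$p1[i], df$p2[i])
  })
  names(out) <- df$name
  out
}

#' @rdname read_priors
#' @export
default_priors <- function() {
  read_priors(system.file("extdata", "radiative_priors.csv",
                          package = "canopyrt", mustWork = TRUE))
}

#' Prior quantile function, median and moments
#'
#' @param prior a `prior_spec`.
#' @param p probabilities.
#' @return quantiles of the prior at `p`.
#' @export
prior_quantile <- function(prior, p) {
  stopifnot(inherits(prior, "prior_spec"))
  switch(prior$family,
         uniform = stats::qunif(p, prior$p1, prior$p2),
         lognormal = stats::qlnorm(p, prior$p1, prior$p2))
}

#' @rdname prior_quantile
#' @export
prior_median <- function(prior) prior_quantile(prior, 0.5)

prior_mean <- function(prior) {
  switch(prior$family,
         uniform = (prior$p1 + prior$p2) / 2,
         lognormal = exp(prior$p1 + prior$p2^2 / 2))
}

prior_sd <- function(prior) {
  switch(prior$family,
         uniform = (prior$p2 - prior$p1) / sqrt(12),
         lognormal = prior_mean(prior) * sqrt(exp(prior$p2^2) - 1))
}

#' Five-point Gaussian-SD-equivalent quantile grid
#'
#' Returns the prior quantiles at the probabilities corresponding to -2, -1,
#' 0, +1 and +2 Gaussian standard deviations (approximately 2.3%, 15.9%,
#' 50%, 84.1% and 97.7%).  These are the evaluation points of the univariate
#' parameter sweeps.
#'
#' @param prior a `prior_spec`.
#' @return named numeric vector of 5 strictly increasing parameter values,
#'   with attribute `probs` holding the probabilities.
#' @export
quantile_grid <- function(prior) {
  probs <- stats::pnorm(-2:2)
  q <- prior_quantile(prior, probs)
  if (any(diff(q) <= 0)) {
    stop("quantile grid is not strictly increasing for prior ", prior$name,
         call. = FALSE)
  }
  names(q) <- c("-2sd", "-1sd", "median", "+1sd", "+2sd")
  attr(q, "probs") <- probs
  q
}

#' Draw seeded samples from a prior
#'
#' @param prior a `prior_spec`.
#' @param n number of draws (>= 1).
#' @param seed integer seed; draws are reproducible for a fixed seed.
#' @return numeric vector of length `n`.
#' @export
sample_prior <- function(prior, n, seed) {
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
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
  switch(prior$family,
         uniform = stats::runif(n, prior$p1, prior$p2),
         lognormal = stats::rlnorm(n, prior$p1, prior$p2))
}

#' Coefficient of variation of a prior
#'
#' The prior standard deviation normalized by the prior mean; used to compare
#' the uncertainty of parameters living on different scales.  Closed form per
#' family: uniform `((b - a)/sqrt(12)) / ((a + b)/2)`; lognormal
#' `sqrt(exp(sigma^2) - 1)`.
#'
#' When the prior mean is within `1e-12` of zero (the orientation factor's
#' symmetric prior) the ratio is unstable and `NA` is returned with attribute
#' `undefined = TRUE`.
#'
#' @param prior a `prior_spec`.
#' @return dimensionless CV, or flagged `NA` when undefined.
#' @export
coefficient_of_variation <- function(prior) {
  m <- prior_mean(prior)
  if (abs(m) < 1e-12) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  prior_sd(prior) / m
}

#' Parameter sets: concrete values for every PFT
#'
#' A parameter set maps each PFT label to named values of the ten radiative
#' parameters.  `median_parameter_set()` builds the all-medians baseline;
#' `apply_parameter_set()` returns a copy of a canopy whose PFT radiative
#' fields are overridden by the set.
#'
#' @param priors named list of `prior_spec` (defaults to the bundled table).
#' @param pft_labels PFT labels to include.
#' @return a named list (per PFT) of named numeric vectors.
#' @export
median_parameter_set <- function(priors = default_priors(),
                                 pft_labels = c("early", "mid", "late")) {
  med <- vapply(priors, prior_median, numeric(1))
  stats::setNames(lapply(pft_labels, function(l) med), pft_labels)
}

# parameter-name -> pft_params field mapping
.param_field <- c(cf = "clumping", of = "orientation",
                  LT_PAR = "leaf_t_par", LR_PAR = "leaf_r_par",
                  LT_NIR = "leaf_t_nir", LR_NIR = "leaf_r_nir",
                  WT_PAR = "wood_t_par", WR_PAR = "wood_r_par",
                  WT_NIR = "wood_t_nir", WR_NIR = "wood_r_nir")

#' @param cnpy a `canopy`.
#' @param pset a parameter set as returned by [median_parameter_set()].
#' @rdname median_parameter_set
#' @export
apply_parameter_set <- function(cnpy, pset) {
  stopifnot(inherits(cnpy, "canopy"))
  cnpy$cohorts <- lapply(cnpy$cohorts, function(co) {
    vals <- pset[[co$pft$pft_label]]
    if (is.null(vals)) return(co)
    for (nm in names(vals)) {
      fld <- .param_field[[nm]]
      if (is.null(fld)) stop("unknown radiative parameter '", nm, "'",
                             call. = FALSE)
      co$pft[[fld]] <- vals[[nm]]
    }
    co$pft <- validate_pft_params(co$pft)
    co
  })
  cnpy
}
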