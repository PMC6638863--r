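# shared test helpers: hand-built layer optics and a reference PFT

make_layer <- function(tai, scatter, backscatter, k_direct = NA,
                       mu_bar = 1) {
  structure(list(tai = tai, scatter = scatter, backscatter = backscatter,
                 orientation = 0, k_direct = k_direct, mu_bar = mu_bar),
            class = "layer_optics")
}

# a pft_params with fully controlled fields (overrides on top of defaults);
# rebuilding through the constructor re-runs the invariant checks
test_pft <- function(label = "early", ...) {
  p <- unclass(default_pfts()[[label]])
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  do.call(pft_params, p)
}

# full default PFT list with overrides applied to one label
pfts_with <- function(label = "early", ...) {
  pfts <- default_pfts()
  pfts[[label]] <- test_pft(label, ...)
  pfts
}

# energy-closure residual relative to incident
closure_residual <- function(res) {
  if (res$incident == 0) return(0)
  abs(res$incident - sum(res$absorbed_per_layer) - res$soil_absorbed -
        res$reflected) / res$incident
}

# max relative discrepancy between two rtm_results
solver_discrepancy <- function(a, b) {
  scale <- max(a$incident, 1e-12)
  d <- abs(a$albedo - b$albedo)
  if (length(a$absorbed_per_layer)) {
    d <- max(d, max(abs(a$absorbed_per_layer - b$absorbed_per_layer)) / scale,
             abs(a$soil_absorbed - b$soil_absorbed) / scale)
  }
  d
}
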