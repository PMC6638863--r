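---
title: "Methods: cohort two-stream radiation and parameter uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort two-stream radiation and parameter uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyrt)
```

## Scope and assumptions

`canopyrt` models the interaction of broadband shortwave radiation (two
channels: PAR and NIR) with a one-dimensional, height-structured forest
canopy. The canopy is a stack of horizontally homogeneous layers, one per
cohort; there is no horizontal heterogeneity, no hot-spot effect, and no
within-crown structure. Canopies are static snapshots: no growth, mortality
or succession. Longwave radiation and the surface energy balance are out of
scope — the package stops at the radiation profile (albedo, per-layer
absorption, soil absorption).

The turbid-medium assumptions of the two-stream family apply: scattering
elements are small, non-overlapping, and randomly distributed within a
layer, with two geometric corrections — a clumping factor Ω that deflates
leaf area to an effective LAI, and an orientation factor that tilts the mean
leaf-projection geometry.

## Geometry

Per cohort: LAI = SLA · N · B (or a direct LAI override), WAI = N · b₁ ·
DBH^b₂, eLAI = Ω · LAI, TAI = eLAI + WAI, and height h = h_ref + b₁ (1 −
exp(b₂ DBH)). Clumping applies to leaves only: wood area enters TAI
unweighted, because stem aggregation is a property of stem placement the 1-D
scheme cannot resolve. Layers are ordered tallest first; equal heights keep
the input order (a deterministic, stable tie-break).

The bundled PFT configuration ships plausible temperate-hardwood allometric
constants, calibrated to two structural facts the fixtures rely on: at
DBH 25 cm the early cohort out-tops mid, which out-tops late; shrinking the
early cohort to DBH 20 cm demotes it below both. They also make
biomass-derived LAI at DBH 25 cm ≈ 6 at the canonical single-cohort stem
densities (0.0851 / 0.0587 / 0.0682 stems m⁻²). The file
(`inst/extdata/pft_params.yaml`) is editable and round-trips through
`read_pft_config()` / `write_pft_config()`; all canonical fixtures pin LAI
directly, so the allometric placeholders never contaminate fixture results.

## Optics

Per tissue (leaf, wood) and band: single scattering a = t + r and
backscatter β = (a + 0.25 (t − r)) (1 + a_orient)² / (2a). Two deliberate
choices here:

- **Sign convention.** The difference term is implemented as (t − r); much
  of the two-stream literature uses (r − t). Both conventions are available
  (`backscatter_sign = "as_printed"` / `"literature"`); the default is the
  former, and the switch isolates the choice for anyone wanting to compare.
- **Clamping.** With the (1 + a_orient)² factor, β can exceed 1 for
  strongly horizontal leaves (a_orient ≳ 0.45 when t ≈ r, which the
  orientation prior's upper sweep quantiles reach). The raw coefficient
  function reports the formula value; layer assembly clamps the mixed layer
  coefficient into [0, 1], since a backscatter fraction is a probability.
  The clamp binds only at the extreme orientation quantiles.
- **Black tissue.** When a = 0 the ratio is undefined; the isotropic
  convention 0.5 (1 + a_orient)²/2 is substituted with a warning. It is
  irrelevant for absorption (nothing is scattered) and only stabilizes the
  mixing formula.

Leaf and wood mix by area for scattering, a = (eLAI·a_leaf + WAI·a_wood)/TAI,
and by scattered flux for backscatter, so that a black tissue cannot drag
the layer's backscatter towards its (physically inert) convention value.

Beam extinction per unit TAI is k = G(μ)/μ with the standard projection
polynomial G(μ) = φ₁ + φ₂μ, φ₁ = 0.5 − 0.633χ − 0.33χ², φ₂ = 0.877(1−2φ₁),
χ the orientation factor. The polynomial is nominally valid for
χ ∈ [−0.4, 0.6]; the orientation prior spans [−0.5, 0.5], so the lowest
sweep quantiles step slightly outside — values are evaluated as-is with a
warning. Diffuse radiation uses the average inverse optical depth
μ̄ = ∫₀¹ μ′/G(μ′) dμ′ (numerical quadrature, rel. tol 1e−10), giving layer
interception 1 − exp(−TAI/μ̄); for spherical orientation (χ = 0), μ̄ = 1.

## Solvers

Each layer interaction is: intercept (1 − exp(−TAI/μ̄) diffuse, or
1 − exp(−k·TAI) beam), scatter fraction a of the intercepted flux, of which
β reverses direction; the remainder is absorbed. The unintercepted beam
attenuates layer by layer and its scattered fraction feeds the diffuse
streams. The interface fluxes then satisfy a (2L+2)-equation linear system
(top boundary: incident diffuse; soil boundary: reflectance = soil albedo,
applied to both diffuse and surviving beam) solved by direct factorization.
Absorption per layer is the net flux divergence, which makes energy closure
exact to solver precision by construction.

The independent check, `solve_profile_neumann()`, never assembles the
system: it propagates flux bundles order by order (each bundle crosses one
layer per iteration, splitting into transmitted, backscattered and absorbed
parts; soil and sky are absorbing/reflecting terminals) until the
circulating flux drops below `tol · incident` (default 1e−12). Both solvers
share the per-interaction coefficients — they are the model definition — so
the comparison tests the solution method, and agreement to better than
1e−8 relative holds across randomized canopies.

Conventions for degenerate inputs: zero incident flux returns all-zero
fluxes with the albedo reported as the unit-diffuse-illumination limit; a
zero-TAI layer is transparent; direct flux with the sun at or below the
horizon is rejected at construction (`band_forcing()`).

## Priors and the sweep design

The ten radiative parameters share one prior table across PFTs
(`inst/extdata/radiative_priors.csv`): clumping Unif(0.4, 0.98), orientation
Unif(−0.5, 0.5), leaf optics lognormal on the natural-log scale (e.g. leaf
PAR transmittance Lognormal(−2.9176, 0.6729)), wood optics uniform. The
lognormal parameters are read as natural-log mean/sd — the shapes this
produces (right-skewed, medians well below 0.5) are the physically sensible
reading. Each prior's support is asserted inside its parameter's physical
bounds: [0, 1) for optical fractions, [−1, 1] for orientation.

Sweeps evaluate one parameter of one PFT at the prior quantiles matching −2,
−1, 0, +1, +2 Gaussian SDs (probabilities 2.275…%, 15.87…%, 50%, 84.13…%,
97.72…%), everything else at medians; the middle point is reused
bit-identically as the baseline. Parameter covariance is deliberately not
modelled — sweeps are univariate by design, so the variance decomposition
reports main effects only.

## Emulation and variance decomposition

The per-output response is emulated by a natural cubic spline through the
five sweep points (exact at the knots, linear extrapolation beyond them —
the natural boundary condition). Elasticity uses the spline's analytic
derivative at the prior median: f′(m)·m/f(m). The partial variance is the
sample variance of the spline over n seeded prior draws (default
n = 10,000; for linear responses this reduces to the closed-form prior
variance times the squared slope, which the tests verify to within Monte
Carlo error). The median-normalized standard deviation
√(partial variance)/|baseline| is the ranking statistic; it is invariant to
rescaling the output. The spline-over-prior-draws formulation was chosen
over a local CV × sensitivity product because the two coincide for linear
responses and the former remains meaningful for the visibly curved ones
(clumping, orientation).

Elasticity and CV are flagged `NA` (attribute `undefined`) where their
denominators vanish: the orientation prior's mean is 0, and a zero baseline
output admits no relative measure.

Outputs are evaluated by default on a solar-noon snapshot of the synthetic
forcing; `forcing_mode = "series"` averages outputs over a diurnal series
weighted by incident flux (PAR-incident for fAPAR outputs), so insensitive
night steps carry no weight.

## Synthetic forcing

The generator emulates a growing-season clear-sky diurnal cycle at the
Willow Creek latitude (45.8059° N): solar geometry from the standard
declination/hour-angle formulas, total shortwave S₀·τ·cosθ with S₀ = 1361
W m⁻² and τ = 0.75, split 50:50 PAR:NIR and 70:30 direct:diffuse (editable
defaults; these partitions are conventional mid-day clear-sky values, not
site measurements). A seed adds a smooth multiplicative cloudiness factor in
[0.4, 1]. What it does **not** emulate: measured meteorology, weather
systems, seasonal optical-depth variation, or spectral structure within the
two bands — so tests passing under this forcing demonstrate correctness of
the radiation scheme and the UQ machinery, not agreement with any observed
flux record.

## Problem sizes and tolerances

Default test and analysis sizes: 100 randomized canopies (1–8 cohorts) for
the conservation and solver-equivalence properties; n = 10,000 prior draws
per variance decomposition (1,000–2,000 in fast-running tests); 10⁵–10⁶
draws where closed forms are verified. Energy closure is asserted at
1e−9·incident (observed ~1e−16), solver equivalence at 1e−8 relative
(observed ~1e−13 at the default successive-orders tolerance of 1e−12). A
full sensitivity analysis of a three-cohort canopy takes on the order of a
second.

## Known limitations

- The discrete-layer treatment makes one whole cohort a single scattering
  step; a very thick single layer reflects at most its one-interaction
  backscatter from above, so the optically-thick limit differs from a
  continuous two-stream solution. Splitting cohorts into sub-layers would
  converge the two but is not implemented.
- The clumping factor scales optical depth identically for beam and diffuse
  streams; no separate beam-clumping treatment.
- One soil albedo per band serves both beam and diffuse at the surface.
- Orientation sweeps at extreme quantiles engage the β clamp and step
  slightly outside the projection polynomial's nominal range; both
  conditions are warned about and confined to those quantiles.
- The inventory fixture's realized layer order depends on the shipped
  height allometry, since the inventory lists no heights.
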