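---
title: "Modelling spatial recording effort with ignorance scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatial recording effort with ignorance scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ignorance)
```

## The score

Presence-only records carry no information about survey effort, so a cell
without records is ambiguous: truly empty, or simply unvisited. The package
works with per-cell *ignorance scores* computed from the pooled records of a
reference taxonomic group — the wider taxon whose recording activity proxies
effort for its member species. With `N_i` records in cell `i`,

$$I_i = \frac{O_{0.5}}{N_i + O_{0.5}},$$

where the tuning constant $O_{0.5}$ is the number of observations considered
enough to halve the ignorance. The score is 1 exactly when `N = 0`, decays
hyperbolically in `N`, and equals 0.5 at `N = O_{0.5}`. There is no single
right $O_{0.5}$: it depends on taxon, resolution and recording style, so the
pipeline sweeps `{1, 2, 5, 10, 20, 50}` and treats stability across the sweep
as part of the result. Counts are gridded per taxon with a half-open
cell convention (`[low, high)` on both axes, top edge closed) so boundary
records land in exactly one cell; records outside the grid are dropped and
counted, never fatal.

## Covariate layers

Six layers describe accessibility on the analysis grid (10 km cells by
convention):

- **Elevation** (m): block mean of a fine digital elevation model.
- **Slope** (%): Horn's 3×3 kernel on the fine DEM, then block-averaged.
  Horn's method is the estimator used by the common GIS slope tool; edges are
  handled by replicating border cells, which is exact for planar surfaces on
  interior cells and flattens estimates along the border — at aggregation
  scale this is negligible.
- **Road and path density** (km/km²): total polyline length clipped to each
  cell divided by cell area. This deliberately replaces the search-radius
  neighbourhood of the usual GIS line-density operator with the
  parameter-free cell-clipped definition: it needs no radius choice, is
  additive over feature sets, invariant to vertex subdivision, and exactly
  testable. Class filtering (e.g. excluding forestry access roads, keeping
  footpaths and hiking trails) belongs to feature preparation, not geometry.
- **Population density** (people/km²): census polygons are rasterized onto a
  1 km grid by exact polygon–cell overlap areas (Sutherland–Hodgman clipping,
  shoelace areas), each polygon's population spread uniformly over its own
  area; the fine raster is then block-averaged. Total population is conserved
  whenever polygons lie inside the grid.
- **Log population density**: natural log of the density layer plus a
  positive offset, to expose effects at the lowest densities. The offset
  defaults to the smallest positive value in the layer (1 if none), mapping
  empty cells to the bottom of the observed range rather than $-\infty$. The
  base and offset rule are package choices; any fixed choice only shifts and
  scales the covariate, which the standardization below absorbs.

No reprojection is performed: all inputs must share the grid's metric CRS.
Raster I/O uses ESRI ASCII text grids and tidy CSV — plain-text formats that
round-trip exactly and diff cleanly.

## The regression

Scores are modelled per covariate (never multivariably — correlated
geography is the reality being described, and single-covariate fits keep the
comparison across taxa interpretable) with a Beta likelihood in the
mean–precision parameterization:

$$I_i \sim \mathrm{Beta}(\mu_i\,\varphi,\ (1-\mu_i)\,\varphi), \qquad
\mathrm{logit}(\mu_i) = \alpha + X_i\beta,$$

with $X_i$ empty (null model), linear, or linear-plus-quadratic in one
standardized covariate. Priors are vague: $\varphi \sim \Gamma(0.1, 0.1)$ and
$\alpha, \beta \sim N(0, 1000)$. The second Normal argument is read as a
*variance* (SD ≈ 31.6); sampler conventions differ on whether such a printed
constant is a variance, SD or precision, and all three remain genuinely
vague at the scale of logit effects, so the choice is exposed as
`prior_coef_sd` in `model_spec()` rather than hard-coded.

**Boundary handling.** The Beta density excludes 0 and 1, but unsampled
cells score exactly 1. The default applies the standard squeeze
$y' = (y(n-1) + 0.5)/n$ to all cells, so unsampled cells inform the fit
(they are the phenomenon of interest); `boundary = "drop"` instead discards
them, which answers a different question — how effort varies *among visited
cells* — and is provided for comparison only.

**Sampling.** `sample_posterior()` runs a joint random-walk Metropolis on
$(\alpha, \beta, \log\varphi)$ — the log transform keeps $\varphi$ positive,
with the Jacobian included. The proposal step size adapts towards 30%
acceptance and the proposal covariance is re-estimated midway through
burn-in; adaptation then stops, so retained draws come from a fixed kernel.
Defaults are 5000 retained iterations after 2000 burn-in, 2 chains with
jittered starts, convergence flagged when any split-chain $\widehat R$
exceeds 1.1. $\varphi$ is confined to $[e^{-18}, e^{27}]$ inside the
log-posterior: far outside that window the log-Gamma terms of the likelihood
cancel catastrophically in double precision, and no data gridded at this
scale can support such precisions. Everything is reproducible from one
integer seed, and sub-seeds in the pipeline are derived arithmetically per
(O-value, covariate, degree), so adding an O-value to a sweep leaves
existing fits bit-identical.

**Model choice.** Fits are compared by plug-in deviance,
$D = -2\log L$ evaluated at the posterior means — not the posterior mean of
the deviance — because the plug-in quantity is the one whose nested
differences are referred to $\chi^2$ quantiles (the posterior-mean variant
is available via `deviance(fit, type = "mean")`). Selection is
stepwise-forward per covariate: linear beats null only if
$\Delta D \ge 3.84$ (the $\chi^2_1$ 95th percentile) and quadratic beats
linear by the same rule; a quadratic is never selected once the linear term
fails. Deviance R², $100\,(D_0 - D_m)/D_0$, is reported clamped at zero.
A caveat documented rather than hidden: the Beta likelihood is a continuous
density, so deviances can be legitimately negative — squeezed unsampled
cells near 1 push the fitted Beta into its U-shaped regime where log
densities are large and positive. When $D_0 < 0$ the ratio is not a
proportion and the clamp activates; the Δ-deviance tests and thresholds are
unaffected, since they only use differences.

**Thresholds.** Because $\mathrm{logit}(0.5) = 0$, the covariate value where
a fitted curve crosses ignorance 0.5 is a polynomial root of the linear
predictor. `crossing_points()` solves it in closed form on the standardized
scale and back-transforms; `threshold_report()` re-verifies every root
against the curve and a dense grid scan (erroring on disagreement), flags
roots outside the observed covariate range, and attaches 95% posterior
intervals obtained by solving the root per posterior draw, matched by
crossing direction (falling/rising). The posterior intervals are an
extension beyond point thresholds and are labelled as such. Crossings are
reported in original units; the standardized root is also returned, since
either scale can be the one a reader wants.

## The synthetic generator

`synthetic_scenario()` defines the study conditions used throughout the
tests: a 50×50 grid of 10 km cells (2500 cells — the same order as a
national-scale grid), each subdivided 10× (1 km) for the fine layers.
Elevation is a moving-average-smoothed Gaussian field with a broad west–east
trend rescaled to 0–1000 m; slope is *derived from that same field* via
`slope_percent()`, keeping the two layers internally consistent; population
is a lognormal field (log-mean 2, log-SD 2 in people/km²) spanning more than
four orders of magnitude, as real census densities do; roads and paths are
random segments (4000 per class, exponential lengths with 20 km mean —
about 0.3 km/km² on average) whose placement mildly tracks population
through lognormal weights $\exp(w\,z(\log \mathrm{pop}))$, $w = 0.5$.
Smoothing is plain moving-average rather than variogram machinery: the
analysis itself ignores spatial autocorrelation, so the generator only needs
plausible gradients, not a calibrated covariance.

Recording effort follows
$\log \lambda_i = \gamma_0 + \sum_k \gamma_k z_{k,i}$ over standardized
layers with Poisson (default) or negative-binomial counts. Defaults describe
a moderately recorded taxon ($\gamma_0 = \log 5$) favouring road access
($\gamma_{\mathrm{road}} = 1$) and populated areas
($\gamma_{\log\mathrm{pop}} = 0.8$, $\gamma_{\mathrm{path}} = 0.3$) and
avoiding high, steep ground ($\gamma_{\mathrm{elev}} = -0.5$,
$\gamma_{\mathrm{slope}} = -0.3$).

Two generation modes exist deliberately. The count mode above feeds the real
pipeline end to end, but the Beta regression is *not* the true distribution
of transformed Poisson counts, so count-mode tests check qualitative
structure (signs, monotonicity, selection behaviour). Exact recovery and
coverage tests instead use `simulate_beta_response()`, where the fitted
likelihood *is* the generator. Passing both says the implementation is
correct and robust to this much misspecification; it does not certify the
model against everything real recorders do (home ranges, trip structure,
detection skill, temporal waves are all outside the generator).

## Problem sizes and numerical choices

The test suite runs at sizes chosen to make Monte Carlo noise small relative
to the tolerances asserted: the χ² calibration of the selection rule uses
200 intercept-only replicates of 500 cells (observed false-selection rate is
required to sit in 5% ± 3%); recovery uses 20 scenarios of 1000 cells with
$\alpha \in [-2,2]$, $\beta \in [-1,1]$, $\varphi \in \{5,20,100\}$ (means
within 3 posterior SDs, ≥85% empirical coverage of 95% intervals);
MLE-equivalence uses 200-cell fits under near-flat priors against an
independent BFGS optimizer (5% relative or 0.05 absolute per parameter);
likelihood values are checked against naive log-Gamma arithmetic at 10⁻¹⁰
relative; geometry against analytic fixtures at 10⁻⁹ or exactly. Reduced
iteration counts (1200–2000 retained, 1–2 chains) are used where only
posterior centres matter; the defaults (5000/2000/2) are what an analysis
run should use.

Other numerical choices: covariates are standardized before fitting (vagueness
of the coefficient prior and sampler conditioning both depend on scale; all
reported curves and thresholds are back-transformed); zero-variance
covariates refuse to standardize rather than silently producing NaNs;
degenerate constant fitted curves report *no* crossings with a warning
rather than "everywhere at the target"; ties between analytic roots and the
verification scan are resolved in favour of erroring loudly.

## Limitations

- Spatial autocorrelation of scores is ignored, as in the modelling approach
  itself; deviance differences are therefore optimistic where residual
  autocorrelation is strong.
- Deviance R² degrades to a clamped 0 when the null deviance is negative
  (see above); comparisons of explanatory power across taxa should then rest
  on Δ-deviance.
- The cell-clipped line density and the replicated-edge Horn slope are
  documented re-implementations of GIS operators whose neighbourhood
  settings vary between tools; absolute density values are comparable within
  this package, not necessarily with a particular GIS configuration.
- Coastline/land masking is the caller's responsibility via the `mask`
  argument; the package has no notion of geography beyond the rectangle.
- GeoTIFF is not read or written; exchange with GIS stacks goes through ESRI
  ASCII grids or CSV.
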