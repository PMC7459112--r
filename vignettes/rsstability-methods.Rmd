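---
title: "Methods: rank-based stability of soil respiration patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based stability of soil respiration patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsstability)
```

This vignette is the package's own account of its models, its numerical
choices, and what its synthetic tests do and do not demonstrate.

## The stability proxies

A campaign survey measures soil respiration `Rs` once per position per
campaign. Within each campaign, positions are ranked ascending (1 =
smallest flux). Ranking deliberately discards the absolute flux level:
campaigns differ enormously in temperature and moisture, and the question
is whether the *relative spatial pattern* persists, irrespective of the
conditions under which each snapshot was taken.

Per position, `rankRs` is the mean rank over campaigns (persistent activity
level) and `rangeRs` the max-minus-min of ranks (response amplitude). A
position that is always 5th out of 78 has `rangeRs = 0` — a resistant
response. A position wandering between rank 10 and rank 70 is rank-mobile —
resilient. With no ties and no missing values, ranks are conserved within
each campaign (they sum to n(n+1)/2), so the mean of `rankRs` over
positions is exactly (n+1)/2 = 39.5 for n = 78.

Tie handling is configurable (`average`, the default, plus `min` and
`ordinal`) because field data with instrument rounding can contain tied
fluxes, and the tie rule shifts `rankRs` away from the tie-free expectation.
Missing campaign values are ranked among the available positions and
averaged over the available campaigns, preserving per-campaign
comparability.

Positions are grouped two ways, and both groupings partition the positions:
`S`/`M`/`L` by `rankRs` against mean ± SD (boundary values fall in the
closed `M` interval; zero variance puts everything in `M`), and SOC
quintiles `C1`–`C5` by near-equal allocation (n %/% 5 per group, remainder
to the lowest groups, ties broken by position order; 78 positions give
sizes 16, 16, 16, 15, 15).

## The bell-curve model

`rangeRs` is modelled as a Gaussian bell in `rankRs`:

$$rangeR_s = a \, \frac{1}{\sigma\sqrt{2\pi}}
  e^{-(rankR_s-\mu)^2/2\sigma^2}.$$

By default `mu` and `sigma` are *fixed at the sample moments* of `rankRs`,
leaving the scale `a` as the only free parameter with the closed-form
weighted-projection solution $\hat a = \sum y_i g_i / \sum g_i^2$ ($g_i$ the
unit Gaussian density at `rankRs[i]`). The rationale: the bell is a
descriptive statement that rank mobility peaks in the middle of the rank
spectrum, and pinning the moments makes `a` directly comparable across
datasets. A full three-parameter nonlinear fit (`fix_moments = FALSE`,
Levenberg–Marquardt initialized at the moment values) is available for
sensitivity analysis; tests require the closed form and the pinned-moment
optimizer to agree to 1e-6. Significance is reported as an F test against
the constant-mean model plus a Wald t for `a`; with the moments fixed, the
F test's numerator degree of freedom is 1. A constant `rangeRs` vector is
flagged as a degenerate fit rather than an error.

## Two-state classification

The two-state reading is operationalized through the rank groups: `L`
(persistently high activity; in the emulated system these
sit at lower elevations with higher mean SOC and SWC) is state I, `S`
(persistently low activity, local ridges) is state II, and `M` is the
intermediate, resilient majority. This is a deliberate choice to reuse the
standard S/M/L machinery rather than invent a second threshold; the
per-state summaries (`summarise_states()`) report the terrain and
background-factor context that the narrative classification relies on.

## The terrain pyramid ("mixed scaling")

The DEM is aggregated by block means by a factor of two per level
(0.2 m base → 6.4 m at level 6) plus a seventh level built by direct
block-mean aggregation to 10 m — the sampling-grid resolution — rather than
by continuing the ×2 series, since 6.4 → 10 is not a doubling. Attributes
are computed at each level with a window of 3 × 3 *of that level's cells*,
so the neighbourhood scale grows with the pyramid rather than with an
explicit window parameter, then upscaled to base resolution by
nearest-neighbour replication. Six attributes are computed: moving-window
mean (`malt`), sample SD (`sd`), TPI (center minus the mean of the window
excluding the center — positive on ridges), Horn 3 × 3 slope in degrees,
and the aspect decomposition northness/easterness (cosine and sine of the
downslope compass bearing; both 0 on flat cells, so `north^2 + east^2 = 1`
exactly where slope > 0). Edge cells renormalize window statistics over the
cells actually present (no fill padding); slope and aspect replicate edge
rows/columns. Moving-window statistics use the separable box/Gaussian
filter with renormalization, which also handles interior missing cells.

Correlation scans run over levels 1–5 by default: at the two coarsest levels
(6.4 m, 10 m) an 80 × 60 m plot offers only a handful of cells and the
attribute fields behave qualitatively differently from the finer levels, so
they are computed and extractable but excluded from the default scan.

## Geostatistics

The empirical variogram is the Matheron estimator over 10 equal-width lag
bins up to half the maximum pairwise distance (both configurable); bins
with no pairs are dropped. Model fitting (exponential, Gaussian, spherical)
minimizes the pair-count-weighted residual sum of squares. Numerically,
the fit profiles the range parameter over a 40-point log grid — for fixed
range the model is linear in (nugget, partial sill), solved by
non-negative weighted least squares with the pure-nugget candidate
preferred on ties so a flat variogram resolves to a nugget, not to a
sub-lag-range sill — and then polishes with Levenberg–Marquardt, keeping
the polish only on strict improvement. Candidate selection requires
Nash–Sutcliffe efficiency E > 0.5 (computed unweighted on the binned
semivariances) and a practical autocorrelation range (3r exponential,
sqrt(3) r Gaussian, r spherical) below the diagonal of the data bounding
rectangle; survivors compete on SSErr. When nothing survives, a rejection
object is returned: there is then no valid ordinary-kriging map, and the
pipeline maps that variable by external-drift kriging only, using the
best-efficiency fit for the covariance structure — rank-range surfaces in
particular often lack a valid variogram.

Kriging is global (all positions; at n = 78 a moving neighbourhood buys
nothing), solved in semivariance form with the bordered system; ordinary
kriging uses an intercept-only basis, external-drift kriging adds one
covariate known exhaustively on the prediction grid — by default the 10 m
local-mean-elevation surface, the only covariate available everywhere.
An exactly constant drift makes the drift column redundant, and the
implementation falls back to the ordinary-kriging system with a message
(tests require KED ≡ OK in that limit); a non-constant but collinear drift
raises an error. Kriging variances are clipped at zero against roundoff.
Leave-one-out cross-validation reports the mean error, nRMSE (RMSE over the
observation span) and MSDR (mean squared error over kriging variance,
≈ 1 for a well-calibrated model; tests require 1 ± 0.3 at n = 200).

## The synthetic-data generator

The generator is an *emulator*, not a process model of grassland CO2
efflux: it is the minimal construction reproducing the qualitative
structure the analysis assumes, and is documented as such.

- **Terrain**: Gaussian-filtered white noise (filter SD = the correlation
  length, default 15 m — the dune-scale undulation of a sandy grassland),
  linearly rescaled so total relief is exactly `relief_max` (default 1.5 m)
  and shifted to 113.5 m a.s.l. Default grid 400 × 300 cells at 0.2 m,
  emulating a laser-scan DEM of an 80 × 60 m plot.
- **Positions**: 78 on the 80 × 60 m grid is over-determined for a 10 m
  lattice (9 × 7 = 63 nodes), so the layout is the lattice plus 15 seeded
  in-fill points at lattice-cell midpoints. Field surveys rarely document their exact
  in-fill layout, so this one is an explicit, configurable assumption.
- **Soil fields**: per-position SOC and baseline SWC are linear in
  z-scored terrain attributes (from a ~1.6 m aggregation, 3 × 3 window)
  plus noise, truncated to physical ranges. Coefficient signs encode the
  observed structure: SOC decreases with elevation, local SD and slope and
  increases with northness/easterness; SWC decreases with SD, slope and
  elevation. Magnitudes were calibrated once so that each sign holds in at
  least 95% of 20 seeded cohorts at n = 78, then frozen.
- **Campaigns**: 15 regimes in spring / summer-drought / autumn triplets
  across seven seasons (dated to a realistic seven-season campaign calendar), each a
  mean soil temperature and a plot-wide wetness multiplier on baseline SWC.
  Fluxes follow `rs_ref * (1 + w*z(SOC)) * Q10^((Ts-10)/10) *
  exp(-((SWC-opt)/width)^2) + noise`, clipped at zero after noise (physical
  bound); SWC is clipped to [0, 100] likewise. SOC is reported in 6 evenly
  spread campaigns only.

The moisture optimum (18%) sits *inside* the observed SWC range: wet
campaigns push wet positions past the optimum (waterlogging-like decline)
while dry campaigns sort positions by moisture. Wet and dry campaigns
therefore order the middle of the field differently, while extreme-SOC
positions are pinned by the SOC factor — which is what makes `rangeRs`
peak at intermediate `rankRs` and produces the bell. These defaults are the
study conditions of every stochastic test and are not tuned per test.

What passing tests show: the pipeline recovers the structure the generator
builds in — sign structure, bell shape, variogram parameters. What they do
not show: anything about real grassland data, which has ties, missing
campaigns, non-Gaussian noise, anisotropy and temporal autocorrelation the
emulator omits. On real campaign data, ties and
missingness pull the mean rankRs away from the tie-free 39.5 — matching a
published analysis therefore requires matching its tie convention, which is
why the rule is configurable.

## Problem sizes and determinism

Stochastic tests use fixed seeds throughout. The test suite runs the
generator cohort checks at the full study design (78 positions, 15
campaigns) over 20 seeds, recovery benchmarks at n = 78–200 with 200
replicates for the bell scale, and keeps the DEM at 160 × 128 half-metre
cells for end-to-end contract tests; the acceptance script runs the full
0.2 m / 400 × 300 configuration. `run_pipeline()` is deterministic given a
config and seed: two runs write byte-identical `summary.json` files.

## Known limitations

- Isotropic variograms only; no co-kriging, no robust variogram
  estimators, no Bayesian uncertainty on variogram parameters.
- The correlation scan applies no multiplicity correction by default:
  each record is reported at its own p < 0.05, the convention in this
  literature; a Benjamini–Hochberg option exists (`adjust = "BH"`).
- Pearson correlations throughout (the scanned relations are modelled as
  linear); rank correlations are not offered.
- Raster I/O is ESRI ASCII grid only.
- The meteorology helper is integer-rounded percent arithmetic on the
  yearly precipitation table: the wettest study year (813 mm) deviates by
  +39% from the 585 mm long-term mean, the driest (431 mm) by −26%.
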