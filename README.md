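# rsstability

Rank-based stability analysis of soil respiration spatial patterns.

Soil respiration (Rs, the CO2 efflux from soil) in grasslands is patchy in
space and restless in time: droughts, rewetting and temperature swings
reorder which patches respire most. `rsstability` asks whether a
measuring position's *place in the spatial pattern* is stable over years of
repeated campaign surveys, and whether micro-topography explains where
stability lives. It is aimed at ecosystem ecologists and biogeochemists
working with campaign-style chamber surveys (one flux value per position per
campaign) on plots with high-resolution elevation models.

## The method

For each campaign, positions are ranked by Rs (1 = smallest flux). Two
per-position proxies summarise the long-term behaviour:

- **rankRs** — the temporal mean of a position's within-campaign rank:
  the persistent activity level (large = persistently high respiration);
- **rangeRs** — the max minus min of those ranks: the response amplitude.
  Small rangeRs means a *resistant* position whose rank barely moves;
  large rangeRs means a *resilient*, rank-mobile position.

The two are linked by a Gaussian bell-curve model,

```
rangeRs = a * 1/(sigma * sqrt(2*pi)) * exp(-(rankRs - mu)^2 / (2*sigma^2)),
```

with `mu` and `sigma` fixed at the sample mean and SD of rankRs and the
scale `a` estimated by least squares (closed form). Both rank extremes are
resistant — persistently low-activity ridge positions ("state II") and
persistently high-activity, wetter, carbon-richer positions ("state I") —
while the middle of the rank spectrum is resilient. Terrain context comes
from a "mixed scaling" pyramid on the DEM: the elevation raster is
repeatedly aggregated by a factor of two (0.2, 0.4, ..., 6.4 m, plus a 10 m
level matching the sampling grid), six attributes (local mean elevation,
elevation SD, topographic position index, slope, northness, easterness) are
computed at every level and upscaled back to base resolution, and
proxy-attribute correlations are scanned across levels and subgroups.
Variogram fitting (exponential / Gaussian / spherical, selected by
Nash-Sutcliffe efficiency, autocorrelation range and residual sum of
squares), ordinary kriging and kriging with external drift map the proxies,
with leave-one-out cross-validation (nRMSE, mean error, MSDR).

A synthetic-data generator emulates the study system — a finely undulating
(≤ 1.5 m relief) semi-arid grassland sampled at 78 positions on an
80 × 60 m grid over 15 campaigns, with soil organic carbon observed in 6 —
so the entire pipeline runs and is tested without any field download.

## Worked example

```r
library(rsstability)

sim     <- simulate_study(seed = 1)       # DEM + 78 positions x 15 campaigns
proxies <- compute_proxies(sim$panel)     # rankRs, rangeRs, groups
bell    <- fit_bell_curve(proxies)
bell
#> <bell_fit> rangeRs = a * N(rankRs; mu, sigma) [moments fixed]
#>   a = 2577.81 (SE 105.24), mu = 39.50, sigma = 18.92, n = 78
#>   R^2 = 0.231, F(1, 76) = 22.84, p = 8.42e-06

summarise_states(classify_states(proxies))
#> # A tibble: 3 x 6
#>   state            n rank_rs range_rs mean_soc mean_swc
#>   <fct>        <int>   <dbl>    <dbl>    <dbl>    <dbl>
#> 1 I               14    63.9     30.8     4.57    18.0
#> 2 II              18    12.9     27.2     1.21     8.60
#> 3 intermediate    46    42.5     43.9     3.22    17.1
```

The mean rank over tie-free campaigns is (n+1)/2 = 39.5 by construction;
`a` is the bell-curve scale (rank units squared), and its highly significant
F test says rank mobility genuinely peaks at intermediate rankRs. The state
summary shows the two resistant equilibria: state I positions are
persistently high-activity with high mean SOC and SWC, state II persistently
low-activity and carbon-poor, while the intermediate majority has the
largest mean rank range (43.9) — resilience, not resistance. Maps come from
`krige_ok()` / `krige_ked()` and `autoplot()`; `run_pipeline()` executes the
whole chain and writes every table, raster and a `summary.json` to a run
directory.

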