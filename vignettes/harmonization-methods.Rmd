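---
title: "Harmonization methods: models, tunables and synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonization methods: models, tunables and synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the statistical and numerical choices behind
`silvharm`: what each harmonization step assumes, which knobs exist and
why their defaults are what they are, and what the synthetic data
generators do and do not emulate.

## 1. Discrete vegetation states

A simulation-year is summarized as
`<SPECIES-CODES>_<LAI-CLASS>_<LOWER>_<UPPER>`.

* **Species codes** are four letters: the first two of the genus and the
  first two of the specific epithet. The *dominant* species (basal-area
  share strictly greater than the dominance threshold, default 0.66) is
  written in uppercase and must come first; *admixed* species (share at
  or above the admixture threshold, default 0.20) follow in lowercase,
  ordered by descending share, ties broken alphabetically. When no
  species reaches the admixture threshold the composition token is
  `mixd`: the stand is a mixture too diffuse to name. The thresholds
  deliberately leave a gap — a stand can have no dominant species yet
  several admixed ones.
* **LAI classes** use the fixed edges 2 and 4: class 1 for LAI < 2,
  class 2 for 2 ≤ LAI ≤ 4 (both boundaries inclusive), class 3 for
  LAI > 4. The inclusive-both-ends middle class is an asymmetry kept on
  purpose; it is tested explicitly at 2.0, 4.0 and 4.01.
* **Height bins** are half-open 2-m intervals [low, low + 2), so 21 m
  falls in [20, 22) and 22 m in [22, 24). The bin width is a tunable
  (`height_bin_width`, default 2) because coarser bins may suit sparse
  ensembles.

`decode_state()` inverts the encoding and validates token structure,
which makes round-tripping a cheap property test.

## 2. Height harmonization

Contributors report different subsets of {min, mean, max, dominant}
canopy height. Harmonization proceeds in three ordered fallbacks:

1. **Mean fill.** A missing mean with known min and max becomes
   (min + max)/2. This assumes an approximately symmetric height
   distribution; it is exact for the synthetic generator and a
   reasonable first-order fill otherwise.
2. **Max from mean.** A missing max is predicted by a linear mixed
   model `max ~ mean + (1 + mean | species)` fitted to calibration
   stands, with population-level prediction for unseen species and a
   floor at the mean (a maximum cannot be below the mean).
3. **Dominant height.** For species with a configured allometric
   factor (`allometric_factors`, default 0.95 for six common European
   species), dominant height is `factor × max`. Otherwise a mixed model
   `dominant ~ mean + max + (0 + mean | species) + (0 + max | species)`
   predicts it. Either path is clamped to [0.8 · max, max]: dominant
   height is by construction near, but not above, the stand maximum.

The factor table and both calibration models are configuration inputs;
the packaged defaults are placeholders suitable for the synthetic study
and should be replaced by values calibrated on inventory data in any
real application.

## 3. Climate matching

Every simulation must end up forced by a daily trajectory from a common
scenario catalogue.

* **Trend index.** Ordinary-least-squares slopes of annual mean
  temperature (°C per century) and annual precipitation (relative %
  per century) are computed for the simulation and every candidate
  trajectory; the distance is |ΔT| + `weight` · |ΔP| with
  `weight = 0.1`, i.e. a 10 % precipitation-trend difference weighs as
  much as 1 °C of temperature-trend difference. Precipitation trends
  are relative because absolute slopes are incomparable across wet and
  dry sites.
* **Candidate filtering.** Simulations flagged as baseline runs match
  only historical trajectories; `rcp_hint`/`gcm_hint` metadata narrows
  the candidate set further when present. Hints constrain, never
  override, the trend match within the allowed family.
* **Spatial assignment** is the nearest catalogue cell by haversine
  distance.
* **Level adjustment.** The selected trajectory is shifted additively
  in temperature and scaled multiplicatively in precipitation so its
  mean annual values equal the simulation's. The adjustment is exact
  arithmetic; the residual is zero to machine precision and is reported
  by the acceptance script.
* **Year mapping.** For each simulation year the three scenario years
  with the smallest |ΔT| + 0.1·|100·(P·ratio − 1)| index are found and
  one is drawn uniformly (ties resolved toward earlier years before
  sampling). The randomization avoids systematically reusing one
  scenario year; drawing per simulation from a seeded substream keeps
  reruns bit-identical.

## 4. Soil completion

The completion cascade for the quantitative soil vector is: verbatim
contributor values → fertility/water rating-class lookup
(`default_rating_lookup()`) → nearest soil-grid cell → GLM prediction
for available nitrogen.

Plant-available nitrogen is modelled through a *pseudo-mineralization
rate*: the ratio of a nitrogen flux (from SQ1 fertility classes
reclassified as 100/65/40/20 kg ha⁻¹ yr⁻¹ for classes 1–4) to the soil
nitrogen pool (∑ content/1000 · bulk density · thickness · 10⁴ kg ha⁻¹,
truncated at 0.30 m depth). The rate is regressed on mean annual
temperature, annual precipitation, temperature seasonality and pH with
a Gamma GLM (log link); goodness of fit is reported as the deviance
ratio D² = 1 − residual/null deviance. The Gamma-log choice guarantees
positive predicted rates and multiplicative covariate effects, which is
how mineralization responds to climate in first order.

## 5. Coverage

Climate space is stratified by mean annual temperature (bin edges −2,
2, 4, 6, 8, 10, 12, 14, 18 °C), annual precipitation (400, 550, 750,
1000, 1400, 2000 mm) and temperature seasonality, defined as 100 × the
population standard deviation of the twelve monthly means (edges 200,
400, 500, 600, 700, 900). Soil space uses five texture classes (from
clay/sand thresholds: clay ≥ 60 → 5, clay ≥ 35 → 4, clay < 18 and
sand > 65 → 1, sand < 15 → 3, else 2), water-holding capacity (50,
100, 150, 180 mm) and available nitrogen (20, 40, 65, 100 kg ha⁻¹).
All bins are half-open [low, high): a value exactly on an edge belongs
to the upper bin, implemented with `findInterval` and verified against
a brute-force linear scan in the tests. Coverage is the
cos(latitude)-weighted area fraction of reference strata occupied by
the ensemble, so it is monotone in the occupied set by construction.

## 6. What the synthetic generators emulate

The generators exist so every harmonization step can be tested against
known truth without external gridded data.

* `gen_scenario_catalogue()` builds (historical + 3 RCPs) × 3 GCM
  trajectories per grid cell over 2011–2100: a seasonal sinusoid plus
  AR(1) noise for temperature (autocorrelation 0.6, innovation sd
  2.5 °C), Bernoulli(0.45)–Gamma daily precipitation, clear-sky
  radiation damped on wet days, and VPD from a Magnus saturation
  pressure with wet/dry relative humidity. Linear trends are injected
  per scenario family and GCM; the default trend specification spaces
  families widely enough (1.0–7.0 °C per century, −12 to +4 % per
  century plus GCM offsets) that realized OLS slopes over 90 years
  identify the source scenario despite weather noise. This is a design
  property, not a tuning outcome: the separation was chosen from the
  sampling variance of a 90-year OLS slope before any recovery test was
  run.
* `gen_simulation_set()` draws simulations from the catalogue with
  reporting *profiles* (which height statistics and soil information a
  contributor provides), small observation noise, site offsets and the
  contributed-file dialect (long species rows, packed annual climate
  strings) the ingest module expects.
* `gen_soil_grids()` embeds a known Gamma-GLM truth: a continuous
  fertility flux is generated *from* the GLM so the fitted model can
  recover the coefficients exactly in the noiseless limit, alongside a
  quantized SQ1 class for testing the reclassification path.
* `gen_height_calibration()` generates stands from per-species
  coefficients around (c_mean = 0.10, c_max = 0.85); with zero spread
  and zero noise the mixed model degenerates to a fixed-effects fit and
  recovers the truth to numerical precision.

They do **not** emulate: spatial autocorrelation of weather between
cells, elevation effects, snow/phenology, correlated height–LAI
errors, or non-linear climate trends. Conclusions about those belong to
real data, not this package's tests.

## 7. Numerical and reproducibility choices

* Per-simulation randomness uses a substream seeded by
  `(seed + hash(simulation_id)) mod (2³¹ − 1)`, so adding or removing
  one simulation does not perturb the draws of the others and all
  derived seeds stay below 2³¹.
* Ties in trajectory selection resolve lexicographically; ties in year
  distance resolve toward earlier years, before the uniform draw among
  the three best.
* Mixed models are fitted with REML via `lme4`; singular-fit messages
  are tolerated because the noiseless test designs are singular by
  construction.
* The Gamma GLM guards zero pseudo-rates with a floor of 10⁻¹².
* SQLite output uses a wide schema (13 descriptors + 4 × 365 daily
  columns) written and read with schema verification; a rerun with
  identical inputs, configuration and seed reproduces every state
  string, soil vector and year mapping.

## 8. Limitations

Default allometric factors, rating lookups and GLM coefficients are
study placeholders. Coverage bins are fixed European-scale choices; for
other regions both edges and the reference grids should change. The
pipeline assumes annual time steps and 365-day years; leap days must be
removed upstream.
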