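# silvharm

Harmonization toolkit for multi-model forest simulation ensembles.

Forest growth models are run by many groups, each with its own output
conventions: different height statistics (mean, minimum/maximum, or
dominant height), different climate forcings, different soil descriptions
(full profiles, fertility ratings, or nothing at all). `silvharm` turns
such heterogeneous contributions into a single queryable database in
which every simulation-year carries

* a **discrete vegetation state** string encoding species composition,
  leaf-area class and a 2-m dominant-height bin (e.g.
  `PIABfasy_3_20_22`: *Picea abies* dominant, admixed *Fagus sylvatica*,
  LAI class 3, dominant height in [20, 22) m);
* a **harmonized dominant height**, inferred from whatever height
  statistics the contributor reported, via species-level mixed models
  and allometric reduction factors, clamped to [0.8·max, max];
* a **matched daily climate trajectory** (tas, prec, rad, vpd; 365
  values per year), selected from a scenario catalogue by
  trend-matching, level-adjusted to the simulation's reported annual
  means, and mapped year-by-year to the three most similar scenario
  years;
* a **completed soil vector** (water-holding capacity, texture, depth,
  plant-available nitrogen), filled from reported values, rating-class
  lookups, gridded soil data and a Gamma GLM of pseudo-mineralization
  rates.

The package also quantifies how much of the European climate and soil
space an ensemble covers, using fixed stratification bins and
area-weighted coverage fractions, and ships synthetic data generators
that emulate contributor output with known ground truth so that the
whole pipeline can be tested end to end.

## Core models

* **Vegetation state.** A species is *dominant* when its basal-area
  share strictly exceeds 66 % (uppercase 4-letter code, two letters of
  genus + two of epithet); species with shares ≥ 20 % are *admixed*
  (lowercase codes, descending share). LAI classes: 1 (LAI < 2),
  2 (2 ≤ LAI ≤ 4), 3 (LAI > 4). Height bins are half-open 2-m
  intervals [low, high).
* **Height harmonization.** Missing mean heights are filled as
  (min + max)/2. Missing maxima come from a mixed model
  `max ~ mean + (1 + mean | species)`. Dominant height is either
  `factor × max` for species with a configured allometric factor, or a
  mixed-model prediction
  `dominant ~ mean + max + (0 + mean | species) + (0 + max | species)`,
  always clamped to [0.8·max, max].
* **Climate matching.** Simulations are matched to catalogue
  trajectories by a trend index |ΔT| + 0.1·|ΔP| (ΔT in °C per century,
  ΔP in relative % per century), within the candidate family implied by
  the contributor's scenario and model hints, at the nearest grid cell
  (haversine distance). Temperature is adjusted additively and
  precipitation multiplicatively so the trajectory's mean annual values
  match the simulation exactly; each simulation year then draws
  uniformly one of the three most similar scenario years.
* **Soil completion.** SQ1 fertility classes reclassify to nitrogen
  fluxes 100/65/40/20 kg ha⁻¹ yr⁻¹; profile nitrogen pools integrate
  content × density × thickness down to 0.30 m; a Gamma GLM with log
  link regresses the pseudo-rate (flux/pool) on mean annual
  temperature, precipitation, seasonality and pH, and predicts
  plant-available nitrogen where no direct information exists.
* **Coverage.** Climate space is stratified by mean annual temperature
  (10 bins), annual precipitation (7) and temperature seasonality (7);
  soil space by 5 texture classes, water-holding capacity (5 bins) and
  available nitrogen (5). Coverage is the cos(latitude)-weighted area
  share of occupied strata.

## Worked example

```r
library(silvharm)

# state encoding: 70 % Picea abies, 25 % Fagus sylvatica, LAI 4.5, 21 m
stand_state(c("Picea abies" = 0.70, "Fagus sylvatica" = 0.25),
            lai = 4.5, dominant_height = 21)
#> [1] "PIABfasy_3_20_22"

# a synthetic study with known truth
catal <- gen_scenario_catalogue(seed = 1)       # 12 scenarios per cell
sims  <- gen_simulation_set(catal, n_sims = 50, seed = 2)
grids <- gen_soil_grids(seed = 3)
cal   <- gen_height_calibration(200, c("Picea abies", "Fagus sylvatica",
                                       "Pinus sylvestris"), seed = 4)

cfg <- harmonization_config(seed = 11, height_calibration = cal)
res <- run_harmonization(sims$simulations, sims$metadata, catal, grids,
                         cfg, out_dir = "harmonized")
res$per_scenario       # 50 simulations spread over 12 scenario databases
#> historical_GCM-A historical_GCM-B historical_GCM-C      rcp26_GCM-A
#>                2                4                3                2
#>      rcp26_GCM-B      rcp26_GCM-C      rcp45_GCM-A      rcp45_GCM-B
#>                8                3                6                6
#>      rcp45_GCM-C      rcp85_GCM-A      rcp85_GCM-B      rcp85_GCM-C
#>                6                2                7                1
res$coverage$table
#>     space occupied_strata covered_area_pct
#> 1 climate               1        100.00000
#> 2    soil              30         67.22642
```

`run_harmonization()` writes one SQLite database per climate scenario
(table `simulations`, 13 descriptor columns + 4 × 365 daily climate
columns), a metadata database, `coverage.csv`, the resolved
configuration and a run log. `read_harmonized_db()` reads a scenario
database back with schema checking.

A command-line wrapper lives at `inst/scripts/harmonize.R`
(subcommands `synth`, `validate`, `run`, `coverage`).

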