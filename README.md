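# hazex — multi-hazard population exposure on gridded data

`hazex` estimates **country-level population exposure** to three
climate-related hazards — tropical cyclones, droughts and floods — from raw
event records and a gridded population layer. It is aimed at global
health / disaster-risk analysts who need a *hazard-frequency–weighted*
exposure baseline that is independent of any particular outcome (mortality,
economic loss, water access), can be stratified into urban and rural
populations, and can be recomputed as soon as a better dataset for any one
input becomes available.

## The model

1. **Hazard frequency.** Each event record is rasterized into a per-cell
   event count: a cyclone tallies every cell within a per-category
   great-circle buffer of its track (once per event), a flood tallies every
   cell whose centre falls in its degree-snapped footprint, and a drought
   event is a run of **three or more consecutive months** with
   precipitation **≤ 50 % of that calendar month's long-term median**.
2. **Relative-frequency deciles.** Cells with population density below
   5 persons/km² and no significant agriculture are excluded; the remaining
   cells with ≥ 1 event are sorted globally into deciles 1–10 per hazard.
   The decile becomes the hazard weight `H = decile / 10 ∈ {0.1, …, 1.0}`
   (0 where no event was recorded).
3. **Exposure.** Per cell, `exposure = Pop_cell × H`; the multi-hazard layer
   is the equally-weighted sum over the three hazards. Per country,

   ```
   score = Σ_cells exposure / Σ_cells population
   ```

   so a single-hazard score lies in [0, 1] (1.0 = the whole population in
   the top decile) and the multi-hazard score in [0, 3]. Urban and rural
   scores restrict both sums to the stratum's cells.
4. **Urban/rural strata.** Each country's cells are labelled urban or rural
   by a country-specific population threshold chosen so that the urban
   cells' share of the national population matches the tabulated urban
   proportion as closely as the grid's discreteness allows.
5. **Ranking.** Countries are ranked by descending score with competition
   ("minimum") ranks — all zero-exposure countries tie at rank
   (number of positive-score countries) + 1 — and split into quintile
   display classes; development-class (HDI) averages are person-weighted.

Because the licensed global inputs (population grid, hazard grids, urban
proportions) cannot be redistributed, the package ships a seeded
**synthetic-world generator** that emits structurally identical inputs
(clustered populations in rectangular countries, storm tracks, flood boxes,
a seasonal monthly precipitation cube with injected deficit runs), so the
entire pipeline is testable and demonstrable offline.

## Worked example

```r
library(hazex)
cfg <- pipeline_config(
  synthetic  = TRUE,
  world      = world_config(n_rows = 24, n_cols = 24, n_countries = 6,
                            n_cyclones = 20L, n_floods = 40L,
                            n_months = 240L),
  output_dir = "demo", seed = 42)
run_pipeline(cfg)
read.csv("demo/report/exposure_multi_total.csv")
```

```
#> [hazex] simulate: wrote inputs for 6 countries on a 24x24 grid
#> [hazex] hazards: 20 cyclone, 40 flood events; 42 drought cells hit
#> [hazex] classify: 261 valid cells, 85 urban cells
#> [hazex] exposure: 72 table rows over 6 countries
#> [hazex] rank: wrote 14 report files
#>   country_id     score population rank quintile
#> 1          4 0.4030403    4742088    1        1
#> 2          5 0.3440738    5543828    2        2
#> 3          1 0.2538213    5405267    3        3
#> 4          3 0.2534478    5767212    4        4
#> 5          6 0.2483265    5442395    5        5
#> 6          2 0.2156715    5013776    6        5
```

Country 4's multi-hazard score of 0.40 means that, averaged over its
population, the sum of its three hazard weights is 0.40 of the single-hazard
maximum (theoretical multi-hazard maximum 3.0) — equivalently, the
population-weighted sum of its cyclone + drought + flood deciles averages
about 4 out of a possible 30. Ranks are competition ranks and `quintile`
is the map display class (1 = most exposed fifth).

The same run writes per-hazard × stratum CSVs
(`exposure_<hazard>_<stratum>.csv`), a combined long-format table, the
urban thresholds actually achieved, and person-weighted HDI class averages
(`hdi_averages.csv`).

The command-line launcher wraps the same stages:

```sh
Rscript exec/hazex run-all --synthetic --seed 42 --outdir demo
Rscript exec/hazex rank --outdir demo        # re-run one stage
```

Each stage reads and writes ordinary files (ESRI ASCII grids + CSVs), so
replacing, say, `demo/inputs/flood_events.csv` with a better flood record
and re-running `hazards → rank` updates only flood-dependent outputs.

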