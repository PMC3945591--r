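---
title: "Methods: multi-hazard population exposure on gridded data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-hazard population exposure on gridded data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazex)
```

## The quantity being estimated

`hazex` computes *population exposure*: the relative likelihood that a
person at a location was exposed to a hazard event (cyclone, drought or
flood) over a multi-decade record, aggregated to the country level. It is
deliberately **not** a risk, mortality or loss model — no vulnerability or
severity weighting enters anywhere — so the scores can be combined
downstream with outcome-specific vulnerability variables (drinking-water
interruption, evacuation capacity, crop loss, ...) without double
counting.

The chain is:

1. event records → per-cell **event counts** per hazard;
2. counts → global **relative-frequency deciles** 1–10 over "valid" cells
   (populated or agricultural), 0 elsewhere;
3. decile → **hazard weight** `H = decile/10`;
4. per cell, `exposure = Pop_cell × H`; multi-hazard is the equally
   weighted sum of the three single-hazard layers;
5. per country and stratum (total / urban / rural),
   `score = Σ exposure / Σ population`.

A single-hazard country score is bounded by 1.0 — attained exactly when
every populated cell of the country sits in the top decile — and the
multi-hazard score by 3.0. These two bounds are the package's structural
acceptance anchors: the deterministic `make_extreme_country_fixture()`
world attains both exactly, end to end, and `scripts/acceptance.R`
recomputes them from scratch at every run.

## Hazard-specific definitions

**Cyclone.** A track is an ordered sequence of points with one intensity
category (1–6, Saffir–Simpson-style). A cell is covered by an event when
any track point lies within the category's buffer radius of the cell
centre (great-circle distance, sphere of radius 6371 km). The original
hazard grids used an unpublished parametric wind-field model to size the
affected swath; since those equations are not available, the buffer radii
are configuration, defaulting to 50/100/150/200/250/300 km for categories
1–6 (monotone, of the order of observed gale-force wind radii). A cell is
tallied **once per event**, however many points of the same track pass
over it.

**Flood.** Footprints are bounding boxes snapped to whole degrees, as in
satellite-derived inundation catalogues. A cell is tallied once per event
whose box contains its centre; the count is of inundation *events*, never
of inundated days.

**Drought.** For each cell's monthly precipitation series, a month
*qualifies* when precipitation is ≤ 50 % of that calendar month's
long-term median, and a drought event is a maximal run of ≥ 3 consecutive
qualifying months. Two choices the source description leaves open:

* *Median*: per-calendar-month climatology rather than one pooled median —
  "long-term median value" of a month most naturally means that month's
  climatology, and the underlying anomaly framework (WASP) is
  seasonally resolved.
* *Arid floor* (`min_median_mm`, default 1 mm): a month whose median is
  below the floor can never qualify. Without it, a hyper-arid cell with
  median 0 satisfies `0 ≤ 0.5 × 0` perpetually. With it, rain-free cells
  record no droughts — reproducing the known artifact that deviation-based
  drought definitions assign water-scarce countries little or no drought
  exposure.

## The valid-cell mask and decile sort

Cells with population density < 5 persons/km² **and** no significant
agriculture are excluded before the sort (agriculture rescues a sparse
cell; density exactly 5 is retained — "less than 5" is strict). Density is
population count ÷ spherical cell area, so the rule is well-defined at any
latitude; cell areas use `(RΔ)·(RΔ cos φ)` with the authalic radius
R = 6371.0 km.

The sort is **global across all valid cells per hazard**, not
per-country: a cross-country ranking needs a common scale. Valid cells
with zero events stay at decile 0 ("no hazard", distinct from decile 1)
and are excluded from the ranked population. Boundaries are the
nearest-rank 10th–90th percentiles of the positive counts; a cell's decile
is 1 + (number of boundaries strictly below its count), which guarantees
equal counts share a decile. Degenerate case: if every positive count is
identical there is no ranking information and all those cells are placed
in decile 10 (they are jointly the most-frequent cells on record). With n
distinct counts each decile holds n/10 cells up to ±1 — asserted as a
property test.

Resolution mismatches (the drought and flood records are far coarser than
the population grid) are handled by nearest-neighbour resampling of the
*count* grids onto the population grid before masking and decile-binning.
Nearest-neighbour is the only defensible choice: counts and deciles are
categorical-like quantities that must never be interpolated.

## Urban/rural classification

For each country the target urban population is
`fraction × country population` (fraction from the national urban
proportion table). Cells are sorted by population, descending (ties broken
by row-major cell order), and the selected prefix is the one whose
cumulative population minimizes the absolute distance to the target
(smallest prefix on ties). The reported "threshold" is the smallest
selected cell population. A pure value threshold cannot in general attain
the tabulated proportion when boundary cells tie, so the prefix
construction is used and the achieved share is always within one maximal
cell's share of the target (the discreteness bound, asserted on 100 random
countries). Cells with zero population are never urban: uninhabited land
is conflated with rural by construction, a known limitation of
density-threshold urban definitions.

## Aggregation, ranking, class averages

Scores are ratios of zonal sums, so the identity
`total score × total pop = urban score × urban pop + rural score × rural pop`
holds exactly (bit-exactly with integer populations — the synthetic
generator rounds populations to integers for this reason). A stratum with
zero population reports a *missing* score rather than 0 so class averages
are not dragged down.

Ranking uses competition ("minimum") ranks on descending score: the
zero-exposure group always lands at rank (#positives + 1). This convention
is what reproduces the published tie structure — with 228 countries of
which 136, 36 or 48 have no recorded exposure, the zero groups tie at
ranks 93, 193 and 181 respectively — and those three constants are an
acceptance criterion. Display classes are quintiles of the *ranked list*
(equal country counts, tie groups kept together), not equal score
intervals; the alternative reading ("equal intervals" as a map-legend
style) is noted but not implemented.

Development-class (HDI) averages are **person-weighted**: pooled
`Σ score × stratum population / Σ stratum population` over the class's
scored countries, with a Global row pooled over all scored countries. The
construction of the published class-average table is not stated precisely
enough to arbitrate between person-weighting and unweighted country means;
person-weighting matches the name "average population exposure" and is the
package's documented choice. Published class-average values are therefore
*not* used as numeric test targets.

## The synthetic world

`generate_world()` emits every input the pipeline reads, under one integer
seed (bit-identical reruns):

* **Countries** are rectangular blocks — no coastline geometry, so zone
  rasterization is exact and tests focus on the model's arithmetic.
* **Population** is a rounded log-normal rural field (default
  `meanlog = log(30 000)`, `sdlog = 1` per 1° cell) with 2 dense urban
  cores per country (~500 000 before noise) and 5 % uninhabited cells.
  Integer populations make the decomposition identities exact.
* **Cyclones** (default 20–30 events) are random straight-ish tracks with
  genesis weighted equatorward; categories sampled with decreasing
  probability (30/25/20/12/8/5 %).
* **Floods** (default 60 events) are 1–3° degree-snapped boxes.
* **Precipitation** is a 240-month (two-decade, matching the length of the
  event records) seasonal sinusoid per coarse cell (baseline 40–150 mm,
  ±60 % seasonality) with multiplicative gamma noise (shape 12), into
  which 3–5-month deficit runs at 30 % of baseline are injected at
  Poisson rate 1.2 per cell, never closer than one clean month apart. The
  ground-truth sidecar records every injected run; a recovery test checks
  each injected run is detected.
* **Urban fractions** are uniform on [0.2, 0.8]; **HDI classes** are
  sampled uniformly.

What the generator does *not* emulate: real storm climatology and track
curvature, spatially correlated precipitation, coastlines and border
effects, census-derived population textures, or reporting bias in event
catalogues. A green test therefore establishes the *arithmetic* of the
model — tallying, masking, binning, thresholding, aggregation, ranking —
not the realism of any particular global dataset, and the published
country rankings and class averages (products of licensed global inputs)
are explicitly out of numerical scope.

## Numerical and interface choices

* Raster I/O is the plain-text ESRI ASCII grid; the environment provides
  no GDAL-backed R package, so GeoTIFF paths raise an informative error
  rather than a wrong answer. Integer layers round-trip bit-exactly.
  The precipitation cube travels as a wide CSV plus a JSON georeference
  sidecar for the same reason.
* Grids are WGS84 geographic degrees, top-left origin, row-major,
  cell-centre sampling; rotated/skewed georeferences are rejected.
* The pipeline configuration file is JSON (`jsonlite`), as no YAML parser
  is available offline; keys mirror `pipeline_config()`.
* Each pipeline stage reads and writes ordinary files, so any one input
  dataset can be replaced and only downstream stages re-run; report CSVs
  are byte-deterministic under a fixed config and seed (an acceptance
  criterion).
* Cells split by a country border are assigned wholly to one country; the
  zone map is taken as pre-rasterized truth.

## Known limitations

Binary urban/rural (no peri-urban gradation); one tally per event however
severe (no severity weighting, by design); drought ignores aridity, so
chronically dry regions can score zero; the buffer-radius stand-in for the
cyclone wind field is configuration, not physics; zonal statistics are
cell-exact rather than area-weighted across borders.
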