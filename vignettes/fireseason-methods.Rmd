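---
title: "Methods: fire-weather, blocking, burned-area and fire-season analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fire-weather, blocking, burned-area and fire-season analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `fireseason`, the
parameters that matter, the numerical conventions, the design decisions
taken where the methodology leaves room, and what the synthetic-data tests
do and do not demonstrate about real data.

## The Fire Weather Index System on grids

The Canadian Fire Weather Index System is an empirical bookkeeping model of
fuel moisture. Three codes track progressively deeper, slower-drying fuel
layers from daily noon weather — temperature (°C), relative humidity (%),
10-m wind (km/h) and 24-h precipitation (mm):

* **FFMC** (fine fuel moisture, bounded [0, 101]): a rainfall routine that
  wets the litter layer, then exponential approach to a humidity- and
  temperature-dependent equilibrium, with wind accelerating drying.
* **DMC** (duff moisture, ≥ 0): a rainfall routine with a storage-dependent
  response plus a temperature/humidity/day-length drying increment. The
  month-dependent effective day lengths are the conventional mid-latitude
  table.
* **DC** (deep organic moisture deficit, ≥ 0): rainfall reduces the deficit
  through the moisture equivalent `Q = 800·exp(−DC/400)`; evapotranspiration
  adds `0.5·V` with `V = 0.36(T + 2.8) + L_f` (month factor `L_f`, floored
  at zero).

ISI (wind + FFMC), BUI (DMC + DC) and FWI (ISI + BUI) follow the standard
closed forms. The exact constants are those of the published consolidated
equations; `fwi_update_codes`/`fwi_indices` are a direct scalar
transcription and the unit tests pin them to the standard worked example
(FFMC 85/DMC 6/DC 15 with 17 °C, 42%, 25 km/h, no rain in April gives
87.69/8.54/19.01 and ISI 10.85, BUI 8.49, FWI 10.10).

**Two implementations, one contract.** `run_fwi_grid` re-implements the
daily update as whole-grid vector arithmetic, written independently of the
scalar forms (branching via `ifelse`/`pmin`/`pmax` instead of `if`). The
suite requires the two paths to agree to 1e−9 per cell-day on 1,000 random
120-day sequences, including season startup/shutdown and overwintering. Per
cell, the trajectory depends only on that cell's weather.

**Fire season.** A cell becomes active the day *after* its daily maximum
temperature has exceeded 12 °C on three consecutive days, and inactive the
day after three consecutive days below 5 °C (both configurable via
`season_rules`). Emitting indices only once the triggering run is complete
keeps the rule causal. Off-season days carry `NA` indices rather than
zeros so percentile climatologies are not diluted; codes are held and the
Drought Code is overwintered at the next startup with
`Q_spring = a·Q_fall + b·(3.94·r_w)` (r_w = total inactive-period
precipitation, mm). The carryover coefficients are not universal constants;
the defaults `a = b = 0.75` correspond to moderate fall moisture and
moderately effective winter recharge and are exposed as parameters. Cells
with no prior shutdown start from the conventional agency defaults
FFMC 85, DMC 6, DC 15.

## Extreme-fire-weather climatology

`percentile_field` computes FWI95 per cell from in-season days of the
baseline years (default quantile level 0.95), using linear interpolation
between order statistics (R's type-7 rule; the choice is verified against a
brute-force implementation and matters little at ~4,500 baseline days per
cell). Cells with fewer than 100 in-season baseline days are masked — below
that the upper tail is too poorly resolved to define an "extreme" day.

`extent_series` reports, per day and region, the area of forested
(canopy cover > 0.20), season-active cells with FWI strictly above FWI95.
Two normalizations are provided:

* `proportion` — divided by the region's total forested area. This matches
  how daily extent is usually plotted, but its long-run mean is *below*
  the nominal 5% even under a stationary climate, because extreme days
  cluster climatologically in midsummer while shoulder-season days
  contribute near-zero numerators.
* `proportion_active` — divided by the forested area actually in season
  that day. The active-area-weighted mean of this quantity (equivalently,
  pooled in-season exceedance extent) is forced to `1 − q = 5%` by the
  definition of the percentile under stationarity, and that is the form the
  acceptance checks use (observed ≈ 4.9–5.2% across seeds on the
  20 × 20 × 35-year reference scenario).

Cell areas on the lat/lon grid are exact spherical:
`A = R²·Δλ·(sin φ₊ − sin φ₋)`, R = 6371.0088 km.

Standardized anomalies are plain z-scores against per-cell baseline samples
(zero-SD cells masked with a warning). Seasonal ranks (May–October means,
rank 1 = most extreme) support both directions; for precipitation,
"most extreme" means driest. The extent-vs-burn association uses Spearman's
rank correlation with midranks for ties (verified against an explicit
midrank computation), undefined below 3 paired days.

## Blocking proxy in 500-hPa heights

`anomaly_field` standardizes heights against a per-cell *calendar-month*
mean and SD over the baseline years ("seasonal" is not otherwise defined; a
3-month centred pooling is available via `smooth_months`). `detect_events`
flags z > 1 (in local SD units), extracts contiguous regions with
8-neighbour connectivity (4 available), links regions on consecutive days
that share at least one cell — splits and merges resolved by
largest-overlap inheritance, the remainder spawning new events — and keeps
events persisting ≥ 5 days whose footprint reaches ≥ 100,000 km² at some
point, within April–October. Day counting (`blocking_day_map`) touches each
flagged (cell, day) exactly once because daily components partition the
flagged cells.

The recovery scenario (`gen_blocking_scenario`) implants rectangular ridges
of known footprint, duration (3–12 days) and amplitude (3 noise-SD) in an
evaluation year, over a 12-year baseline. The scenario's height climate is
deliberately smooth — seasonal amplitude 30 m, AR(1) 0.6, near-noise-free
evaluation year — because a strong seasonal cycle interacts with
calendar-month climatologies: at month edges the seasonal drift plus
finite-baseline estimation error can push isolated cells past 1 SD,
attaching spurious cells or days to implants and making "exact" truth
ill-defined. With the smooth climate the implants are provably the only
supra-threshold structures, so precision, recall and per-cell day counts
can be required to be exact. Detection thresholds themselves are never
altered. Consequence for real data: in strongly seasonal height fields,
month-edge artifacts of a calendar-month climatology are a real effect the
user should mitigate with `smooth_months = TRUE`.

## Snowmelt and flash drought

Snowmelt timing is the first day of the longest snow-free run in the
calendar year (ties → earliest run; runs do not wrap; never-snow-covered
cells return day 1 as a flagged degenerate case; never-snow-free cells are
`NA`). Departures subtract the baseline-mean melt day (negative = earlier).

The drying statistic scans windows fully inside May 1 – June 30 and
measures `x(t) − x(t + 14)` — the decrease *across* a 14-day span — floored
at zero, with the earliest maximal window winning ties and the onset date
at the window midpoint `t + 7`. The endpoint convention (rather than
in-window max minus min) was chosen because a "maximum amount of drying in
a 14-day sliding window" most naturally means the 14-day change: a steady
1 kg m⁻² day⁻¹ decline then yields exactly 14 kg m⁻². Both statistics are
pinned to brute-force oracles on 1,000 random series, and the generator's
implanted melt days and ramps are recovered exactly. In the generator the
background soil-moisture decline defaults to 0.125 kg m⁻² day⁻¹ — exactly
representable in binary — so that on ramp-free cells all windows tie
*exactly* and the earliest-window convention is exercised rather than left
to floating-point noise.

## Burned area from hotspot buffering

All geometry runs on axis-aligned pixel frames in a spherical Albers
equal-area projection (standard parallels 50°/70° N, origin 40° N, central
meridian 96° W). Polygons are pixel masks: buffering is an exact
point-to-pixel-centre distance test; dissolving is the union it implies;
contraction is morphological erosion via a Euclidean distance transform
(`EBImage::distmap`), keeping pixels whose centre-to-centre distance to
background exceeds `r_in`. The two half-pixel discretization effects (mask
boundary overshooting the true set, and centre-to-centre distance
overshooting the distance to the background region) cancel: measured area
bias on eroded discs is < 0.25% at `res ≤ r/30`, and the buffer identity
`area = π(r_out − r_in)²` for an isolated point holds within 0.5% at the
test resolution (5 m for a 300-m disc; the workflow default is 30–180 m
depending on stage).

Radius optimization evaluates every candidate `(r_out, r_in)` pair against
reference perimeters per ecozone, scoring pooled intersection-over-union
(maximizing overlap while jointly penalizing commission and omission), with
deterministic ties to the smallest `r_out`, then `r_in`. Calibration
factors divide reference by buffered area per ecozone and year and collapse
years by the unweighted mean of ratios (area-weighted pooling available) —
the stratification is by ecozone and year, and equal year weights keep one
anomalous year from dominating. Cleaning erases water before applying the
1-ha minimum (so lake-split slivers are also caught), using 8-connected
components as the polygon unit. The hybrid total is
`Σ reference + Σ (buffered × factor)`, with a hard error if a fire appears
in both sources.

The recovery scenario generates three ecozones with two historical years
(optimization + calibration inputs) and a 20-fire evaluation year (60%
mapped, 40% hotspot-only) with water holes, unburned islands, 12 pre-April
false detections and 3 sub-1-ha artifacts; the candidate grid is
{300, 500, 700} × {0, 150, 300} m. The national total is recovered within
5% (observed |error| ≤ ~2.5% across seeds), the April-1 filter removes
exactly the false detections, and the 1-ha filter exactly the artifacts.
Buffered-then-calibrated estimation corrects *on average*; per-fire errors
remain, which is why the guarantee is on the total, not per fire.

## Day-of-burn kriging

Hotspot times are converted to local standard time with the longitude-band
offset `round(lon/15°)` hours; detections before April 1 are dropped as
off-season false alarms. For each fire (≥ 5 hotspots; otherwise a flagged
nearest-neighbour fallback) the detection dates, as continuous day
ordinals, are interpolated by ordinary kriging to the pixel centres of the
perimeter mask. The variogram (exponential by default; spherical/gaussian
available) is fitted per fire to the binned empirical semivariogram by
weighted least squares on log-parameters; duplicate locations are collapsed
to their mean date; a 1e−9 diagonal ridge stabilizes the solve with
clustered points; above 2,500 points a seeded subsample bounds the linear
system. Predictions are clamped to the fire's observed date range and
rounded half-up to whole days. Conservation is structural: daily areas are
pixel tallies of the day-of-burn grid, so they sum exactly to the footprint
area. On the reference fire (20 days, ~20,000 ha, ~2,000 hotspots at 1 per
10 ha, 180-m grid) the per-pixel MAE is ~0.5 days against the generator's
truth, within the 1.5-day requirement.

## Fire-level summaries

Size classes are left-open intervals (a 200-ha fire is *not* "large");
ignition-month proportions use fires > 1,000 ha; containment is the
fraction of fires held strictly under 200 ha per response type. Duration is
`out − start + 1`; a fire's potential spread days count the days in its
active interval on which *any* overlapping grid cell exceeds its FWI95. The
"90% interval" reported with median durations is the 5th–95th percentile of
the per-fire duration distribution — the parenthetical ranges such summaries
carry are distribution quantiles, not resampled confidence intervals (a
bootstrap could be added, but the quantile reading is the parsimonious
one). The size–spread-day relation is fitted as
`log(size) ~ log(spread days + 1)` by least squares; on synthetic fires
with known exponent γ ∈ {0.5, 1, 2} at n = 200 and log-normal noise
(σ = 0.4), the estimate falls within 2 standard errors — a ~95% event per
draw, so the tests require 4 of 6 replicate scenarios inside the band
rather than betting a single draw. PM2.5 exceedance days use strict
`> 27 µg m⁻³` (the daily ambient standard).

## The synthetic generators: what they do and do not show

`gen_weather` produces seasonal-cycle temperature with per-cell AR(1)
anomalies (φ = 0.7, SD 3 °C), humidity anti-correlated with temperature,
log-normal wind, and thinned-gamma precipitation (wet-day probability
0.35, shape 0.7, scale 6 mm) on a 20 × 20 half-degree grid — chosen as
plausible boreal magnitudes. Implanted heat/dry episodes and height ridges
are recorded in the truth bundle. Fires grow as day-indexed expanding
ellipses with stochastic axis increments (guaranteeing a monotone
day-of-burn field), sampled by hotspots at 1 per 25 ha of daily growth
(1 per 10 ha for the kriging study), above the 1-per-50-ha floor the
buffering calibration assumes.

Deliberate simplifications: no spatial correlation of weather between
cells (per-cell statistics and cell-independence contracts are unaffected,
but spatially coherent extremes are not emulated); no physical fire
spread (ellipses cannot reproduce wind-driven runs or spotting); snow and
soil-moisture series are noise-free where exact recovery is asserted.
Passing tests therefore demonstrate the *correctness of the computations*
— that each statistic measures what it claims on data whose answer is
known — not that the statistical assumptions hold on reanalysis or
satellite data. Problem sizes (35-year 400-cell climatology, 32-fire
burned-area scenario, one 20,000-ha kriging fire, 1,000-sequence oracles)
were chosen so the full suite documents the method at meaningful scale
while remaining quick to run.

## Degenerate inputs and conventions

Calendar dates are R `Date`s; day-of-year is 1-based; intervals include
both endpoints. Inactive-season indices are `NA`, never 0. Zero baseline
SDs mask rather than propagate infinities. Empty hotspot sets buffer to an
empty perimeter set; ecozones with no historical fires are skipped with a
warning; strata with zero buffered area are dropped from calibration with
a warning. A fire present in both hybrid sources, overlapping day-of-burn
grids, series with date gaps, and misaligned grids are hard errors naming
the offending objects. The staged runner (`fs_validate_config`/`fs_run`)
type-checks every stage parameter against a declared schema, aggregates
all violations into one report, recomputes missing upstream intermediates,
and writes a manifest with an MD5 checksum per output; reruns under the
same seed are byte-identical.

## Known limitations

* Vector geometry is raster-based; areas inherit pixel discretization
  (sub-0.5% at the documented resolutions) and perimeters are not exported
  as vector polygons.
* The blocking climatology is calendar-month based by default; see above
  for the month-edge caveat on strongly seasonal fields.
* Overwintering coefficients are scenario parameters, not estimated from
  data.
* Kriging assumes a single variogram per fire and stationarity of the
  date field within the perimeter; long multi-lobed fires may violate
  this (the clamp to the observed date range bounds the damage).
* The pipeline runner covers the weather→extent chain; the burned-area and
  kriging stages are driven by the `analysis/` scripts rather than the
  YAML runner.
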