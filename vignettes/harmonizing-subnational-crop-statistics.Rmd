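---
title: "Harmonizing subnational crop statistics across boundary changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing subnational crop statistics across boundary changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropharmony)
library(dplyr)
```

## The problem

Subnational crop statistics in data-sparse regions arrive as a patchwork:
units report in some years and not others, the same crop appears under
shifting sub-crop labels, fine-level reporting switches to coarser levels
mid-record, and administrative boundaries themselves are redrawn every few
years. Used naively, such a record confounds genuine production variability
with reporting artefacts. `cropharmony` turns a raw table of unit x product x
season x system x year observations of planted/harvested area (ha), quantity
produced (mt) and yield (mt/ha) into continuous, quality-flagged time-series
on a single current set of administrative units, without ever deleting or
silently altering a reported value.

The record layout is a fixed 16-column schema keyed by `fnid`, a geocode
naming an administrative unit *at a specific boundary vintage*; statistics
join to polygon vintages through it. Missing means "not collected" and is
kept distinct from zero throughout: surveys are often skipped precisely in
bad years, so conflating the two would bias every downstream analysis.

## Quality control

Two screening rules operate on each yield series (one series per `fnid`,
product, season, production system). Both write flags; neither touches the
values.

**High-yield outliers (flag 1).** A year is flagged when all three hold:

* its Z-score exceeds 3 standard deviations above the series mean,
* it is at least 250% of the nearest observed preceding *or* following
  yield, and
* the series ever exceeds 0.5 t/ha.

The Z-score alone over-flags short, noisy series; the neighbour ratio
requires the spike to be locally anomalous, not just high; and the 0.5 t/ha
guard exempts low-yielding systems whose relative variance is legitimately
large. The standard deviation is the population convention (divide by *n*),
switchable via `qc_params(sd_type = "sample")`; on a 20-year series of
nineteen 1.0s and one 6.0 this gives z = 4.36 and a flag, while a 4.8 t/ha
year flanked by 2.0s (ratio 240%) has z = 4.09 but is correctly spared.
Z-scores are computed once on the raw series, not re-estimated after
masking: the rule is a single-pass screen, not an iterative estimator.
The 250% test is inclusive (>=), reading "at least" literally.

**Low-variance runs (flag 2).** Repeated values and values lying exactly on
a trend line betray imputation or carry-forward reporting. The second
difference d(i) = y(i+1) - 2 y(i) + y(i-1) is zero along any line; wherever
three consecutive |d| fall below 1.5% of the median series yield, all years
spanned by the window (five, for the default run length of three) are
flagged, and overlapping windows merge. Second differences are only formed
along maximal runs of consecutively observed years, so gaps never fabricate
curvature. The median is taken over all observed yields of the series.

Where both rules hit one year, the outlier code wins: the table schema
carries a single integer flag, and a spike is the more actionable signal.
Both rules are invariant under positive rescaling of the series (all three
tests are ratios), which the test suite checks property-style.
`apply_qc()` recomputes flags from scratch, so it is idempotent and safe to
re-run after any upstream edit.

## Standardization

**Sub-crop re-aggregation.** Reporting vocabularies drift (e.g. "millet"
splitting later into pearl and finger millet). A user-supplied mapping sends
reported products to canonical ones; within each unit-season-system-year,
production and area are summed (missing contributes nothing; all-missing
stays missing) and yield is recomputed as production/area. Seasons are
*never* merged here: season heterogeneity (an "annual" season coexisting
with "short rains"/"long rains") is genuine signal and is preserved; merging
would be a separate, explicit user decision.

**Aggregation across administrative levels.** When fine-level reporting
stops, a continuous series can be built at the coarser level — but summing
whatever happens to report would understate totals in poorly covered years.
The coverage gate admits a coarse aggregate only when reporting subunits
account for at least 50% of the *expected* production of the coarse unit.
Expectation comes from a smoothed production climatology per subunit: a
normalised Gaussian kernel (sd 3 years, truncated at 4 sd) over the observed
production values. Normalised convolution makes the estimate well defined at
every year of the span, including unobserved ones — the natural reading of a
climatology, and the choice documented here because the gate needs a
denominator precisely where observations are absent. It preserves constants
exactly and renormalises gracefully down to a single observation.

The admitted aggregate is the plain sum over reporting members — never
inflated by 1/coverage. Minimal adjustment keeps the output interpretable as
"sum of reports"; inflation is available as an explicit `inflate = TRUE`
opt-in. Lowering the threshold can only add observed years, never remove
them (a monotonicity the tests assert). Yield is recomputed after every
aggregation so yield x area = production holds wherever all three exist.

Planted vs harvested area is metadata: both feed the same `area` column and
the package performs no conversion between the two bases.

## Boundary calibration

Statistics reported on an old boundary vintage must be carried onto the
current units. `detect_boundary_changes()` first matches units 1:1 where the
best-overlapping counterpart changes area by less than 10% — renames and
trivial digitization differences pass through untouched (the 10% trigger is
measured as |new - old| / old). Remaining units are grouped into connected
components of the intersection graph (edges where overlap exceeds a 1%
sliver tolerance) and each component is classified:

* **Case A** — the union of new geometries coincides with the union of old
  geometries (symmetric difference at most 1% of the union) and the
  component is a pure split or pure merge. For a split of one unit into
  *n*, each new unit *i* receives the share
  P_i / sum_j P_j of the old series, where P_i is the new unit's mean
  quantity produced after the change — computed per crop, since crops
  concentrate differently in space. Shares apply uniformly to production and
  area, so every new unit inherits the old yield exactly and per-year totals
  are conserved to machine precision. A merge needs no ratios: the new
  series is the sum of the old ones.
* **Case B** — boundary areas genuinely changed. Production cannot be
  apportioned by post-change reporting (the units are not nested), so the
  transfer is dasymetric: X_new = sum_j X_j x A(new ∩ j) / A(j), with A the
  cropland area extracted from the raster by exact polygon-cell overlay.
  These weights are crop-independent. Totals are conserved exactly when the
  new units tile the cropland of every old unit; otherwise the loss equals
  the untiled weight fraction, and `verify_conservation()` reports the
  per-year discrepancy and whether the tiling condition held.

Decisions taken where the method is underdetermined, recorded here as the
package's own choices:

* The averaging window for Case A shares is the intersection of the new
  units' reporting years when non-empty (comparability), else per-unit means
  with a warning.
* A new unit that never reports a crop falls back to cropland-area shares
  for that crop (production shares are undefined), with a warning.
* In Case B, a missing value in *any* contributing old unit makes the output
  year missing: a partial weighted sum would silently underestimate, which
  mirrors the coverage-gate philosophy.
* Calibration brings old statistics forward onto the current vintage, never
  backwards.

## Cross-validation

`national_annual_production()` collapses the harmonized table to national
annual totals (assignment by harvest year, the closest analogue of
calendar-year reference statistics; switchable), leaving years with no
subnational observation absent rather than zero. Case A calibration provably
cannot change these totals — a cross-module property the tests exercise.
`correlate_with_reference()` computes the Pearson correlation per (country,
product) against a reference table over exactly matching years, reports it
only when at least five overlapping years exist, and returns an explicit
reason (insufficient overlap, constant series) otherwise. Raw production is
correlated by default; `use_log = TRUE` is available. The summary statistic
is the median r over defined cells.

## The synthetic scenario generator

Real deposits are large and not redistributable, so every stage is tested
against `make_scenario()`: gridded integer-coordinate vintages (areas and
overlaps are then exact), a seeded cropland raster, a national reference
series, and crop statistics with known anomalies.

The default conditions are 2 provinces x 5 districts x 5 staple crops
(maize, sorghum, millet, rice, cassava at 0.8-6 t/ha with mild positive
trends) over 20 years — 50 series — with lognormal yield noise at 15% CV,
5 injected spikes (multiplier 6) and 5 injected 5-year constant runs, full
reporting, and a boundary event on request (split into 0.4/0.6 shares,
merge, or a 3-into-4 strip reorganization whose interior strips each
straddle two old units). Area is a fixed unit-crop base (500-2000 ha) with
5% CV year noise, and production = yield x area holds identically, so
generated tables always pass strict schema validation.

Truth labels are guaranteed, not probable: each series is redrawn (up to
200 times) until its clean background contains no year satisfying either
screening rule and every injection satisfies its rule, judged by a compact
inline re-derivation of the rules kept separate from the `qc` module. With
zero noise this guarantee is vacuous — a noiseless trend is by definition
low-variance — so noiseless series are accepted as generated, and the
recovery properties are only claimed for noisy configurations. What the
generator does *not* emulate: spatially correlated weather shocks, reporting
biases correlated with production level, heaping/rounding artefacts, and
multi-season interleaving. Passing recovery tests therefore demonstrate
correctness of the rules' implementation, not their field performance on
real statistics.

## Numerical choices and limitations

* All geometry is planar. The package performs no reprojection: boundary
  and raster inputs must arrive in a common equal-area coordinate reference,
  which is carried as a declared string and checked for equality between
  layers. Boundary files are read from GeoPackage or GeoJSON; rasters from
  Esri ASCII grids (with a sidecar `.prj` note).
* Zonal statistics use exact polygon-cell intersection, not centre-point
  sampling — Case B weights for small units depend on slivers. Intersection
  areas inherit the clipping library's coordinate snapping (~1e-8 of a
  coordinate unit), so conservation identities involving the raster hold to
  about 1e-7 relative; purely arithmetic identities (Case A) hold to 1e-9
  or better.
* Invalid (self-intersecting) polygons are repaired by nonzero-fill
  decomposition where possible and rejected (by identifier) otherwise.
* Test and example problem sizes (50-series scenarios, 20-seed detector
  sweeps, 10x50 rasters) were chosen as the smallest sizes at which every
  property is non-trivially exercised.
* Pairwise vintage calibration only: multi-vintage histories are handled by
  applying the pairwise step in sequence, and no automatic chaining or
  per-country manual override files are provided (configuration hooks
  exist, their content is the user's).

## Worked example

```{r example, eval = FALSE}
library(cropharmony)

sc <- make_scenario(scenario_config(seed = 1, boundary_event = "split"))
out <- run_pipeline(pipeline_config(),
                    records = sc$series$records,
                    records_old = sc$series$records_old,
                    records_new = sc$series$records_new,
                    old_units = sc$vintages$old,
                    new_units = sc$vintages$new,
                    raster = sc$raster,
                    reference = sc$reference)
max(out$conservation$rel_discrepancy, na.rm = TRUE)  # ~1e-16
median_correlation(out$validation)                   # ~0.99
```
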