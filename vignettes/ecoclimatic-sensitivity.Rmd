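---
title: "Process-based ecoclimatic suitability and Taguchi sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-based ecoclimatic suitability and Taguchi sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoclimex)
```

# The model

`ecoclimex` implements a CLIMEX-style process-based climatic niche model.
The premise is eco-physiological: in a favourable season a population grows;
in an unfavourable one it must survive.  Growth and survival are scored
separately from weekly climate and combined into a single annual score, the
Ecoclimatic Index (EI), on a 0-100 scale.

## Growth

Weekly growth is the product of two trapezoidal responses,

* a temperature index TI(t), zero at or below the limiting low temperature
  DV0 and at or above the limiting high temperature DV3, one on the optimal
  plateau [DV1, DV2], linear on the ramps; and
* a moisture index MI(s) with the same shape over the soil-moisture knots
  SM0-SM3, where s is soil moisture as a fraction of bucket capacity.

The weekly growth index is GI_w = TI_w x MI_w and the annual growth index
GI_A is its mean over the 52 weeks.  TI is evaluated on the weekly *mean*
temperature: the optimal range describes the conditions growth responds to,
while the stress thresholds below are physiological extremes and therefore
read the weekly minima and maxima.

## Stress

Each stress (cold, heat, wet) has a threshold and a weekly accumulation
rate.  Cold stress accumulates when the weekly minimum falls below TTCS,
heat stress when the weekly maximum exceeds TTHS, wet stress when soil
moisture exceeds SMWS.  Weekly increments are `|rate| x exceedance`,
multiplied by the number of consecutive stressed weeks so far, so
accumulation grows superlinearly with stress duration -- one mild week is
almost harmless, a season of them is fatal.  The counter resets on any
stress-free week.  The annual sum is capped at 1, the point at which the
species cannot persist.  The exact recurrence used by the proprietary
implementation this model emulates is not published; the consecutive-week
multiplier is this package's declared realization of "exponential"
accumulation, chosen because it is deterministic, monotone in both rate and
exceedance, and reproduces the qualitative all-or-nothing behaviour of
threshold stresses.  Cold-stress rates are conventionally printed negative
(THCS = -0.01/week); the sign is stored but the magnitude is applied.

No dry stress is implemented: the date-palm parameterization defines none,
dryness already acts through MI = 0.

## The Ecoclimatic Index

EI = 100 x GI_A x (1 - CS) x (1 - HS) x (1 - WS).

The multiplicative form honours both printed anchors: EI is capped at 100,
and any stress reaching 1 forces EI = 0 regardless of growth.  Categories:
EI = 0 unsuitable, 0 < EI < 10 marginal, 10 <= EI < 20 suitable, EI >= 20
highly suitable.  The published category definition leaves the boundary
values unassigned (strict inequalities on both sides); this package assigns
10 and 20 to the upper category so the four intervals partition [0, 100].

## Default species parameters

The defaults are the fitted date-palm (*Phoenix dactylifera*) values: a
wide thermal plateau (DV1 = 20 to DV2 = 39 C) between DV0 = 14 and
DV3 = 46 C; extreme drought tolerance (SM0 = 0.007, SM1 = 0.013) with
waterlogging sensitivity (SM2 = 0.81, SM3 = 0.9); and stress pairs
TTCS = 4 C / THCS = -0.01, TTHS = 46 C / THHS = 0.9, SMWS = 0.9 /
HWS = 0.022 per week.

```{r}
unlist(species_parameters())
```

# From monthly normals to weekly forcing

The driving data are long-term monthly normals (minimum and maximum
temperature, precipitation, relative humidity at 09:00 and 15:00) on a
regular grid.  Weekly series use a fixed 52 x 7-day year: temperatures are
interpolated linearly between month midpoints (cyclic over the year) at
week midpoints rescaled from the 364-day week calendar onto the 365-day
month calendar; weekly precipitation is the midpoint month's total times
7/days-in-month.  This conserves the annual total to within 3 % (tested),
which is well below the uncertainty of any climatology.  Humidity fields
are carried through I/O for completeness but the default water budget does
not consume them.

## The soil-moisture bucket

Weekly storage follows a single-store balance
`sm_w = clamp(sm_(w-1) + (P_w - E_w)/C, 0, 2.5)` with evaporative demand
`E_w = k x max(0, tavg_w)`.  Defaults: capacity C = 100 mm, k = 0.8 mm per
degree C per week (about 1000 mm/year of demand at 25 C, a mid-range
potential evapotranspiration), maximum storage 2.5 x capacity so that
waterlogged states above field capacity exist and can trigger wet stress.
Storage is expressed as a fraction of capacity, which is the scale on which
the moisture knots (SM0 = 0.007 ... SM3 = 0.9) are defined -- those values
only make sense capacity-normalized.  The annual cycle is iterated from an
initial storage of 0.5 until two successive years agree within 1e-6
(at most 20 cycles).  Whenever the forcing ever clamps the store (a fully
dry or fully saturated week), the converged cycle is independent of the
initial value; under exactly neutral forcing the initial value persists,
which is a documented property of any conservative bucket.

This budget is deliberately the simplest defensible one: no
Penman-Monteith, no radiation, no irrigation.  The proprietary hydrology it
stands in for is undisclosed, so the package treats the budget as a declared
replacement, not a reconstruction.

# The Taguchi sensitivity analysis

The question: which of the fourteen parameters move the predicted suitable
area most?  A full factorial at three levels would need 3^14 runs; the
mixed-level orthogonal array L54(2^1 x 3^25) needs 54.

## The orthogonal array

The packaged array has 54 runs and 26 columns: one two-level column (27/27)
and twenty-five three-level columns (18/18/18), every pair of three-level
columns strength-2 balanced (each of the nine level pairs exactly 6 times).
It is built constructively over GF(3) (an Addelman-Kempthorne-type
construction: runs indexed by a half indicator and a vector in GF(3)^3;
thirteen linear-form columns plus twelve quadratic columns whose y1^2 term
flips sign between halves, with correction constants that make the
quadratic Gauss-sum defects of the two halves cancel).  The construction is
validated exhaustively at load -- balance and all 300 column pairs -- so its
correctness does not rest on the algebra.

## Factor-to-column allocation

Each factor occupies one three-level column; eleven three-level columns and
the two-level column stay unassigned.  The allocation is not arbitrary: in
a strength-2 array, the interaction contrast of two columns aliases onto
specific other columns.  Trapezoidal responses make within-family
interactions unavoidable -- the slope of the upper temperature ramp depends
on DV2 *and* DV3, and the ordering repairs couple knot pairs as well -- so a
naive allocation lets, say, the DV2 x DV3 interaction masquerade as a main
effect of an unrelated factor (we observed ~0.2-0.9 dB of spurious delta
on moisture and stress factors in climates where those factors provably do
nothing).  The default allocation therefore follows classical linear-graph
practice: the package computed the array's full triple-balance structure
and placed the four temperature knots and the four moisture knots on column
families whose within-family interactions fall only on unassigned columns.
`build_design(columns = ...)` overrides this for users who want a different
allocation.

## Runs, repairs, response and SN

Each run materializes a full parameter set from the factor levels
(level 2 of every factor is the baseline value).  Combinations that violate
knot ordering (e.g. DV2 = 45 with DV3 = 40) are repaired by clamping the
upper knot to the lower knot + 0.1 -- a degenerate ramp -- and every repair
is logged; 30 of the 54 runs require at least one repair under the packaged
factor table.

The response y of a run is the combined area (km^2) of the suitable and
highly suitable categories.  The model is deterministic, so each run is a
single replicate and the larger-the-better signal-to-noise ratio reduces to
SN = 20 log10(y); the general form -10 log10(mean(1/y^2)) is implemented
and tested for multi-replicate input.  Larger-the-better is the natural
class for an area the analysis seeks to characterize by its maximum
response; nominal-best would require an arbitrary target.  A run with
y = 0 has no defined SN; such runs are floored to 1 km^2 and flagged,
which preserves ranks (any positive floor below the smallest real response
would) without discarding the run.

Main effects: the mean SN over the 18 runs at each level of each factor;
the sensitivity delta is the range of the three level means; factors are
ranked by delta with ties broken in factor-table order; the optimum level
is the argmax, flagged when it coincides with the baseline level.

# The synthetic climate generator

The generator emulates the *structure* of a 0.5-degree global climatology:
12 monthly values per variable per cell, a latitudinal temperature gradient
(equator mean 30 C, lapse 0.45 C/degree) with a seasonal sinusoid
(amplitude 9 C, phase inverted in the southern hemisphere), a fixed diurnal
half-range of 6 C (the tmin/tmax structure of real normals is not modelled
beyond this), an arid belt (|lat| 15-35, 250 mm/year) blending linearly
into humid surroundings (1000 mm/year) over 8 degrees, monsoonal
precipitation seasonality (amplitude 0.7, wettest in the local summer), and
humidity increasing monotonically with annual precipitation.  Cell-wise
noise (sd 0.5 C) is applied once to the annual mean so seasonal shapes stay
smooth; identical seeds give bit-identical grids.  These values were chosen
once as a plausible subtropical configuration in which the date-palm
parameters produce all four suitability categories along the gradient; the
demonstration region (6-24 N, 44-64 E at 0.5 degrees, 1440 cells) sits
across the humid-to-arid transition.

What the generator does *not* emulate: spatial autocorrelation beyond the
latitudinal gradient, orography, coastlines or land masks, interannual
variability, and any covariance between temperature and precipitation
noise.  Tests passing on synthetic grids therefore demonstrate the
correctness and the qualitative behaviour of the pipeline, not predictive
skill on real climatologies.

The occurrence fixture (145 records, 19 without coordinates, sources
labelled GBIF/MBG/literature/survey) reproduces the counts and missingness
structure of a typical multi-source compilation; the records' locations are
uniform draws over the demonstration region and carry no ecological signal.

# The engineered recovery climates

The strongest end-to-end test of the sensitivity machinery is parameter
recovery: in a climate where only one climatic axis limits the species,
only that axis's parameters should show sensitivity.  Two such climates are
packaged.

`climate_temperature_limited()`: weekly mean temperature spans 6.5-38.5 C
across latitude and season with zero diurnal range, so minima stay above
every cold-stress level (max 5 C) and maxima below every heat-stress level
(min 40 C); precipitation is scheduled so the converged soil-moisture cycle
is either exactly 0 or inside the plateau common to all moisture levels,
with every transition week stepping over the dry ramps (0.005-0.017).  The
growing season is moisture-gated to about 19 weeks, which pins the warm and
cold edges of the grid near the EI = 10 boundary where temperature-knot
changes move the suitable area.  Result: nonzero deltas for DV0-DV3 only.

`climate_moisture_limited()`: constant 28 C mean (inside the plateau for
every temperature level), extremes kept away from all stress thresholds;
a latitudinal wetness gradient drives a short moisture pulse -- an
exactly-attributed February rise, a March hold, a single-week evaporative
collapse under a higher-demand bucket (k = 2.1) -- whose peak sweeps from
the dry ramps through the plateau up to 0.58.  Result: nonzero deltas for
SM0-SM3 only.

Two structural confounds shape these designs and are worth knowing about
when interpreting any analysis of this model family.  DV3 shares its level
values (40/46/50) with TTHS, and both compare against weekly temperature:
a climate in which the DV3 knot binds directly (means above 40 C) must
trigger heat stress at some level.  DV3's recovered sensitivity therefore
flows through the slope of the upper ramp in runs with DV2 = 30 (means in
30-39.5 C), which is clean.  Symmetrically SM3 shares levels (0.6/0.9/1)
with SMWS, and its sensitivity is probed through the upper moisture ramp in
runs with SM2 = 0.5 (storage in 0.5-0.58).  These are properties of the
parameterization itself -- upper growth limits and the corresponding stress
thresholds are nearly redundant descriptions of the same physiology -- and
they are one reason a sensitivity analysis of this model should be read at
the family level.

A technical note: weekly precipitation attribution (7/days-in-month at the
week's midpoint month) delivers a month's total scaled by the number of
week midpoints falling in it; the scheduling helper divides the
storage-changing part of each month's precipitation by that attribution
factor so weekly storage tracks the prescribed monthly targets exactly.
February is the only month whose factor is exactly 1, which is why the
moisture pulse rises there.

# Area accounting, change maps and validation

Cell areas use the spherical band formula on the authalic sphere
(R = 6371 km), so a 0.5-degree cell shrinks from ~3091 km^2 at the equator
by the cosine of latitude.  Category areas exclude no-data cells from both
the categories and the total, keeping the partition exact.  Change maps
pair each cell's baseline and adjusted categories into a 4 x 4 transition
table whose marginals equal the two rasters' own category areas.
Occurrence records map to cells half-open on the east and north edges
(`[west, east) x [south, north)`), a deterministic, partition-complete
convention; records outside the grid, in no-data cells, or without
coordinates are tallied separately so all counts sum to the raw total.

# Numerical choices and problem sizes

* Soil-moisture convergence: sup-norm 1e-6 between annual cycles, at most
  20 cycles, initial storage 0.5.
* Classification boundaries at EI = 10 and 20 go to the upper category.
* Rank ties broken by factor-table order; optimum-level ties by the lower
  level.
* Repair offset 0.1 (degenerate ramp) for both temperature (degrees C) and
  moisture (fraction) knots; on the moisture scale 0.1 is a substantial
  step, but a repaired run is by construction outside the physical range
  and only needs a valid, logged parameter set.
* The oracle-equivalence tests run the gridded pipeline against an
  independent scalar implementation on 3 x 3 grids at 1e-9 relative
  tolerance; recovery runs the full 54-run design on 20 x 20 grids (a few
  seconds); the monotonicity and conservation properties are tested over
  100 random scenario/parameter draws on 3 x 3 grids.  These sizes give
  fully converged, deterministic answers; nothing about the method changes
  at larger grids beyond runtime, which scales linearly in cells.

# Known limitations

* The water budget is a one-parameter-demand bucket; real soil hydrology,
  snow, runoff and irrigation are out of scope.
* The stress recurrence is a declared stand-in for an unpublished one;
  absolute stress values should not be compared against other software,
  though thresholds, monotonicity and the EI = 0 persistence rule match.
* The generator's worlds are latitudinal caricatures; use real normals for
  any substantive distribution question.
* Sensitivity deltas depend on the response (suitable + highly suitable
  area) and on the factor table's level spacing; they are comparative, not
  absolute, measures.
* No diapause, light or substrate indices, no multi-species composites, no
  climate-change scenario projections.
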