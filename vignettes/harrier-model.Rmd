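---
title: "An individual-based model of hen harrier population dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of hen harrier population dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harrierIBM)
```

## The model

`harrierIBM` simulates a hen harrier (*Circus cyaneus*) population as a set
of individual birds on a static raster landscape of 1-km cells.  Each cell
carries five attributes: a meadow pipit abundance index (the main prey on
heather moorland), a heather-burning index on the integer scale 0--4 (a
proxy for the intensity of grouse-moor management and hence for the risk of
illegal persecution), a habitat-suitability index, the heath area in
hectares, and the mean altitude.  Each bird carries an id, age, sex,
breeding status, last year's breeding outcome and its natal and current
cells.  The only mutable cell state is the residency registry: at most one
resident male and one resident female per cell (monogamy is assumed
throughout).

One time step is one year, beginning in spring, with five sub-models in
fixed order:

1. **Breeding site selection.**  Birds that bred successfully last year keep
   their territory and partner; a successful female whose mate died over
   winter re-disperses, as do all unsuccessful birds and all first-years.
   Dispersal is a two-stage choice described below.  All males settle before
   any female chooses.
2. **Pair census** (the observation step).  A breeding pair is a resident
   female aged one or more sharing a cell with a resident male.  The census
   precedes persecution so that females about to be killed are still counted
   as attempting pairs, matching how field surveys see them.
3. **Persecution mortality.**  Each breeding female dies with probability
   `PERSmort[burning index] * PMF` (clamped at one).  Males and non-breeders
   are not persecuted.
4. **Reproduction.**  Each surviving breeding female fails completely with
   probability `PFAILGMOOR` on heavily managed grouse moor (burning index
   above `GMBIT`) or `PFAILOTHER` elsewhere.  Otherwise her brood is
   `max(1, Poisson(MFLEDGE))` fledglings — the floor reflects that the nest
   has already been classed successful — each fledgling male with
   probability one half, placed in the parents' cell.  The pair's `success`
   flag records this outcome and drives next spring's site fidelity.
5. **Winter mortality and clean-up.**  Adults and juveniles die with their
   class- and sex-specific probabilities; survivors age one year; surviving
   juveniles join the adult list as one-year-old non-breeders.  Dead birds
   are then removed, their residency slots vacated, and the adult processing
   order is reshuffled.

## Two-stage site selection

A dispersing bird first chooses a *landscape-scale (LS) square* — a
`LOCDIM` × `LOCDIM` block of cells (9 × 9 km by default) — from the
`LANDDIM` × `LANDDIM` arrangement of LS squares centred on its current cell
(11 × 11 squares, a ±49.5 km reach).  Every square gets a score; the bird
draws one square with probability proportional to score × distance weight
(roulette-wheel selection), then draws a cell within that square with
probability proportional to the meadow pipit index of the eligible cells,
with no distance or capacity weighting at the cell stage.

A cell is *suitable* when heath ≥ `MINHEATH` (inclusive), suitability ≥
1e-7 (effectively any positive value) and altitude ≤ `MAXALT` (inclusive).

**Male square score.**  With `T` the sum of meadow pipit indices over the
suitable cells of the square, `K_i` the per-cell carrying capacity (below),
`N` the number of resident males in the square, and
`K_eff = (Σ K_i) × (fraction of cells suitable)`:

    score = T × max(0, K_eff − N) / K_eff

and zero when no cell is suitable or `K_eff` is zero.  All cells — suitable
or not — contribute to `Σ K_i`, because unsuitable cells can still serve as
foraging ground; the suitable-fraction multiplier then discounts the
capacity to the available nest sites.  A negative numerator (more males
than capacity) clamps to zero so scores remain valid roulette weights.

**Female square score.**  The number of cells holding a resident male but
no resident female.  At the cell stage a female needs a lone resident male
in a suitable cell that is not her natal cell.

**Distance weight.**  `exp(−k d)` with `d` the Euclidean distance in cells
from the bird to the square's centre and `k` context-specific: natal
dispersal (first-years) `KDISTNM` = 0.04 (males) / `KDISTNF` = 0.50
(females); post-failure dispersal `KDISTFM` = 0.50 / `KDISTFF` = 0.90.
Males roam far from the natal site; failed breeders re-settle nearby.

**Long-distance dispersal.**  Before searching, each first-year performs a
long-distance movement with probability `PLDD` = 5%: a distance from a
sex-specific normal (males 150 ± 67 km, females 100 ± 42 km; negative draws
redrawn) in a uniformly random direction, with up to nine attempts to land
on a land cell, otherwise staying put.

**Fallbacks.**  A male whose whole search area scores zero, or whose chosen
square offers no eligible cell, becomes a non-breeder where it stands.  A
female whose whole search area scores zero moves one LS square (`LOCDIM`
cells) in a uniformly random compass direction — among the directions that
keep her on the grid — and tries once more before giving up.  First-years
are pre-filtered by the breeding-eligibility draws `PBREED1M` = 13% and
`PBREED1F` = 80%; ineligible first-years still perform the selection
movement but never claim residency (and thus cannot attract mates), which
is our resolution of a case the status codes imply but do not spell out.

## The carrying-capacity curve

The per-cell capacity `K_i ∈ [0, 1]` (at most one territorial male per
km²) is a saturating function of half the meadow pipit index — the 0.5
converts a per-2-km transect count to the per-km scale on which the
underlying density observations were made.  The exact curve used with the
original national data set is not recoverable, so the package treats it as
a pluggable monotone function with a piecewise-linear default

    K_i = min(1, 0.5 × MP_i / KSCALE),    KSCALE = 10,

which reaches the one-male ceiling at MP = 20, roughly half the maximum of
the prey model's range (43.5).  This is the one genuinely free shape in the
model: absolute equilibrium densities scale with it, so comparisons across
scenarios (elasticities, factorial grids) are more trustworthy than
absolute abundances.  `KSCALE` is an ordinary parameter and can be varied
like any other.

## Parameters

Defaults (see `harrier_params()`): thresholds `MAXALT` 600 m, `MINHEATH`
20 ha; search geometry `LANDDIM` 11, `LOCDIM` 9; persecution `PERSmort`
(0, 20, 40, 45, 50)% for burning 0--4, multiplier `PMF` 1.0, grouse-moor
threshold `GMBIT` 2; breeding `PFAILGMOOR` 63%, `PFAILOTHER` 40%,
`MFLEDGEGMOOR` 4.26, `MFLEDGEOTHER` 3.99 (the fledgling means already fold
in repeat breeding attempts); winter mortality 22% for adults and 64% for
juveniles of both sexes.  Percentages are stored on the 0--100 scale.

Two closed-form consequences anchor the test-suite: on uniform grouse moor
the proportion of successful attempts converges to
(1 − 0.45)(1 − 0.63) = 0.2035 and fledgling production to
0.2035 × (4.26 + e^−4.26) ≈ 0.870 per breeding female per year; on uniform
other habitat, 0.60 and 0.60 × (3.99 + e^−3.99) ≈ 2.405.

## Initialisation

Breeding pairs are released into random distinct land cells of rectangular
regions, one pair per cell, both members resident, ages uniform on
{2, ..., 5} and flagged as previous-season breeders, so year one opens with
established territories.  The default release follows the 1988/89 census
apportionment: 71 pairs in Orkney, 20 Hebrides, 85 North Highlands, 148
West Highlands, 109 East Highlands, 80 Southern Uplands, 18 England and 27
Wales — 558 pairs in all.  Each region is then augmented with
non-breeders, `NBRATIO` = 42% of its pairs (rounded to the nearest integer
per region, since releases are described per region), released in
male–female pairs of one-year-olds that hold no residency.  The exact
region rectangles used with the original data set are not published;
`gb_default_regions()` ships coarse approximations on the 599 × 1205-cell
British National Grid extent, and any region table can be supplied through
the configuration.  Counting regions for output are configured separately
from release regions; cells outside every counting region still count
towards the national total.

## The synthetic landscape generator

The five real input layers for Great Britain are not distributed, so
`generate_synthetic_landscape()` produces layers with the same value ranges
and granularity: a smoothed random prey field rescaled to [0, `mp_max`]
with `mp_max` = 43.5 (the prey model's maximum), heath and suitability as
smoothed fields, altitude as a squared smoothed field (skewing cells toward
low ground) up to 1300 m, and a blockwise burning index constant over
10-km blocks — the scale at which the real index was derived — drawn from a
configurable frequency distribution whose default makes heavily managed
moor a minority class.  Constant-layer overrides give the uniform
landscapes used for closed-form checks, and `sea_margin` adds a NODATA
ring for coastline-dependent dispersal tests.

What the generator deliberately does **not** emulate: the spatial
correlation *between* layers in real uplands (prey, heath, altitude and
management co-vary), coastline geometry, and the regional geography of
Great Britain.  Tests passing on synthetic landscapes therefore validate
the mechanics and the demographic arithmetic of the simulator, not its
ability to reproduce the real national trajectory, which depends entirely
on the withheld input layers.

## Numerical and scheduling choices

* Cell indices are 0-based in map units and 1-based inside R; `x` is the
  easting column, `y` the northing row counted from the south; ESRI ASCII
  grids are read and written with their native north-first row order.
* Off-grid or sea cells are everywhere "unsuitable, score zero" rather than
  errors, so searches near edges degrade gracefully; LS squares keep
  whatever on-grid cells they have, and the suitable-cell fraction is still
  taken out of the full `LOCDIM²`.
* Roulette draws use `sample.int(n, 1, prob = w)`; an all-zero weight
  vector means "no choice" and triggers the fallbacks above.
* One R RNG stream per replicate, seeded from `(base_seed, replicate)` and
  consumed strictly in scheduling order; identical configuration and seed
  reproduce a run bit for bit.  Reordering optimisations would break this
  and are therefore avoided.
* The hot path precomputes the static per-square sums (`T`, `Σ K_i`,
  suitable-cell counts) for every possible square centre with summed-area
  tables and keeps the dynamic male counts as incrementally updated
  box-count matrices; the exported per-square scoring functions use direct
  enumeration and the test-suite checks the two paths agree exactly.
* A widowed successful female disperses with the post-failure female
  weight `KDISTFF`; she is not a natal disperser and the model has no
  separate widow class.
* Persecuted females keep their residency slot until clean-up, and their
  mates stay resident and unpaired for the rest of the year (persecution
  follows dispersal; there is no second pairing pass within a year).

## Experiments

`run_elasticity_experiment()` perturbs one scalar parameter to `P ± P/10`,
runs both scenarios with the same replicate seed stream, and reports the
elasticity at the census calendar years (1998, 2004, 2010) plus 2030:

    e = ((BP₊ − BP₋) / BP₋) / ((P₊ − P₋) / P₋)

with both denominators at the lower end of the range.  Integer parameters
are rounded with the adjusted difference; for `GMBIT` = 2 both perturbed
values round back to 2, so the experiment falls back to a unit step
(1 and 3) and flags the deviation in its output — the published handling of
this collision is unstated, so the fallback is surfaced rather than hidden.
`run_factorial_grid()` crosses the persecution factor (0--2 in steps of
0.5) with juvenile winter mortality of both sexes (0--96% in steps of 16%),
35 scenarios of 20 replicates each by default.

## Problem sizes in the test-suite

The shipped tests run the full annual cycle on constructed landscapes:
uniform 100 × 100 grids with roughly a thousand released pairs over six
years and several replicates for the breeding-statistic checks (at least
20,000 breeding female-years each), and a 100 × 100 synthetic landscape
with a deliberately modest prey ceiling (`mp_max` = 6, i.e. a carrying
capacity of a few hundred pairs) for the 50-year × 20-replicate
paired-seed mortality experiments.  The modest ceiling keeps the
equilibrium population, and with it the runtime, small while leaving the
qualitative structure — growth under baseline mortality, decline under
elevated mortality, extinction at 96% juvenile mortality — intact.  The
paired-mortality checks raise juvenile mortality (both sexes jointly, as
in the factorial design), adult mortality (both sexes jointly) and the
persecution factor, one class at a time.

## Known limitations

* Polygyny is absent by design, although it is widespread in the species;
  all pairing is strictly monogamous.
* The landscape is static: no temporal change in prey, management intensity
  or habitat, hence no capacity to track real decade-scale trend changes.
* Density dependence acts only through territory saturation (the `K_eff`
  discount); there is no density-dependent mortality or productivity.
* The `K_i` curve is a calibrated stand-in (see above); absolute abundances
  inherit its uncertainty.
* Movement is a sequence of draws, not a path; perceptual error and memory
  of previous sites are not modelled.
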