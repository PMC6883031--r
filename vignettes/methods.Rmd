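---
title: "Modelling migratory-strategy energetics for Arctic seabirds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling migratory-strategy energetics for Arctic seabirds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

polarflyway asks a biogeographic question with an energetic answer: when
summer sea ice no longer separates the Atlantic from the Pacific, which
overwintering strategies become available to an Arctic-breeding seabird, and
what does each cost? The package chains five models — a species screen, a
habitat-suitability ensemble, distance-rule habitat derivation, constrained
route construction, and a steady-state heat-balance engine — and runs them
end to end on synthetic gridded worlds whose structure (and whose truth) is
fully known, so every stage can be validated quantitatively.

## The species screen

The screen is a filter cascade over a trait table: retain species breeding
in the Arctic whose breeding range overlaps the Arctic by at least 5%
(inclusive), classify migrants and partial migrants by winter habitat
(pelagic, coastal marine, other), and flag documented polar-night activity.
Pelagic migrants are candidates for transarctic migration; marine-wintering
migrants with polar-night competence are candidates for year-round
high-arctic residency. Species that are already residents are assumed to
remain so. The packaged table
(`inst/extdata/species_traits_synthetic.csv`) is synthetic: its species are
placeholders and only its marginal counts (449 breeders; 359 at the overlap
threshold; 316 migrants; 29 pelagic plus 37 coastal-marine winterers; 24
polar-night-capable) are meaningful, because the testable surface of this
module is the cascade arithmetic, not the underlying bibliography. The
polar-night flag is an input: whether a species can forage in darkness is a
bibliographic fact no algorithm here could derive.

## The synthetic world

`make_synthetic_world()` generates monthly fields per climate member and
scenario on a regular cell-centered latitude–longitude grid (degrees east in
[−180, 180), distances on a 6371.0 km sphere):

* **Air temperature** = latitudinal gradient (30 − 0.55·lat °C) + seasonal
  cosine peaking in July, with the amplitude halved over ocean (maritime
  moderation) + a member-specific warming delta in the future scenario +
  smooth spatial noise (bilinearly interpolated coarse white noise, SD 1 °C)
  + fine-scale noise (SD 0.3 °C).
* **SST** = 0.85·airtemp + 1.5, floored at −1.8 °C (freezing seawater).
* **Sea ice** = a decreasing logistic of the pre-floor SST scale, with
  center and width chosen so water warmer than 5 °C is essentially ice-free
  while additional warming keeps thinning ice over cold water.
* **Snow fraction** (land only) = a decreasing logistic of air temperature.
* A **land mask** (default: two meridional continents flanking an open
  Atlantic sector, an open Pacific sector and an open Arctic basin),
  **bathymetry slope**, and a **coast-distance class** raster with
  right-open breakpoints {10, 20, 50, 100, 200} km computed by great-circle
  distance to the nearest coastal cell center.

Two deliberate anomalies construct the inter-basin asymmetry the strategy
comparison hinges on: a midlatitude Pacific sector 10 °C warmer in deep
winter (November–March, 40–65°N) and a Barents-like warm-inflow tongue
(+8 °C, winter, 10–100°E north of 60°N) that keeps the sea near the
demonstration colony within the species' thermal niche — without it no
residency area exists at all, whereas the warmer members of a climate
ensemble are exactly where residency is expected to become feasible. The
default warming deltas (3 and 4 °C for the two demo members) sit in the
mid-century strong-forcing range.

What the generator does **not** emulate: ocean currents and fronts,
interannual variability (one representative year per scenario),
productivity or prey fields, and observation biases in occurrence data.
Passing tests therefore demonstrate that the machinery recovers what it is
pointed at, not that real little auk data would behave as cleanly.

Presences are sampled over marine cells proportional to a known logistic
suitability `plogis(b0 + Σ b_v·env_v)`; coefficient names with an `_sq`
suffix add quadratic terms, which is how the demo species' thermal-band
preference (suitability peaking near −5 °C air temperature and falling off
on both sides) is expressed. A band, rather than a monotone preference, is
what makes the environmental-envelope pseudo-absence design meaningful:
absences exist on both the too-cold and the too-warm side.

## The suitability ensemble

Four pluggable learners (boosted trees, random forest, classification tree,
linear discriminant) are fitted over every pseudo-absence set for several
cross-validation runs; each model is scored with the True Skill Statistic
(sensitivity + specificity − 1, maximized over thresholds at midpoints of
sorted unique scores, ties to the lower threshold) on a random 25% hold-out,
and the ensemble predicts the TSS-weighted mean with negative-TSS members
excluded. Two pseudo-absence designs are implemented: the environmental
envelope (sample cells with at least one predictor outside the presence
min–max envelope; the cell environment is the mean over the presence season
months so the comparison is like for like) and the distance buffer (cells
more than 2° of arc from every presence). Pseudo-absences are dated by
resampling the presence date distribution and their environments extracted
at their own location and date.

Learners receive prevalence-0.5 case weights (both classes contribute equal
total weight). Without this the presence/absence imbalance shrinks
predicted probabilities toward absence and the ensemble cannot reach the
conservative 0.9 suitability threshold even in core habitat; with it the
threshold behaves as intended. Ensembles are evaluated with the continuous
Boyce index (Spearman correlation between 101 overlapping suitability
windows of width 0.1 and their presence-to-background frequency ratio).

The recovery experiment (`recovery_experiment()`) uses the buffer design:
buffer pseudo-absences overlap the presences environmentally, which yields
graded, Boyce-evaluable maps, whereas envelope absences produce
near-binary discriminators. It fits 3 sets × 2 runs × 4 learners on 300
presences from a two-predictor logistic law, and measures ensemble TSS on an
independent validation draw plus the Boyce index of the projected map — with
uniform and inverted presence sampling as negative controls.

## Habitats, routes and destinations

Suitability maps (winter-month means) are thresholded strictly above 0.9.
Breeding areas are suitable nesting cells with suitable foraging within
200 km; residency areas are marine suitable-wintering cells within 250 km of
a breeding site, and an empty result is a valid "residency infeasible"
outcome, reported per climate member. All distance rules use cell-center
great-circle distances with inclusive radii; neighbourhood searches use a
latitude-band prefilter that is exact (a band of radius/111.195° contains
every cell that could qualify) and is tested against brute force.

Routes live on the 8-neighbour grid graph. The direct route is the
discretized great circle when no consecutive land run exceeds 100 km;
otherwise an exact Dijkstra search over (cell, land-run) states, with the
accumulated run discretized in 10 km buckets rounded upward so accepted
paths can never exceed the limit. A leg counts as land only when both its
endpoint cells are land; coastal legs reset the run. The peripheral route
minimizes `length × (1 + β·[ice ≥ 0.5])` with β = 10 by default — large
enough to dominate routing where open water exists at comparable cost,
finite so crossing residual ice stays possible (the concentration threshold
and β are configurable; the field describes "dense" ice qualitatively). One
subtlety the tests encode: the guarantee "peripheral ice exposure ≤ direct
ice exposure" is an optimality corollary *within the graph family* — against
the free great-circle polyline small discretization differences can go
either way, so the invariant is asserted against the zero-penalty shortest
grid path.

Wintering destinations follow the published rules: the current-strategy
destination is the suitability centroid of the Atlantic-sector consensus
cells (cells suitable for every member, falling back to any member when the
intersection is empty); the transarctic destination is the consensus Pacific
cell nearest the colony; the residency destination is the residency-area
centroid, per member. The spring return journey reuses the September route
except for the transarctic strategy, where both a direct and a peripheral
(ice-avoiding) March return are computed and reported side by side.

## The heat-balance engine

The bird is a horizontal cylinder (core diameter 0.055 m, length 0.18 m for
the ~160 g default) wrapped in a plumage shell (depth 12 mm, effective
conductivity 0.045 W m⁻¹ K⁻¹). At steady state the metabolic heat conducted
through the shell, `2πkL(Tb − Ts)/ln(r_out/r_in)`, equals the external loss
at the plumage surface: forced convection (Hilpert cylinder-in-crossflow
correlation with fluid properties at the film temperature and a calm-air
floor of 3 W m⁻² K⁻¹) plus full-T⁴ longwave exchange with an effective sky
(clear sky 20 K below air temperature, blended linearly with cloud) over a
radiating fraction 0.8 of the outer area, minus absorbed shortwave (zero in
the polar night). On water the surface splits by the immersion fraction
(default 0.55): the immersed part exchanges with water by convection only,
the emergent part with air and sky. The surface temperature is found by
bisection (interval tolerance 10⁻⁶ relative, ≤200 iterations; the residual
closure at the solution is returned and tested below 10⁻⁵). The required
metabolic rate inflates the net loss by a respiratory evaporative share
(default 5%) and is floored at the basal rate (1.8 W), flagged
thermoneutral when the floor binds and heat-stressed when the gradient
reverses.

All physiological defaults are synthetic placeholders sized for a small
diving seabird — plausible in magnitude (the resulting 430–560 kJ day⁻¹
daily costs fall in the range reported for wintering little auks) but not
calibrated to any proprietary parameterization; users override them per
species via `bird_spec()`. Flight is an input power (11 W default) that is
assumed to cover flight thermoregulation; no aerodynamic model is included.

## Budgets and the strategy comparison

The non-breeding season is September (outbound migration), October–February
(wintering) and March (return), 212 days with a non-leap February.
Wintering months use the destination's monthly environment with a 90%
on-water / 10% rest-in-air budget; migration months use the route-averaged
environment (leg-length-weighted at leg midpoints) with the flying fraction
from the one-month, 13 m s⁻¹ rule and the remainder split by the same
budget, so migration-month daily values include flight costs. Ambient wind
(6 m s⁻¹) and cloud (0.6) are configuration constants because the synthetic
world carries no wind or cloud fields. Totals are `Σ daily × days / 1000`
MJ; ensemble statistics are means and sample standard deviations over
feasible climate members, with infeasible members recorded by name.

## Problem sizes and numerical choices

The demonstration configuration uses a 20 × 40 cell grid (2.5° × 9°), two
climate members, 150 presences, 2 envelope pseudo-absence sets × 300 × 2
runs × 4 learners, and completes in a few seconds; the recovery experiment
uses 20 seeds × (3 sets × 2 runs × 4 learners) on 300 presences. These sizes
were chosen so the full validation suite runs comfortably on a laptop while
leaving every statistical conclusion (recovery medians, strategy ranking)
stable across seeds. Ties in nearest-cell lookup resolve to the lower
(lat, lon) index; the land-run bucket rounding is conservative (upward); the
Boyce index drops windows with zero background frequency; degenerate inputs
(constant predictor columns, one-class labels, empty masks) raise explicit
errors except where the specification of the analysis makes emptiness
meaningful (the residency area).

## Known limitations

The cylinder-with-shell geometry omits appendages, posture and wind-driven
plumage compression; the energetics are steady-state with no fasting or
body-reserve dynamics; route costs ignore wind assistance and stop-over
quality (polynyas are not modelled); the species screen cannot discover
polar-night competence, only propagate it; and all quantitative claims about
recovery hold on the synthetic generator's terms, which are deliberately
simpler than observational data.
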