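---
title: "Patient-flow regionalization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-flow regionalization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionflow)
```

## The problem

Administrative health regions are drawn top-down; patients move bottom-up.
When a region's municipalities cannot resolve an event as common as
childbirth, residents cross municipal borders toward better-equipped
hospitals, and the set of municipalities that *actually* exchange patients —
the functional region — can differ sharply from the designated one.
`regionflow` quantifies that mismatch from admission-level data: who goes
where, which places are self-sufficient, which are service exporters, and
how far people travel to reach the dominant hub.

The unit of analysis is the municipality. The inputs are a table of
admission records (residence unit, hospital unit, diagnosis group, year)
and a unit attribute table (centroid, population, beds, designated-region
and micro-region membership). All statistics are census-style quantities
computed on the full record set; no sampling uncertainty is attached.

## The origin–destination matrix

`build_od_matrix()` counts, for every ordered pair (i, j), the patients
residing in i hospitalized in j. Conventions:

* The matrix is square over **all** units in the unit table; inactive
  units appear as zero rows/columns rather than disappearing, so set
  operations (sufficiency of arbitrary aggregates) stay well defined.
* The grand total always equals the number of contributing records; every
  filtering step logs what it dropped, so
  `records = matrix total + dropped` is an exact invariant checked in the
  tests and at every pipeline stage boundary.
* `apply_origin_filter()` implements the usual significance screen:
  origins sending **more than** `min_sent` patients (strict; the default 5
  means "at least 6") into the study hospital set are kept, the rest have
  their rows zeroed. The threshold is applied at the *origin* level — the
  origin's total flow into the hospital set — because the screen is about
  whether a municipality participates in the system at all, not about any
  single link; a per-edge variant is available (`per_edge = TRUE`) for
  sensitivity analysis. Members of the hospital set are always retained:
  dropping a hospital municipality for sending few patients elsewhere
  would delete its columns' context.
* `cross_border_summary()` defines cross-border at the municipal level
  (i ≠ j) over the rows of a resident scope, reporting the proportion at
  one decimal of a percent, the field's reporting convention.

## Sufficiency: LIFO and LOFI

The Elzinga–Hogarty coefficients, adapted to hospital markets, measure the
two directions of dependence for a subject S (a unit or an aggregated set):

* **LIFO** ("little in from outside") = (1 − inflow / H) × 100, with H the
  hospitalizations occurring inside S and inflow the part contributed by
  outside residents. Low LIFO = the subject's hospitals are critically
  relied on by outsiders (a service exporter).
* **LOFI** ("little out from inside") = (1 − outflow / R) × 100, with R
  the hospitalizations of S's residents and outflow the part occurring
  outside. Low LOFI = residents leak out for care.

S is **Sufficient** only when both strictly exceed the threshold
(default 75%). Design conventions, each of which matters in edge cases:

* **Aggregate before the ratio.** A set's coefficients come from its
  pooled flows, never from averaging member coefficients; internal flows
  between members count as neither inflow nor outflow. This is what makes
  the closed-system identity exact: for the set of all units,
  LIFO = LOFI = 100 identically.
* **Unrounded, strict comparison.** Reports print integer-rounded
  percentages, but classification always uses full precision with a strict
  `>`. A unit printing "75%" may therefore legitimately be Sufficient
  (75.4 > 75) or Insufficient (75.0 is not > 75).
* **0/0 is Undefined, not 100.** A unit with no hospital activity has no
  LIFO; a unit with no resident cases has no LOFI. An undefined
  coefficient blocks the Sufficient label — absence of activity is not
  evidence of autonomy.
* Self-flows (i = j) sit in every denominator; they are excluded only from
  the network's edge set (below).

`sufficiency_table()` assembles the three-level hierarchy: one row per
municipality with hospitalization (positive column sum — a unit with beds
but no admissions is excluded, since its coefficients would be undefined),
one aggregate row per micro-region, one per designated region.

### Successive enlargement

`frech_enlarge()` delimits a self-sufficient area constructively: evaluate
the seed set; while Insufficient, add the outside unit with the largest
total exchanged flow (sent into + received from the current set) and
re-evaluate. The exchange ranking was chosen because sufficiency is a
two-sided criterion — a unit can break it from either direction — so both
directions of linkage should count when choosing the next candidate;
in-flow-only and nearest-centroid rankings are exposed as options. Ties
break lexicographically by unit id, making traces fully deterministic. The
procedure stops when the set is Sufficient, when no outside unit exchanges
any patients (the set is then returned with its Insufficient label — a
disconnected remainder cannot help), or when all units are absorbed;
termination in at most `n_units` steps is guaranteed and tested. The seed
is caller-supplied: the pipeline seeds one run per micro-region and one
with the full designated region.

## The flow network

`build_flow_graph()` represents each ordered pair with cross-border flow
as one directed edge weighted by the patient count. Self-flows are not
self-loops — the network is about displacement — but are retained as the
`self_flow` node attribute, so the conservation identity
`edge weights + self-flows = total records` holds exactly. Hubs are ranked
by in-strength (patients attracted), the natural centrality for a
"who serves whom" question; no betweenness or community detection is
offered because flows to hospitals are single-hop, not transitive.
Components are weak (direction-ignored): the question "does this cluster
connect to the rest at all once the hub is removed?" concerns
connectivity, not reachability.

`origin_entropy()` summarizes each origin's destination dispersal,
H<sub>i</sub> = −Σ<sub>j</sub> p<sub>j</sub> ln p<sub>j</sub> over the
origin's destination shares. Published variants of this index differ in
base, normalization and the treatment of home treatment; here natural log
is used, normalization by ln(number of destinations used) is the default
(with H = 0 for a single destination), and self-flows count as a
destination by default. All three choices are arguments, and absolute
values should only be compared within one configuration.

## Geography

Distances are haversine great-circle lengths between municipal centroids
on a sphere of radius 6371.0088 km (configurable). Centroids already
approximate true origins at the tens-of-km scale of interest, so an
ellipsoidal geodesic would add sub-km precision to a quantity with km-level
input error; it is not worth a heavier dependency.

`displacement_stats()` reports the patient-weighted mean displacement of
cross-border flows into the hub versus all other cross-border flows —
the contrast that exposes a preference for the central place beyond what
distance decay alone explains. `catchment_quartiles()` grades a
destination's origins by migration intensity into quartiles computed *per
destination* (each hospital town's catchment is its own map; a global
quartile scale would let one giant hub flatten every other catchment's
gradation), with linear-interpolation percentiles and ties assigned
downward so a degenerate all-equal catchment is uniformly Q1.

## The synthetic generator

Real admission databases are confidential, so the package ships a
generator whose output has the statistical structure the analysis assumes,
making every pipeline stage testable end to end. `synthetic_scenario()`
defaults describe a hub-dominated region (`scenario_preset("drs13-like")`):

| parameter | default | meaning |
|---|---|---|
| `n_units` / `n_designated` | 60 / 26 | universe vs designated region (units nearest the hub) |
| `n_micro_regions` | 3 | angular sectors around the hub |
| `hub_bed_share` | 0.75 | hub share of total beds |
| `hub_pop_share` | 0.52 | hub share of designated-region population |
| `population_range` | 2,000–120,000 | log-uniform municipal populations |
| `beds_per_1000` | 2.46 | total bed supply per 1000 inhabitants |
| `bed_unit_fraction` | 0.5 | share of non-hub units operating hospitals |
| `birth_rate` | 0.015 | births per inhabitant-year |
| `episodes_per_birth` | 1.1 | admissions per birth (puerperium adds episodes) |
| `attraction_exponent` γ | 1 | bed-count exponent |
| `decay_scale_km` δ | 15 | e-folding distance of the exponential decay |
| `local_preference` λ | 30 | multiplier on the home municipality |
| `hub_preference` η | 4 | multiplier on the hub |

Destination choice is gravity-like:
u<sub>ij</sub> = beds<sub>j</sub><sup>γ</sup> · e<sup>−d<sub>ij</sub>/δ</sup> ·
λ<sup>[j=i]</sup> · η<sup>[j=hub]</sup>, row-normalized. Exponential decay
was chosen over a power law because it has no singularity at d = 0 (the
self-flow case) and one interpretable length scale. Case volumes are
`round(population × birth_rate × episodes_per_birth)` per origin —
deterministic, so record counts are exactly predictable — and destinations
are multinomial draws from the gravity row. Each origin draws from an RNG
sub-stream derived from the scenario seed and its own unit id, so adding
or removing units never perturbs other origins' records.

Geometry: centroids are uniform in a ~167 × 166 km bounding box sized like
a mid-size state health region, except the hub, which is pinned to the box
centre (the configuration being emulated is a centrally located referral
city; a corner hub would make "nearest the hub" a one-sided half-disc).
Hospitals are assigned to a population-weighted random half of the
non-hub units — larger towns are likelier to have one — which leaves many
small municipalities bedless, as in reality.

The preference parameters are calibration knobs, not estimates: no
published coefficients exist for them. They were set once so that the
default scenario reproduces the qualitative regime of a hub-dominated
maternity-care system — roughly a quarter of designated-region admissions
cross-border, a designated region that is Sufficient while none of its
micro-regions is autonomous, and hub-bound displacements substantially
longer (typically 1.2–2.4×, ≈49 vs ≈29 km on average across seeds) than
other cross-border trips. With weaker decay (δ ≈ 30 km) the long tail of
inter-town flows erodes the displacement contrast; δ = 15 km with η = 4
restores it while λ = 30 keeps hospital towns retaining about two thirds
of their residents.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: road networks and travel times (distances are
straight-line), non-contiguous catchments created by highway corridors,
incomplete hospital reporting and residence misregistration, temporal
dynamics within the year, severity stratification, and out-of-universe
leakage (residents hospitalized beyond the 60 simulated units simply do
not exist here, whereas real regional databases are censored at their own
boundary).

## Numerical conventions and degenerate inputs

* Strict inequalities throughout (`> min_sent`, `> threshold`); equality
  always falls on the excluded side, matching the "more than" phrasing of
  the conventions being implemented.
* Undefined ratios (0/0) propagate as `NA` plus an explicit flag or an
  `Undefined` label; they are never silently treated as 0 or 100.
* All orderings that feed decisions (enlargement candidates, hub ranking)
  break ties lexicographically by unit id, so every result is reproducible
  to the byte; the pipeline re-run test asserts exactly that.
* Empty subjects, empty scopes, unknown unit ids and destinations without
  in-flow raise errors naming the offender rather than returning empty
  results.

## Problem sizes

The test suite works at three scales, chosen to keep the full run within a
few seconds while still exercising the asymptotics that matter: the
three-unit closed system with hand-computable coefficients; batches of
100+ random small datasets (≤ 10 units, ≤ 500 records) compared against
independent record-iteration oracles; and twenty seeds of the 60-unit
default scenario (~40,000 records each) for the structure-recovery
properties (hub identification, region-sufficient/micro-insufficient
pattern, functional-region growth, displacement contrast).

## Limitations

Coefficients are census quantities with no uncertainty attached, so
near-threshold labels are sensitive to single-record changes in small
municipalities. The origin-level ">5" screen and the 75% threshold are
field conventions, not estimated quantities; both are configurable and
results near either boundary deserve a sensitivity pass. The entropy
index's normalization varies across the literature, so only within-run
comparisons are meaningful. And the generator, however structurally
faithful, is a model of a model: it validates the machinery, not any
particular real-world region.
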