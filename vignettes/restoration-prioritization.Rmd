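---
title: "Methods: multi-objective restoration prioritization with forestNCP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-objective restoration prioritization with forestNCP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestNCP)
```

## The planning problem

`forestNCP` formalizes forest-restoration planning as systematic
conservation planning over a grid of planning units. Each unit $i$ has a
restorable area $c_i$ (ha), which doubles as its cost. Benefits are
Nature's Contributions to People (NCP), encoded as features $j$ with
per-unit contributions $r_{ij}$ and targets $t_j$:

* climate NCP: carbon accumulated over 30 years of natural regrowth
  ($r_i$ in tC), target = the landscape total (the maximum attainable);
* biodiversity value NCP: one feature per species, $r_{ij}$ = the km² of
  suitable habitat unit $i$ would add, $t_j$ = the species' habitat
  restoration target;
* societal NCP: people reliant on forests for livelihoods, energy and
  housing material ($r_i$ in persons), target = the landscape total.

Given a plan's weights $w_j$ and a budget $B$, the solver minimizes the
weighted proportional shortfall
$\sum_j w_j\, y_j / t_j$ subject to
$\sum_i x_i r_{ij} + y_j \ge t_j$, $\sum_i x_i c_i \le B$,
$x_i \in [0,1]$, $y_j \ge 0$. The proportional (continuous) decision
variable makes the core problem a linear program; a binary decision mode
($x_i \in \{0,1\}$, a MILP) is retained for whole-cell plans and for
enumeration-based verification. Normalizing each shortfall by its target
puts features measured in tC, km² and persons on one scale, so a plan
cannot buy progress on a large-unit feature with collapse on a small one.

Minimizing proportional shortfall is equivalent to maximizing the
(capped) delivery of each weighted NCP, so for a single-NCP plan the
optimum simply maximizes that NCP's delivery under the budget — which is
why single-objective plans dominate all others on their own NCP at every
budget, a property the test suite asserts rather than assumes.

## Plan schemes and the weighting decision

Four plans are supported: carbon-centric, biodiversity-centric,
people-centric (each weighting only its own NCP) and integrated
(weighting all NCP). "Equal weighting" is ambiguous when one NCP group
(biodiversity) comprises $N$ species features while the others have one
feature each. The package's default, `weight_mode = "group-equal"`,
assigns each NCP *group* a total weight of 1 — species features get $1/N$
each — so the integrated objective cannot be dominated by feature count.
The alternative reading, `weight_mode = "feature-equal"` (every feature
weight 1), is provided because the choice is genuinely open; the mode is
recorded in sweep results and output manifests. Features with $t_j = 0$
are excluded from the objective (their proportional shortfall is
undefined) but their delivery is still reported.

## Habitat target setting

Species targets follow an area-based protocol inspired by IUCN Red List
reasoning. Potential AOH is the habitat (range ∩ suitable habitat class ∩
elevational window) a species would have if all restorable area were
restored; current AOH is the part of potential AOH outside the
restorable mask. Species with potential and current AOH both under
2,200 km² take their full potential AOH as the preliminary target;
otherwise the preliminary target is
$\min(\max(2200,\ 0.8 \times \text{potential AOH}),\ 10^6)$ km².
Deducting current AOH (floored at 0) gives the restoration target. Two
boundary interpretations are deliberate:

* because current AOH ≤ potential AOH by construction, the case
  "potential < 2,200 and current > 2,200" cannot occur, so the branch
  condition reduces to both-below-the-floor versus the formula;
* the deduction is clamped at zero — a negative habitat area is
  meaningless;
* any strictly positive target keeps a species in the optimization
  subset by default (`min_additional = 0`): real analyses of this kind
  retain targets as small as fractions of a hectare, and no numeric
  cutoff for "significant additional habitat" is established, so the
  threshold is exposed as configuration rather than hard-coded.

A unit's habitat contribution is scaled by its restorable area (a cell
that is half restorable contributes half its area as restorable habitat).
This is an interpretation: partial overlap of habitat and restorable land
within a cell is not resolvable at grid scale.

## The synthetic landscape generator

The generator is first-class, tested code; its defaults are the study
conditions, not tuning knobs. It emulates the statistical structure the
analysis assumes at national scale:

* **Grid**: 50 × 50 cells of 10 km (2,500 units), each with a Beta(2, 4)
  restorable fraction of the 10,000 ha cell (mean one third, mimicking a
  sparse restoration mask within a larger study area).
* **Spatial autocorrelation**: continuous fields are white noise smoothed
  with a separable Gaussian kernel (length scale in cell units),
  standardized, then mapped through a marginal transform. This is the
  simplest controllable stand-in for clustered real layers (e.g. carbon
  hotspots along mountain ranges); length scale 0 gives independent
  fields, which the tests verify with a neighbor-correlation diagnostic.
* **Carbon rates**: lognormal marginal (median 3 tC/ha/yr, sdlog 0.5),
  in the range reported for natural tropical forest regrowth. Exactly
  `round(0.046 x n_units)` units are missing carbon data — the 4.6%
  no-data share of the motivating national layers — placed as contiguous
  clusters (lowest values of an independent smoothed field), since real
  data gaps are regional, not salt-and-pepper. Missing is an explicit
  `NA` sentinel, distinct from zero: such units still deliver the other
  NCP and stay in every problem.
* **People counts**: three lognormal fields with per-unit means
  112 / 632 / 192 persons (livelihoods / energy / housing), chosen so
  default landscape totals match the order of magnitude of the national
  totals that motivated the design (0.28 M / 1.58 M / 0.48 M people over
  ~2,500 cells); 0.15% of units are missing people data. The rural
  fraction is Beta(6.5, 3.5) (mean 0.65, a largely rural population);
  reliance weights default to 1 (rural) and 0.2 (urban), exposed as free
  parameters because no standard spatial definition of urban reliance
  exists.
* **Species**: contiguous range blobs (random frontier growth, rook
  adjacency) covering 3–15% of the grid, habitat preferences of 1–3
  classes and an elevational window. By default every species is
  constructed "viable" — its preferences are anchored on a restorable
  in-range cell — so the default landscape yields 56 species features
  with positive targets plus climate and societal: the 58-feature,
  400-problem experimental design. Lower `species_viable_share` produces
  species with empty habitat for stress testing.
* **Subjurisdictions**: a nearest-centroid tessellation (each unit
  belongs to exactly one), with populations aggregated from a smoothed
  per-unit field. Disadvantaged and women fractions are drawn from Beta
  distributions and then calibrated — an additive shift, clipped to
  [0, 1], with an exact re-balancing step on the unclipped set — so the
  population-weighted national means equal 34.2% and 48.9% to machine
  precision. Calibration is idempotent and is re-exposed as
  `calibrate_subjurisdictions()` for custom targets.

What the generator does *not* emulate: real geography (no coastlines,
biome boundaries or actual species ranges), covariance between carbon
and habitat quality beyond what shared smoothness induces, and — by
default — any correlation between forest reliance and disadvantage.
Passing tests therefore demonstrate the correctness and qualitative
behavior of the method (dominance, monotone accumulation, cessation,
equity identities), not the magnitude of any real-world tradeoff:
national headline numbers depend on the real layers, which are out of
scope here.

## Numerical choices

* **Solver**: HiGHS through `scipy.optimize.linprog` in a batched Python
  subprocess; one subprocess solves a whole plan sweep. HiGHS is
  deterministic for a fixed input, and residual degeneracy (alternative
  optima) is resolved by the fixed input ordering of units. The
  package's own accounting recomputes shortfalls as
  $y_j = \max(0, t_j - \sum_i x_i r_{ij})$ for every feature — including
  unweighted ones, whose $y_j$ is unconstrained slack in the LP — and
  cross-checks the recomputed objective against the solver's at 1e-6.
* **Verification**: binary instances with ≤ 12 units are checked against
  exhaustive subset enumeration; proportional single-feature instances
  against the fractional-knapsack greedy, which is exactly optimal. Both
  oracles are implemented independently in R, so the LP path and its
  check share no code.
* **Tolerances**: feasibility and target-met tests at 1e-6 relative;
  cessation declared when the weighted objective drops below 1e-6
  (absolute, on an objective of order 1); calibration to 1e-9 (achieved
  at machine precision).
* **Degenerate inputs**: an all-zero NCP layer flags its feature
  degenerate and its accumulation curve is reported `NA`, not 0/0; a
  target exceeding deliverable habitat is kept (the shortfall absorbs
  it) with a warning; budget 0 and full budget reduce to closed forms
  the tests pin down.
* **Budgets** are measured in restorable area (ha), with level $b$%
  meaning $B = b/100 \times \sum_i c_i$; the top level is set exactly to
  the total to avoid round-off infeasibility.
* **Selection frequency** is emitted in both conventions — thresholded
  ($x_i \ge 0.5$) counts and fractional sums — because no standard
  definition of "included" exists for fractional decisions.
* **Cessation** does not truncate a sweep: solves past the cessation
  budget are cheap and keep the curves complete; the budget is flagged
  instead.

## Problem sizes used in the tests

Unit and property tests run on 5×5 to 12×12 grids (25–144 units, 2–8
species), where enumeration oracles are exact and a full sweep takes
seconds. The end-to-end experimental-design check runs the full default
configuration — 2,500 units, 58 features, 400 LPs — which completes in
well under a minute; these sizes were chosen so the complete suite
exercises every scale the package documents while remaining quick enough
to run routinely.

## Known limitations

* No boundary-length or compactness penalties, locked-in/out
  constraints, or non-area costs: none are part of the design being
  reproduced.
* Equity accounting treats disadvantaged and women fractions as
  independent marginals (no joint distribution is available) and
  apportions beneficiaries proportionally to $x_i$; counting whole cells
  instead would change the numbers for strongly fractional solutions.
* Nestedness of priorities across budgets is a narrative property, not a
  guarantee of independent LP solves; the package measures it (Jaccard
  similarity between consecutive selections) but does not assert it.
* The 30-year carbon accrual is linear in the annual rate; no
  saturation curve is modeled.
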