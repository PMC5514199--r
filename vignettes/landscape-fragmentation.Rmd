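---
title: "Class-level fragmentation metrics, deforestation incidence, and trend tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-level fragmentation metrics, deforestation incidence, and trend tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landfrag)
```

## The problem

Multi-decadal land-cover mapping of tropical forest landscapes typically
produces, per site and (roughly) per year, a categorical raster with three
substantive classes — mature forest (MF), non-forest (NF), and secondary
forest (SF) — plus a nodata code. Two questions recur:

1. How is the *spatial pattern* of each class changing — is forest getting
   more fragmented, is cleared land coalescing, are disturbance scars more
   irregular?
2. Are legally protected areas (conservation units, CUs) actually receiving
   less deforestation than their surroundings, and is that protection
   eroding over time?

`landfrag` answers both with a small, deliberately parsimonious toolkit:
four class-level fragmentation metrics, a deforestation-incidence ratio,
and autocorrelation-aware linear trend tests, all stratified by analysis
zones (inside vs. outside CUs, or per CU category). A seeded synthetic
landscape generator supplies test data with known structure, since real
classified scene stacks are large and rarely redistributable.

## Data model and conventions

A `land_raster` is an integer matrix plus cell size (metres), year, class
codes (default MF = 1, NF = 2, SF = 3) and a nodata code. Zones are boolean
masks; `apply_zone()` turns everything outside the zone into nodata, so each
zone is analysed as its own landscape and patches are clipped at the zone
boundary (masking and patch delineation commute, which the tests assert).

Two neighbourhood rules coexist by convention, and both are exposed:

* **Patches** are maximal sets of equal-class cells connected under the
  *queen* (8-neighbour) rule.
* **Adjacency** for the clumpiness index uses *rook* (4-neighbour) cell
  sides with the double-count convention: each ordered (cell, neighbour)
  pair is one tally, so a shared side between like cells adds 2 to
  `g[i, i]`.

The grid boundary and nodata cells are "outside the landscape": they count
toward patch *perimeter*, but are excluded from adjacency tallies and — by
default — from edge density. Whether a landscape border should contribute
edge is genuinely ambiguous in practice (it depends on what lies beyond the
mapped extent), so the no-border convention is the default and
`boundary_edge = TRUE` flips it; the pipeline log records which was used.

## The four class-level metrics

For a class *i* within a zone of area *A* (ha), with patches *j* of area
*a_j* (ha) and perimeter *p_j* (m):

* **Edge density** `ED = (Σ edge length in m) / A`, where an edge segment
  is a cell side between class *i* and a *different substantive class*.
  Each unlike side counts once toward each of its two classes. A class that
  is absent has ED 0.
* **Clumpiness** compares the like-adjacency proportion
  `G = g_ii / (Σ_k g_ik − min_e)` with the areal proportion `P_i`
  (share of non-nodata cells), where `min_e` is the minimum perimeter (in
  sides) of a maximally compact patch holding the whole class area; if the
  subtraction would make the denominator non-positive (tiny classes), `G`
  falls back to `g_ii / Σ_k g_ik`. Then
  `CLUMPY = (G − P)/P` if `G < P` and `P < 0.5`, else `(G − P)/(1 − P)`,
  clamped to [−1, 1]. A checkerboard gives −1, random placement ≈ 0, a
  single compact block 1. It is undefined (`NA`) when the class is absent
  or fills the zone.
* **AREA_AM** `= Σ a_j² / Σ a_j`, the area-weighted mean patch size: the
  expected patch size experienced by a randomly chosen cell of the class.
  It always lies between the smallest and largest patch.
* **SHAPE_AM** is the area-weighted mean of the per-patch shape index
  `p_j / min_p(z_j)`, where `min_p(z)` is the minimum perimeter of any
  raster patch (polyomino) of `z` cells: with `n = floor(√z)`, `min_p` is
  `4n` for a perfect square, `4n + 2` if `z ≤ n(n+1)`, else `4n + 4`. The
  index is 1 for squares and grows with boundary irregularity. The closed
  form is validated in the tests against exhaustive polyomino enumeration
  up to 8 cells.

Undefined values propagate as `NA`, never as zeros; downstream trend fits
simply skip missing years (real mapping records have gaps anyway).

All four metrics are checked against independent brute-force
implementations (flood-fill labelling, per-cell side counting) on every
two-class 4×4 grid (65,536 of them) and on 1,000 random three-class 10×10
grids, at 10⁻⁹ relative tolerance.

## Relative incidence of deforestation

Deforestation between two consecutive maps is the area of MF cells that
became NF. For zones *i* that partition the landscape,

```
RID_i = (D_i / D_total) / (A_i / A_total)
```

normalises each zone's share of deforested area by its share of landscape
area: 1 means proportional incidence, below 1 under-incidence (effective
protection), above 1 disproportionate pressure. The area-weighted mean of
RID across zones is identically 1 whenever it is defined, which the test
suite asserts on every computed interval. When an interval has no
deforestation at all, RID is undefined (`NA`) rather than forced to a
number; a zone with none while others have some gets exactly 0.

Two conventions are configurable because mapping practice varies:

* `annualize` divides deforested area by the interval length; RID itself is
  unchanged (a common factor cancels), so the default reports raw
  per-interval areas.
* Direct MF→SF transitions violate the succession rule that secondary
  forest must pass through a non-forest state; they are surfaced in a
  separate QC column and excluded from `D` by default. SF→NF re-clearing is
  likewise excluded unless `include_sf_clearing = TRUE`, since the statistic
  targets loss of *mature* forest.

## Trend testing with autocorrelated errors

Each metric series (per zone × class × metric, plus RID per zone) is
regressed on calendar year. Because consecutive maps share disturbance
history, residuals are autocorrelated, and the record is irregular (1–4
year gaps), the fit proceeds in two stages:

1. **Order selection** (`select_error_structure`): OLS residuals are placed
   on an annual lattice with missing years as `NA` — preserving true lag
   distances rather than squeezing gaps — and ARMA(p, q) models with
   p, q ≤ 2 are fitted by maximum likelihood (state-space, so missing
   values are handled exactly). The order minimising AICc wins; ties go to
   the smaller p + q, then the smaller p. Series shorter than 8
   observations default to (0, 0).
2. **GLS fit** (`fit_trend`): generalized least squares of value on year
   with the selected ARMA correlation on the integer-year lattice. With
   order (0, 0) this reduces exactly to OLS (asserted in the tests).
   Estimation uses REML by default: in a Monte Carlo with n = 27 annual
   observations and AR(1) errors (φ = 0.6), the REML slope test holds its
   nominal 5% size to within the acceptance band, while ML is visibly
   anticonservative. Slope inference is a two-sided t test.

Numerical edge cases are handled explicitly: a perfectly flat series
returns slope 0 with p = 1 (rather than a 0/0 t statistic); ARMA fits that
fail to converge either raise an error (default) or, with
`fallback_ols = TRUE` (used by `trend_table`), refit as OLS with
`converged = FALSE` and the reason recorded — never silently.

No multiple-testing correction is applied by default, matching
per-regression reporting conventions; `adjust = TRUE` applies
Benjamini–Hochberg across the table. The significance threshold for the
summary columns defaults to 0.05 and is echoed in the run log.

The two-stage procedure as a whole is anticonservative when the error
order is misselected (order selection at these sample sizes picks white
noise or an MA(1) a substantial minority of the time under strong AR(1)
noise), so borderline p-values in the trend table deserve caution; the
calibration that the tests certify is for the GLS stage at a given order.

## The synthetic landscape generator

`generate_series()` emulates the qualitative dynamics the analysis is
designed to detect, not any particular region's rates:

* clearing spreads *contagiously*: each year a fixed budget of MF cells
  flips to NF, sampled with probability mass `contagion` on cells adjacent
  to existing NF and `1 − contagion` on an exponential road-proximity
  kernel (Chebyshev distance to the nearest road cell, e-folding scale
  `road_decay`);
* `fishbone_roads()` builds the spine-plus-ribs geometry of planned
  settlement projects; road cells are NF from year one and never regrow;
* scheduled wildfires burn connected scars grown by biased accretion:
  `irregularity` 0 prefers frontier cells with many burnt neighbours
  (compact, near-disc scars), 1 prefers lonely frontier cells (dendritic
  scars), interpolating via an exponential weight on the burnt-neighbour
  count;
* cleared cells may regrow to SF only after a minimum fallow age
  (`fallow_min`, default 3 years) and then with annual probability
  `p_regrow`; SF re-clears with probability `p_reclear`. SF is therefore
  *always* preceded by NF — asserted pixel-by-pixel on every generated
  series, including internally simulated gap years;
* a CU mask multiplies clearing probability by `protection` (0 = absolute
  protection, a hard constraint, also asserted); wildfires deliberately
  ignore the mask, since fire does not respect administrative boundaries;
* gap years are simulated but omitted from the output, mimicking missing
  scenes. Preset gaps are at most two consecutive years while the minimum
  fallow is three, so the succession rule remains verifiable from the
  output series alone.

Defaults (80×80 cells of 30 m ≈ 576 ha, 1984–2011, budgets of 12–80
cells/year, protection 0.3) were chosen once to give end-state forest
fractions between roughly 20% and 85% across the three presets —
`isolated_low_pressure`, `spontaneous_with_fires`, `planned_settlement` —
spanning lightly to heavily transformed landscapes. Validation-suite
problem sizes (replicate counts, grid sizes, the 27-observation trend
Monte Carlo) are stated in the tests themselves and were sized to exercise
each property at meaningful power.

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: classification error and its temporal
autocorrelation, mixed pixels at 30 m, georeferencing jitter between
scenes, realistic deforestation rates or agent behaviour, cloud/SLC
artefacts, and topographic constraints on clearing. The generator's job is
to produce series whose *constructed* directional effects (protection
depresses RID inside CUs; fires spike NF edge density and shape
irregularity; contagion raises NF clumpiness) must be recovered by the full
pipeline, which the acceptance suite checks over ≥ 20 seeded replicates
each.

## Design choices worth knowing about

* **File formats.** Raster I/O is ESRI ASCII grid (text, self-describing
  header); zone polygons are accepted as GeoJSON and rasterized by
  centre-point containment. Georeference is carried through untouched;
  there is no reprojection or resampling.
* **Determinism.** Every stochastic component draws from one seeded
  generator; the seed is stored in scenarios, echoed in the run log, and
  the pipeline is byte-identical under a fixed config.
* **Self-describing runs.** `run_pipeline()` writes a JSON log naming every
  defaulted convention actually exercised (connectivity, boundary-edge
  handling, RID annualization, SF handling, alpha, ARMA search bounds), so
  a run can be audited without reading code.
* **Missingness.** Absent classes and degenerate proportions yield `NA`
  metrics; all-missing series are skipped with a logged reason; nothing is
  imputed.

## Limitations

Landscape-level (as opposed to class-level) metrics, patch-level output
tables, vector-based metric variants, changepoint or nonlinear trends, and
spatial (as opposed to temporal) autocorrelation are out of scope. Metric
values published for specific real sites cannot be reproduced here without
the original classified maps; this package reproduces the *method*, and its
numerical claims are exactly those its tests and acceptance script compute.
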