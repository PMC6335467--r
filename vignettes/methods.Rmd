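---
title: "Methods: phylogenetic turnover in environmental space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic turnover in environmental space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind the package, the
decisions taken where the design was genuinely open, and what the synthetic
generator does and does not establish. It states no empirical result that the
test suite does not itself compute.

## The turnover model

For two assemblages evaluated on a rooted phylogeny with branch lengths, let
`a` be the branch length shared by their root-to-tip path unions and `b`, `c`
the branch lengths unique to each. The true-turnover (Simpson) component of
phylogenetic beta diversity is

$$\beta_{sim} = \frac{\min(b, c)}{a + \min(b, c)}.$$

It equals 0 for identical assemblages, 1 for assemblages sharing no branch,
and — unlike the Sørensen family — it does not respond to pure richness
differences (nestedness). On a star phylogeny with equal branch lengths it
reduces exactly to the species-count Simpson index, which the tests verify.

**PD is rooted.** `faith_pd()` includes the path from the community's MRCA up
to the tree root. The source procedure does not state which convention it
uses; rooting at the tree root is adopted because it is the common convention
for phylogenetic beta components on rooted trees and makes the partition
identity `a + b + c = PD(union)` exact, which in turn makes the
inclusion–exclusion route (`branch_partition()`) and the edge-classification
route (the test oracle) provably identical. Communities that contain the
same single lineage straight from the root would give `a = 0, min(b,c) = 0`;
this degenerate case returns 0 with a warning.

**Phylogenetic uncertainty.** β is computed per candidate tree and averaged
arithmetically over the tree set (default 20) *before* any regression — the
mean β is the quantity carried forward, not the mean of downstream residuals.

## Tree rescaling and truncation

`delta_transform()` raises node depths, normalized by tree height, to the
power δ, then (by default) restores the original height. δ is therefore
dimensionless; δ = 1 is an exact identity on the pairwise tip-distance
matrix; δ > 1 moves internal nodes rootward (stretching recent branches,
weighting recent divergences in β), δ < 1 does the opposite. The default δ
set for pipeline runs is {0.1, 0.3, 1, 3, 10}. Non-ultrametric trees are
accepted: depth-from-root is used as is.

`truncate_tree()` cuts all branches crossing a given depth from the root and
collapses each crossed branch's clade into one tip; for an ultrametric tree
in time units a cut at depth *d* is an age of height − *d* before present.
The tie-break at a node sitting exactly on the cut is half-open — the node's
*child* branches are cut — which is deterministic and side-independent. The
collapsed branch's geographic distribution is the union (logical OR,
`collapse_communities()`) of its descendant tips' occurrence columns.
Because candidate trees may disagree on topology, the pipeline collapses
occurrences per tree, not once.

## Environmental layers and sampling

The moisture axis is the mean June–August difference (mm) between monthly
precipitation and Turc potential evapotranspiration,
`PET = k · T/(T + 15) · (Rs + 50)` with `k = 0.40` (30/31-day months) or
`0.37` (February) and a floor of 0 at `T ≤ 0` °C. The source text does not
print its Turc constant set; these classic monthly coefficients are used and
exposed as arguments. Solar radiation is in cal cm⁻² day⁻¹, temperature in
°C.

`stratify()` cuts each layer into `k` equal-width classes spanning the
observed min–max over land (top class right-closed), crossed into stratum id
`class1 · k + class2`. Widths are data-driven, not theoretical variable
ranges. `allocate_samples()` implements log-proportional allocation: the
source states proportionality to log pixel count with endpoints 1 (rarest
stratum) and 10 (largest); the exact interpolation rule is not printed, so
the package linearly interpolates in `ln n_s` between the endpoints and
rounds, clipping to `[min_n, min(max_n, n_s)]` — this reproduces both printed
endpoints and is monotone. When all strata have equal size the rule
degenerates to `max_n`. Cells with no species present are ineligible.

## Land distance and residualization

Geographic distance is the least-cost path over the 8-connected grid, a step
costing `res_km · step_factor · (cost_u + cost_v)/2` with `step_factor =
√2` on diagonals; sea cells cost 10× land by default (sea is expensive, not
forbidden). The edge-cost convention and connectivity are not stated in the
source and are config-exposed; the average-of-endpoints rule is the standard
symmetric choice. Penalties 1 and 100 and a pure Euclidean mode support
robustness checks; distances are provably monotone in the penalty.

Raw β is mapped to the logit scale after the Smithson–Verkuilen squeeze
`(β(n−1) + 0.5)/n` (logit is undefined at 0/1; the squeeze is reversible and
n-dependent), then regressed by OLS on distance and distance². The residuals
are the distance-independent turnover fraction. The regression is fit over
*all* site pairs; neighboring-strata means are computed afterwards from the
fitted residuals. Residuals stay on the logit scale for aggregation and
mapping — whether the source averaged on the logit or response scale is
unstated, and logit-scale averaging keeps the OLS zero-sum and orthogonality
properties exact.

## Aggregation, interpolation

For every pair of strata adjacent in the k × k class grid (rook by default —
"neighboring equidistant strata" suggests minimal-step neighbors; queen
available) with sites on both sides, the mean residual over all
*cross-stratum* site pairs is placed at the midpoint of the two stratum
centers in (env1, env2) space. Within-stratum pairs are never aggregated.

`rasterize_env()` interpolates these scattered values onto a regular grid by
Delaunay triangulation (Bowyer–Watson, implemented in the package since no
installed library provides it) with barycentric weights: on a regular input
lattice this is bilinear interpolation up to the value-identical choice of
cell diagonal; it reproduces inputs exactly, never exceeds the input range,
and is left undefined outside the convex hull — the surface never invents
environmental domains that were not sampled.

## Macroecological drivers and importance

Per site: SR (community size), PD (rooted Faith, averaged over the candidate
trees), relPD (OLS residual of PD on SR + SR²; positive = more divergent
lineages than richness predicts) and NS (mean over present species of the
95% bivariate data-ellipse area of the species' occupied cells in env
space, `π √det(S) · χ²₀.₉₅(2)`, ≈ 5.9915 √det S π). Occupied land cells —
not sample sites — are the ellipse points: the source is ambiguous, and
occupied cells are the deterministic superset. Species with fewer than 3
points or collinear occurrences have undefined NS and are skipped in the
site mean (median available).

The importance regression takes one observation per neighboring stratum
pair: response = mean residual turnover; regressors = per-pair means of the
two strata's site means of SR, relPD, NS, standardized, plus their squares
(squares of standardized terms, re-standardized). The observational unit is
not stated in the source; the stratum pair is the finest unit consistent
with explaining the mapped pair-level surfaces. LMG importance is the
Shapley decomposition of R²: each column's sequential ΔR² averaged over all
orderings of entry, computed via the subset-aggregation identity (64 subset
fits for 6 columns) and checked in the tests against an explicit
all-orderings brute force. Linear and quadratic shares are summed per
variable and rescaled to sum to 1.

## The synthetic world

The generator emulates the *structure* of the real inputs: a 40 × 40 grid at
15 km resolution with ~10% clumped sea (smooth-field threshold), a
temperature-like gradient (0–25) along columns and a moisture-like gradient
(−50–100 mm) along rows with a 0.3 admixture correlation, a unit-height Yule
tree (pure birth — guaranteed tip count; extinction left as future work), a
set of branch-length–jittered tree copies standing in for the posterior
tree set, Brownian niche centers (rate 0.04 per axis in normalized units:
moderate niche conservatism) and axis-aligned Gaussian suitability with
breadth 0.2 of each gradient's range, thresholded at 0.5 — ranges spanning a
few strata, as a scientist would expect of mid-sized temperate ranges. These
defaults were fixed once, before any acceptance outcome was observed.

Planted scenarios override the env1 centers: `basal_barrier` places the two
basal clades at 0.25/0.75 of the env1 range with narrow (0.12 of range)
breadths, so cross-midline site pairs separate the deepest split and the
residual-turnover surface should peak in the middle third of env1;
`recent_barrier` splits *cherries* (sister species) across the midline, so
the signal is carried by terminal branches and should strengthen under
δ = 10 relative to δ = 0.1. The acceptance tests verify exactly these
qualitative recoveries at reduced scale (28 × 28 grid, 36 species, 4 trees —
scaled down to stay within test-time budgets; the checked property does not
depend on scale).

What a green suite does **not** establish: realistic European geography or
glacial-refugia history, range shapes beyond axis-aligned Gaussians,
non-climatic range limits, richness gradients arising from diversification
rather than niche geometry, or any of the source study's clade-specific
numbers (correlations, R², importance shares), which require its real range
maps and phylogenies.

## Numerical choices and limitations

* Equality at class boundaries: top stratification class is right-closed;
  the truncation cut is half-open at nodes.
* The Bowyer–Watson in-circle test uses a relative 1e-12 tolerance;
  cocircular lattices get an arbitrary but valid diagonal, which cannot
  change interpolated values of planar fields.
* `round()` (R's banker's rounding) is used in the allocation rule; ties at
  .5 are vanishingly rare for log-interpolated targets.
* Distances use igraph Dijkstra on the full grid graph; continental-scale
  grids (≫ 10⁵ cells) would need graph simplification, which is out of
  scope.
* NS underestimates niches of species ranging beyond the study area;
  no correction is attempted.
* Seeds: every stochastic step (landscape, tree, niches, jittered trees,
  site draws) derives from a single master seed; identical config + seed
  gives byte-identical CSV artifacts.
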