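---
title: "Multi-extent niche modeling, resistant-kernel connectivity and gap analysis"
author: "connscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-extent niche modeling, resistant-kernel connectivity and gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connscape)
```

# Overview

`connscape` implements an end-to-end conservation-planning workflow for
presence-only wildlife data on raster landscapes: multi-scale habitat
suitability modeling, transformation of suitability into movement
resistance, resistant-kernel and factorial least-cost-path connectivity,
core-habitat delineation with landscape pattern metrics, graph-theoretic
patch prioritization, and protected-area gap analysis. Every stage is
exercised end-to-end on synthetic landscapes with known ground truth, so
the statistical behaviour of the whole chain is testable without external
geodata.

This vignette explains the models and procedures, the tunable parameters
and their defaults, what the synthetic generator does and does not
emulate, and the numerical and design choices that were genuinely open.

# The suitability model

Habitat suitability is estimated by a presence-background ensemble. The
single-model family is a ridge-penalized logistic regression contrasting
presence cells against a uniform background sample, over linear and
quadratic features of the (screened) predictor stack. This is the same
model family as maximum-entropy presence-background estimation restricted
to linear/quadratic feature classes; hinge and product features are out of
scope. Predictions are on the 0–1 logistic scale and are interpreted as
relative habitat suitability (HS).

The ensemble protocol follows the standard multi-replicate bootstrap
design: per replicate the presence set is resampled with replacement,
split 75/25 into calibration and evaluation points, a fresh background
sample is drawn, and the penalized fit is capped at a maximum number of
optimizer iterations. Defaults (`modelConfig()`):

| parameter        | default | meaning                                        |
|------------------|---------|------------------------------------------------|
| `nReplicates`    | 10      | bootstrap replicates                           |
| `nBackground`    | 10000   | background cells per replicate (uniform, with replacement, presences not excluded) |
| `trainFraction`  | 0.75    | share of each bootstrap resample used to train |
| `maxIterations`  | 500     | optimizer iteration cap                        |
| `regularization` | 0.01    | ridge penalty (glmnet lambda)                  |

Model performance is the Mann–Whitney AUC of held-out presence scores
against background scores. Variable importance is permutation importance
(mean AUC drop when one predictor is shuffled across evaluation points,
rescaled to sum to 100): the path-dependent "percent contribution" of the
original maximum-entropy software is not reproducible outside that
program, and permutation importance is the model-agnostic replacement.

Continuous suitability maps are binarized by either of two rules, both
resolved from data: the 10th percentile of suitability at training
presences (averaged over replicates, so ~90% of training presences are
classed suitable), or the mean suitability at all occurrence points.
Percentiles use the linear-interpolation convention (R's `type = 7`)
throughout the package; no alternative convention is exposed. A cell is
suitable when HS is greater than or equal to the threshold. Whether the
mean rule should use training presences only was an open choice; this
implementation uses all occurrence points and documents it here.

# Multi-extent analysis

Species–environment relationships are scale-dependent, so the whole model
is refitted at several focal extents: every predictor is replaced by its
mean within a circular moving window of radius 0.1, 0.5, 1, 2 and 4 km
(the default ladder), and one ensemble is fitted per extent. Window
membership is by cell-centre distance (centre within the radius); at the
landscape edge the window shrinks to the available cells, which avoids the
bias a padded window would introduce. Nodata cells are ignored inside
windows and stay nodata in the output.

The best extent is selected by the highest mean test AUC across
replicates, with ties resolved toward the larger extent, and that extent's
suitability map feeds the connectivity stage.

Predictors are screened for collinearity before fitting: while any pair
has |Pearson r| > 0.8, the member of the worst pair with the larger mean
absolute correlation to all other retained variables is dropped. The
threshold is the conventional 0.8; the drop rule is this package's
documented tie-break (the convention only states the cut). Zero-variance
layers cannot be screened and are flagged and retained with a warning.

Spatial autocorrelation of the occurrence data is screened with global
Moran's I. The statistic needs a unit and a weighting convention that the
underlying ArcGIS-style usage leaves unstated; this package bins points to
counts on an aggregation grid (default 10x the cell size) and uses
inverse-distance weights between aggregation-cell centres, with the
z-score computed under the normality assumption (E[I] = −1/(n−1)). This is
a documented stand-in convention, cross-checked in the tests against an
independent implementation (note that `ape::Moran.I` row-standardizes
weights and uses the randomization variance, so only I and E[I] are
directly comparable).

# From suitability to movement

Resistance is the negative-exponential transform `R_raw = 1000^(-HS)`,
linearly rescaled to [1, 10]. The rescaling maps the transform's analytic
codomain [0.001, 1] — not the empirical range of a particular map — so
R(HS = 1) = 1 and R(HS = 0) = 10 exactly and the transform is
map-independent. One *cost unit* is one resistance-weighted meter: moving
100 m across cells of resistance 1 costs 100 cost units, so a dispersal
threshold of 50000 cost units corresponds to a 50 km reach through optimal
habitat.

Accumulated cost is Dijkstra's shortest path on the 8-neighbour lattice,
with edge cost equal to the mean resistance of the two cells times the
centre-to-centre distance (cell size orthogonally, cell size times sqrt(2)
diagonally) — the standard cost-distance convention. Path ties are
resolved deterministically by the graph library; for fixed inputs the same
path is always returned.

The resistant kernel around each source point is a linear decay from 1 at
the source to 0 at the dispersal threshold D,
`K_s(x) = max(0, 1 - c_s(x)/D)`, summed over sources. Linear decay is the
corridor-simulator default; a Gaussian alternative is exposed via
`decay = "gaussian"` but is not used by the pipeline. The default
threshold ladder {50000, ..., 250000} cost units spans 50–250 km of
optimal-habitat reach, bracketing the dispersal uncertainty of a wide-
ranging carnivore.

The factorial least-cost-path surface computes one least-cost route per
unordered pair of source points (no dispersal threshold), buffers each
route by 200 m (two cells at the 100 m analysis resolution; the buffer
width is conventionally unstated, so it is configurable and logged), and
sums the buffered routes into a per-cell corridor-strength count.

# Core habitats, pattern metrics and prioritization

Core habitats are the 8-connected components of the region where the
kernel surface strictly exceeds its 70th percentile. The percentile is
taken over the positive-kernel support, not the whole landscape: the
kernel is exactly zero beyond every source's reach, and on a large
landscape those structural zeros would drag the percentile down until the
"cores" covered nearly the entire kernel footprint. Taking the percentile
over all cells remains available via `support = "all"`. Two degenerate
cases are explicit statuses rather than errors: a kernel with no positive
cells (`"empty"`) and a constant positive kernel, where the strict
inequality removes everything (`"degenerate"`).

Four pattern metrics summarize each binary habitat map: PLAND (percent of
landscape in habitat), NP (number of 8-connected patches), LPI (largest
patch as percent of landscape) and CL (correlation length: the
area-weighted mean radius of gyration, where each patch's radius of
gyration is the mean distance of its cell centres to the patch centroid).

Patch prioritization uses the probability-of-connectivity index
`PC = sum_ij a_i a_j p*_ij / AL^2` over ordered patch pairs (including
i = j with p* = 1), where `p*_ij` is the maximum-probability path under
the negative-exponential direct probability `p_ij = exp(-k d_ij)`.
Distances are edge-to-edge (minimum Euclidean distance between patch cell
centres). The decay constant is calibrated by `p(dMed) = pMed`
(default pMed = 0.5 at a median dispersal distance), following common
practice for this index; the calibration is configurable because no
universal value exists. Per-patch importance is
`dPC_k = 100 (PC - PC_without_k)/PC`, decomposed into intra (the patch's
own area term), flux (its pairwise terms with all others) and connector
(the residual: the loss in other pairs' best paths when the patch is
removed). The residual form equals the direct definition by the
decomposition identity, which the tests verify to 1e-9 on random graphs.

Gap analysis overlays target habitat on the conservation-area network: the
covered percentage is the share of target cells whose centres fall inside
the polygons of a category (cell-centre point-in-polygon; no partial-cell
areas, so the overlay is bit-exact). For conservation-area prioritization
each area is treated as a patch whose attribute is the suitable-habitat
extent inside it; areas containing no suitable habitat are excluded with a
warning, because a zero attribute is not a valid node of the PC graph.

# The synthetic landscape generator

The generator emulates the statistical structure the analysis assumes:

- continuous predictors as spatially autocorrelated Gaussian random
  fields (white noise convolved with a Gaussian kernel on the torus,
  standardized to mean 0, sd 1). Convolution is the simple, controllable
  choice; spectral synthesis with a target variogram is not needed for
  testing the workflow;
- distance-to-feature predictors: roads as random cross-landscape
  polylines, settlements and dumpsites as random point features,
  croplands as random rectangles, each rasterized and passed through the
  exact Euclidean distance transform;
- occurrences sampled at cell centres, without replacement, with
  probability proportional to a known logistic "truth" over the stack
  variables. Cell-level sampling without replacement avoids duplicate
  coordinates that would distort Moran's I. Source-class labels follow
  the 55:88:45 den/scat/sighting mix of a typical multi-source carnivore
  dataset, and all classes are treated identically (how the original
  multi-source records should be weighted is unknown, so the generator
  does not invent a weighting);
- a conservation-area network of non-overlapping rectangles in a
  2 wildlife-refuge / 2 protected-area / 5 non-hunting-area category mix;
- per-prey suitability (logistic fields) and zonal density surfaces
  (abundance divided by zone area, constant within zones), combined as
  sum over species of suitability times density.

The default truth is `trueModel(c(var1 = 2.5, var2 = -2), intercept = -4)`.
The intercept matters: a baseline prevalence of a few percent reflects a
rare, wide-ranging species whose ~190 records sit in a small fraction of
the landscape. With an intercept of 0 half the landscape saturates at
p ≈ 1, presences spread uniformly over that half, and no model — including
the true one — can exceed AUC ≈ 0.75; with the low-prevalence truth the
recovery band (ensemble test AUC > 0.8) is met with margin.

All randomness flows from a single integer seed through scoped generators
(the caller's RNG state is never touched), and per-stage child seeds are
derived from the master seed and the stage label, so every output is
bit-reproducible and stages are insensitive to reordering.

What the generator does *not* emulate: real terrain (elevation, slope,
roughness), vegetation indices, anisotropic or long-range autocorrelation
structures, observation bias (e.g. roadside sampling), and positional
error in occurrence records. Passing tests therefore demonstrate that the
pipeline's statistical machinery behaves as specified under its own
assumptions — not that any particular field system satisfies those
assumptions.

# Numerical choices and degenerate inputs

- Focal means use zero-padded FFT convolution of the masked values and
  the mask, then divide; this is exact up to ~1e-12 and fast at any
  radius. Edge and nodata handling fall out of the mask division.
- The distance transform is an exact Euclidean distance map (verified
  against brute-force nearest-feature search in the tests).
- Percentiles are always linear-interpolation order statistics
  (`type = 7`).
- Thresholding is inclusive (≥); core delineation is strict (>) to match
  the "greater than the percentile" definition.
- Moran's I on constant counts, empty patch sets, empty conservation
  networks and all-zero kernels return explicit statuses instead of
  errors; sub-cell focal radii warn and return the input unchanged.
- Cost distances beyond `maxCost`, and unreachable cells, are `Inf`; a
  source on nodata is an error.
- In the PC graph, an infinite inter-patch distance means p = 0 and
  contributes no edge; a zero distance between distinct nodes is floored
  at an infinitesimal edge weight so the path search remains valid.

# Scaled-down study sizes

The package defaults mirror the full study protocol (100 m cells,
extents to 4 km, thresholds to 250000 cost units, 10 replicates, 10000
background points). The test suite and the worked examples run the same
code on smaller problems chosen as desk-scale analogues: 96 x 96 to
40 x 40 cell landscapes, a 5–25 km dispersal ladder, and reduced
background samples where the statistical claim does not depend on the
background size. The monotone-trend properties (core area non-decreasing
in the dispersal threshold; NP trending down and LPI/CL trending up with
focal extent) are asserted as sign-of-trend tests per seed — the
qualitative pattern is the claim; individual steps of the ladder can
legitimately sawtooth on a finite landscape.

# Known limitations

- The presence-background model is linear/quadratic only; strongly
  non-monotone responses beyond a single optimum are not representable.
- Patch edge-to-edge distances are between cell centres, so two patches
  separated by one cell boundary are 1 cell size apart, not 0.
- The Moran's I convention (aggregation cell, inverse-distance weights,
  normality z-score) is a documented stand-in where the field usage is
  underspecified; compare absolute values across conventions with care.
- Corridor strength counts pairs, not path multiplicity: cost ties keep
  a single deterministic route per pair.
- The PC/dPC comparison of real landscapes additionally depends on the
  p(d) calibration; rankings are robust to joint rescaling of attributes
  and landscape area, but absolute dPC values are calibration-dependent.
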