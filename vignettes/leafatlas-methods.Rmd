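---
title: "From digitizer grids to a 2D leaf-shape atlas: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From digitizer grids to a 2D leaf-shape atlas: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafatlas)
```

leafatlas turns structured 3D-digitizer point grids of maize ear leaves into
flat, area-preserving 2D leaf models, a 29-feature morphometric phenotype, a
ranked leaf-shape atlas, and an inbred-line identifier. This vignette
explains the model behind each stage, the tunable parameters and why their
defaults are what they are, and the design decisions taken where more than
one reasonable construction existed.

## The acquisition grid and the raw mesh

A digitizer operator records five evenly spaced points per transect,
perpendicular to the midvein, moving from the leaf base to the tip, and
finishes with a single tip point. A leaf with `n` transects therefore holds
exactly `5n + 1` points; `read_digitized_leaf()` enforces this count and
refuses anything else. Typical maize ear leaves need 13-18 transects
(66-91 points). Column 3 of each transect samples the midvein; columns 1
and 5 are the left and right margins ("left" meaning first in acquisition
order).

The grid is triangulated deterministically: each quad between consecutive
transects is split along its lower-left to upper-right diagonal, and the
tip is joined to the last transect by a four-triangle fan, giving
`8(n-1) + 4` faces and disk topology by construction. The diagonal
orientation is a convention; one consequence worth knowing is that the
triangulation of a leaf and of its mirror image are not mirror images of
each other, so mirrored leaves reproduce each other's left/right features
to about a percent rather than to machine precision (the subdivision
relaxation and the mesh centroid feel the diagonal). Tests account for
this.

## Replicate screening

Within an inbred line, up to three replicate leaves are compared on four
cheap raw-mesh features: midvein length, maximum transect width, their
ratio, and the raw-mesh folding angle. The screening rule is a
one-vs-rest outlier test on a triplet: if one sample's distances to both
others exceed the remaining pair's mutual distance by more than 0.1, it is
dropped. The 0.1 threshold is unitless, so the four features are min-max
scaled to `[0, 1]` over the whole dataset before distances are taken --
without a common scale, a threshold mixing centimeters and radians would
be meaningless. Pairs and singletons are never screened.

## Normalization and subdivision

`normalize_mesh()` rotates the vertex cloud onto its principal axes
(largest variance along x), fixes signs so the tip points to +x and the
left-edge base vertex has positive y, completes a right-handed frame,
centers the centroid at the origin and scales uniformly into `[-1, 1]`.
The applied scale is kept as `scale_to_cm` so every downstream feature can
be reported in centimeters.

The coarse mesh is refined by sqrt(3) subdivision: insert a vertex at each
face centroid, flip every interior pre-iteration edge, and relax interior
pre-iteration vertices toward their neighbor average with the
degree-dependent damping `a_n = (4 - 2 cos(2*pi/n)) / 9`. Two iterations
(the default) multiply the face count by exactly 9. Boundary vertices are
held fixed and boundary edges are never flipped: fidelity of the leaf
contour matters more here than limit-surface smoothness at the margin.
Original vertex indices survive subdivision, which is what lets widths be
measured at the original transect stations after flattening.

## ARAP flattening

The flattening minimizes the as-rigid-as-possible energy

$$E(u, L) = \sum_t A_t \, \lVert J_t(u) - L_t \rVert_F^2,
\qquad L_t \in SO(2),$$

where `A_t` is the 3D area of triangle `t` and `J_t` the 2x2 Jacobian of
the planar map relative to an isometric 2D frame of the 3D triangle.
Minimization alternates two exact block steps: the local step projects
each `J_t` onto the rotations (closed-form 2x2 polar factor,
`theta = atan2(J21 - J12, J11 + J22)`), and the global step solves one
prefactored sparse least-squares system for `u` with all rotations fixed.
Because both steps are exact minimizers over their block, the energy is
monotonically non-increasing -- asserted on every run in the test suite.

Choices the energy itself does not dictate:

* **Initialization.** A least-squares conformal (LSCM) map with the
  midvein base and the tip pinned, falling back to projection onto the
  two principal axes if the conformal solve degenerates. Pure projection
  can fold over strongly curled tips; LSCM does not.
* **Stopping.** Relative energy decrease below `1e-6` or 200 iterations.
  Meshes here are ~900 faces, so a full run costs a fraction of a second;
  hitting 200 iterations is reported as a warning, not an error, because
  the map is useful long before the asymptotic tail ends.
* **Gauge.** The translation gauge is fixed by pinning the centroid; the
  converged map is then re-oriented by the same canonical-frame rules as
  the 3D normalization (tip to +x, left edge at y > 0), and a globally
  reflected solution (negative signed area) is repaired by flipping y.

The per-leaf diagnostic is the total-area ratio of the 2D map to the 3D
mesh. On synthetic populations with realistic bend, twist, margin waves
and folds the ratio stays within (0.990, 1.000), the behavior expected of
a near-isometric parameterization of a gently folded surface.

## Contour sampling and the six sectors

The flat model's boundary (edges on exactly one face, chained CCW) is
sampled by 600 rays from the leaf center (0, 0). Where a wavy margin
gives several intersections on one ray, the farthest is kept: the sampled
curve is the outer silhouette, which is what an atlas drawing shows.
Rays grazing a vertex are treated as hits (inclusive segment test,
tolerance 1e-12). 600 rays resolve the tip and base, which sit far from
the center of an elongated leaf.

For the contour features the rays are partitioned into six sectors: tip
and base sectors of half-width 15 degrees, and upper/lower left/right
quadrant remainders split at 90 degrees. The sector bounds are
configurable constants -- no text defines them numerically -- and the
partition is exact: every ray belongs to exactly one sector.

## The 29 features

Seventeen mesh features (chain lengths LL/RL/ML, widths WA/WM/WV/WP,
LWR, tip angle LTA, offset angles LOA/ROA/MOA, midvein tortuosity
MTA/MTV, area A, folding FA/FV) and twelve radial contour features
(TP, RUP, LUP, RLP, LLP, BP, UP, LP, L, W, UL, LW). Conventions that the
feature names alone do not fix:

* Widths are measured at the original digitizer transects tracked through
  subdivision, not by re-slicing a fitted midvein: deterministic, and
  perpendicular to the midvein by construction of the acquisition grid.
* Offset angles are sums of *absolute* turning angles; tortuosity angles
  are unsigned. Variances are population variances (divide by N) -- the
  features are descriptors, not estimators.
* The widest-position tie (a plateau of equal widths) resolves toward the
  base, so a rectangle has WP = 0.
* Folding uses `alpha(x, y) = arccos(|x . y| / (|x||y|))` between
  edge-neighbor face normals, so it ignores normal orientation and lives
  in `[0, pi/2]`. It is computed on the subdivided 3D mesh; on any flat
  mesh it is identically zero, which the tests use as a guard against
  computing it on the wrong mesh.
* The contour feature table's row for W references an RLP feature whose
  own definition row is missing in the source tables; RLP is implemented
  symmetrically to LLP.
* `LWR = ML/WA`, `LW = L/W` and `UL = UP - LP` hold exactly, by
  construction.

## Semantic features, weights, and L2D

Redundancy among the 29 features is removed by hierarchical clustering
with average linkage on the Pearson distance `1 - r`, cut at 0.25; each
cluster is represented by its medoid (smallest mean intra-cluster
distance), a deterministic rule standing in for the source's unstated
"more representative" criterion. An override argument can force any
selection, e.g. the eleven features WP, LWR, L, LTA, WV, W, FA, MTV,
MTA, LOA, ROA reported for the original field population.

Per-feature weights come from a greedy grid search: each feature's raw
weight takes the seven values 0, 0.5, ..., 3 in turn with all others at
1, and the value maximizing identification ability is kept (ties toward
the smaller weight); the assembled raw vector is normalized to sum 1.
"Identification ability" is operationalized as the mean of rTop-1
through rTop-10 under leave-one-replicate-out evaluation -- each query
leaf is scored against per-line gallery means with its own replicate
removed from its line's mean, so a leaf can never match itself.

The composite index is the weighted sum of min-max standardized semantic
features, `L2D = sum_i w_i v_i`. Two decisions live here. First,
standardization: the semantic features mix cm, cm^2, rad and
dimensionless ratios, and no combination rule is stated for them;
min-max to `[0, 1]` over the atlas population makes L2D a calibrated
"how pronounced is this leaf" score with range `[0, 1]` and strict
monotonicity in every weighted feature. Second, the formula: the source
calls L2D a vector modulus but displays a weighted *sum*; the displayed
formula is the more precise statement and is what `compute_L2D()`
implements, with `modulus = TRUE` available for comparison. Lines sorted
ascending by L2D (ties by line id) form the atlas.

## Identification

A query leaf's standardized semantic vector is compared to each line's
gallery vector by cosine similarity of the element-wise weighted vectors;
lines are ranked by similarity and rTop-X is the fraction of queries
whose true line appears in the first X. Gallery vectors are per-line
means of replicate vectors, matching the one-model-per-line atlas. For
shape lookup from a semantic vector alone, a match is accepted only at
similarity >= 0.9; below that the requested shape is declared absent
rather than drawn from a poor match. Cosine similarity is blind to
positive scaling of a vector, so two lines with exactly proportional
weighted vectors are indistinguishable -- a measure-zero event for real
populations but worth knowing when constructing toy examples.

## The synthetic population generator

Real digitizer data for the original 518-line population is not
redistributable, so validation runs on a parametric generator that
emulates what the digitizer sees: a midvein bent with constant curvature
(circular arc, arc-length parameterized so the true midvein length is
known exactly), a beta-shaped width profile `(t + 0.25)^a (1 - t)^b`
whose peak location is the controllable widest-position truth, twist
accumulating linearly to the tip, sinusoidal margin waves on columns 1
and 5, and a transverse fold field with its amplitude envelope centered
at 35% of the leaf length -- echoing the observation that folds
concentrate in the lower-middle blade. With all deformations zero the
generated surface is exactly planar, which anchors several tests.

Default line-parameter ranges are chosen once as a plausible maize
ear-leaf population at silking: length 60-95 cm, maximum width 6-12 cm,
widest position 30-50% of length, bend up to 0.05 rad/cm, total twist up
to 0.3 rad, margin waves up to 0.3 cm, folds up to 2% of width, 13-18
transects. Replicates within a line redraw each parameter with Gaussian
noise at 0.15 of the between-line standard deviation, plus 0.02 cm
point jitter emulating probe precision. Every leaf's RNG stream derives
from (master seed, line, replicate), so populations are reproducible and
order-independent.

What the generator does *not* emulate: serrated or torn margins, the
ligule/sheath transition at the base, operator placement bias along the
transect, senescence, or growth-stage allometry. Green tests on this
population therefore demonstrate the pipeline's geometric and
statistical correctness, not field-data performance; headline accuracy
numbers from any real population are dataset-specific and are not
reproduced here.

## Problem sizes and numerical notes

The test suite exercises the full pipeline on a 100-line, 3-replicate
population (the package's default population specification), a 50-leaf
single-replicate population for the area-preservation band, and a
30-leaf noise-free population for ground-truth recovery (midvein length
and maximum width within 2%, widest position within 0.05). These sizes
keep a full check under a couple of minutes on one core while leaving
the identification task non-trivial (chance rTop-1 is 1%).

Degenerate inputs are rejected early with specific errors: point counts
not of the form 5n+1, fewer than two transects, zero-area triangles
(naming the transect), collinear vertex clouds, non-manifold meshes,
multiple boundary loops, rays with no boundary intersection (naming the
angle), constant feature columns (naming the feature), and all-zero
weight vectors. ARAP non-convergence at the iteration cap is a warning
carrying the full energy trace, never a silent truncation.
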