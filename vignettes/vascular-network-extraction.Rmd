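---
title: "From stained volumes to vascular topology maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stained volumes to vascular topology maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculonet)
```

## The problem

Intraluminal staining (for example perfusing a fluorescent lectin through
the feed artery of a lymph node) labels the walls of every perfused blood
vessel, and block-face confocal imaging of the resin-embedded organ yields
an isotropic 3D grayscale volume — in the motivating setting, 2 µm voxels
over a few cubic millimetres. Quantitative questions about such a network
(How many vessel segments? What is the diameter and length distribution?
How far is each tissue location from its nearest vessel? Which vessels are
morphologically high endothelial venules?) require converting the voxel
image into a *topology map*: a graph of nodes (junctions and endpoints)
and segments (vessel runs) carrying a centerline polyline and a radius at
every centerline point.

`vasculonet` implements that conversion and the downstream topological
analyses. Because organ-scale stained volumes are rarely shareable, the
package also contains a first-class phantom generator that produces
parametric vascular trees with exact ground truth; every stage of the
pipeline is validated against those phantoms.

## Conventions

All physical quantities are micrometres. Volumes are 3D arrays with
isotropic voxel size; the world coordinate of the center of voxel
$(i,j,k)$ (0-based) is $\mathrm{origin} + v\,(i,j,k)$ with $v$ the voxel
edge length. The third array index is the slice index. Anisotropic voxels
are rejected at load time: a single convention end to end avoids
off-by-one drift between modules.

## Segmentation: threshold, insideness filling, largest component

**Local thresholding.** A voxel is foreground iff its intensity exceeds
the mean over a cubic window of half-width `window_radius` plus `offset`.
The window (default 25 voxels ≈ 50 µm at 2 µm resolution) must be wider
than the widest vessel so that the window mean estimates local
background rather than vessel interior. The implementation uses a 3D
integral image, so cost is independent of window size.

**Insideness filling.** Luminal staining labels walls, not lumina, and
leaves gaps where the stain did not reach. The *insideness* of a
background voxel is the fraction of a fixed, deterministic set of ray
directions along which a foreground voxel is met within a search radius;
voxels at or above a threshold fraction are converted to foreground, and
the operator is iterated to a fixpoint (converted voxels support further
conversions) with a hard cap of 10 sweeps. The operator is extensive and
monotone, which the test suite checks as properties. For the default 26
voxel-neighbour directions the per-direction visibility is computed
exactly by linear lattice sweeps (one pass per direction), so a full
sweep is $O(26N)$; other ray counts use a Fibonacci-sphere direction set
and explicit ray marching.

Two regimes use this one operator:

* *Lumen filling* (defaults: 45 µm reach, 26 rays, threshold 0.85). Deep
  inside a tube essentially every direction meets wall within one vessel
  diameter, so a high threshold fills lumina without touching the
  exterior. The 45 µm default reach sits just above the largest vessel
  radius expected in a lymph node (87 µm diameter).
* *Gap-shell closing* (`segment_vessels` stage two; defaults: 10 µm
  reach, 66 rays, threshold 0.6, candidates restricted to a 6 µm shell
  around the current surface). A voxel in a shallow surface dent — the
  footprint of a staining gap after the lumen beneath has filled — sees
  vessel over clearly more than a hemisphere of directions at short
  range, whereas a voxel resting on a flat or convex outer surface sees
  at most a hemisphere (fraction 0.5). The threshold 0.6 is the midpoint
  between that hemisphere bound and the ≈0.7 visibility of a gap floor.
  The short reach matters: it is chosen *below* the closest approach of
  distinct vessels, so stage-two rays can never register a neighbouring
  branch and bridge two vessels.

This two-regime structure is a genuine limitation worth stating plainly:
the outermost one-voxel shell of a wall gap has visibility that straddles
0.5 — locally it is indistinguishable from exterior background. On
phantoms with tube radii of three voxels and above the pipeline recovers
≥ 99 % of true vessel voxels with < 5 % spurious additions; when tube
radii approach two voxels, carved gaps become notches comparable to the
tube itself and recovery saturates around 98.5–99 %. No ray-coverage
threshold separates the residue without runaway surface growth (we
verified thresholds 0.50–0.65, reaches 10–45 µm, 26 vs 66 rays, and
ball-closing post-passes up to 8 voxels).

**Largest component.** The stained network of interest is connected, so
segmentation ends by keeping the largest 26-connected component. Ties are
broken deterministically toward the component containing the
lexicographically smallest voxel.

## Skeletonisation and tracing

**Thinning.** The filled mask is reduced to one-voxel-wide centerlines by
iterative topology-preserving thinning: a voxel may be deleted only when
it is a *simple point* for (26, 6) connectivity — exactly one
26-connected foreground component in its 26-neighbourhood and exactly one
6-connected background component in its 18-neighbourhood touching the
center — and never when it is a curve endpoint. Deletion proceeds in six
directional subiterations (up/down/north/south/east/west) with
sequential re-checking, making the result deterministic and keeping the
skeleton centered. Connected components and independent loops are
preserved; the suite verifies both on trees and on a solid torus (whose
skeleton must retain exactly one cycle).

**Radii.** The radius at a skeleton voxel is its Euclidean distance to
the nearest off voxel (exact squared distance transform, voxel-center
convention). This estimator has a known upward bias of up to about half
a voxel on-axis and a downward bias where thinning leaves the centerline
slightly off-axis; on 2 µm phantoms per-segment diameters land within
one voxel (±2 µm) of truth for > 99 % of segments.

**Tracing.** Skeleton voxels with one 26-neighbour are endpoints, with
three or more are junction voxels; a 26-connected clique of junction
voxels collapses to one node at its centroid (the distance estimator is
inflated inside junction blobs, which is also why the first and last
point of a segment with ≥ 4 points are excluded from its diameter).
Maximal chains of degree-2 voxels become segments; isolated cycles are
anchored at their lexicographically smallest voxel and stored as
self-loop segments — self-loops and multi-edges are first-class, since
real capillary beds contain reconnecting arcades.

Two geometric corrections are applied by default and are worth knowing
about:

* *Tip trimming* (`trace_skeleton(trim_tips = TRUE)`): thinning a tube
  with a rounded end leaves a centerline overrunning the tube end by
  about one radius; each terminal segment is therefore shortened at its
  free end by the radius measured there. Without this, total network
  length on phantoms is biased by ≈ +9 %; with it the error is ≈ 4–7 %.
* *Junction fusion* (`prune_network(merge_junction_distance = …)`):
  thinning a thick bifurcation can leave a tiny triangle or bubble of
  skeletal bridges (observed up to ≈ 2.4 × the parent radius). Two
  genuine branch points closer than a vessel radius are not resolvable
  as distinct junctions at this voxel size, so junction-to-junction
  segments shorter than the given scale are contracted. In the
  validation suites the scale is 35 µm: above the fusion zone of the
  thickest phantom vessels (2.4 × 12 µm ≈ 29 µm) and below the shortest
  genuine segment the generator produces (45 µm); the measured
  populations are cleanly separated (spurious bridges ≤ 28 µm, genuine
  traced internal segments ≥ 45 µm).

**Pruning.** Terminal segments shorter than `min_length` or thinner than
`min_mean_diameter` are removed and pass-through (degree-2) nodes are
dissolved, repeating to a fixpoint; this is the automated stand-in for
interactive editing of the raw trace. Pruning never increases the
component count.

**Summaries.** Segment length is the polyline arc length; segment
diameter the length-weighted mean of point diameters (junction-adjacent
end points excluded as above); segment volume the sum of conical frusta.
Totals are reported in cm (length) and mm³ (volume), histograms in 1 µm
bins. Totals are additive over any partition of the segments, which the
suite asserts.

## Analytics

* **Branch counts** (`branch_counts`): breadth-first edge distances from
  a user-chosen feeder node on the segment multigraph. Edge count (not
  junction count) is the convention: the first generation of branches
  off the feeder has count 1. Unreachable nodes are flagged `NA`, never
  silently 0. The feeder is supplied by the user (in the original organ
  the artery and vein are identified visually); `suggest_feeder_nodes`
  ranks degree-1 nodes by incident diameter as candidates.
* **Diameter selection** (`select_by_diameter`, `split_trees`): keeps
  segments by mean-diameter window and minimum length. The putative-HEV
  preset is 16–32 µm diameter with length ≥ 40 µm — a morphology-based
  proxy for high endothelial venules; expect the result to be several
  connected subnetworks plus isolated vessels, and use
  `exclude_segments` for known arterial branches rather than any
  automatic guess. Thresholding above 15 µm and splitting into connected
  components yields candidate arterial and venous trees (no flow
  direction is inferred).
* **Organ region** (`ln_region`): morphological closing of the vessel
  mask with a ball (default 60 µm) followed by hole filling — background
  components not 6-connected to the volume border become tissue. The
  result is always a superset of the mask.
* **Distance fields and voids** (`distance_field`, `find_voids`): the
  region is overlaid with a grid (default 4 µm, which must be an integer
  multiple of the voxel size so grid points coincide with voxel
  centers), and every grid point inside the region but outside the
  vessels gets the Euclidean distance to the nearest vessel *voxel
  center* — not the analytic vessel surface; at 2 µm voxels the
  difference is sub-voxel, and the brute-force oracle in the tests uses
  the same convention so agreement is exact, not approximate. Voids are
  grid points farther than a threshold (60 µm conventionally) from any
  vessel; `write_stack` turns the void mask into a white-voxel TIFF for
  3D viewing.
* **Virtual histology** (`histology_2d`): counts centerline crossings of
  an axis-aligned plane, one per transit, with tangential runs on the
  plane counted once; the local diameter is interpolated between the
  bracketing centerline points, and density is crossings per mm² of
  region cross-section.
* **Subregion statistics** (`region_stats`): for a rectangular block
  (typically 100³ voxels ≈ 200 µm per side), the mean nearest-vessel
  distance, the 3D density as segments whose arc-length midpoint falls
  in the block per mm³ (the midpoint rule makes counts additive over a
  partition into blocks), the 2D density on the block's central plane,
  and the mean diameter of the midpoint segments.

## The phantom generator

`phantom_spec`/`generate_tree` grow a full binary tree of straight tube
segments: `2^(levels+1) - 1` segments, radii shrinking by `radius_ratio`
per generation, segment lengths and branch angles drawn uniformly from
their ranges, daughters leaving at opposite azimuths. The default preset
is lymph-node-like: six levels from a 30 µm radius feeder at ratio 0.75,
spanning diameters of roughly 8–60 µm at 2 µm voxels, against the 4–87 µm
range seen in a real node. Everything is deterministic given the seed.

`rasterize` draws the tree as a union of capsules (solid mode) or as
wall shells with the interiors of *all* capsules subtracted so junctions
stay open (hollow mode), then carves a seeded fraction of wall voxels in
contiguous spherical patches of radius 2 voxels — the staining-gap model
that the insideness filler targets; scattered salt-and-pepper dropout
would be a different, easier failure mode.

By default branches other than siblings may pass arbitrarily close
(`min_clearance = 0`), because real capillary beds contain near-touching
vessels and an extractor must tolerate them — but a tracer cannot be
*validated* against ground truth on such trees, since touching tubes are
indistinguishable from a true junction at the image level. For
validation, `sample_phantoms` therefore draws trees with an enforced
surface clearance (20 µm) between non-adjacent branches and a minimum
angle between siblings, and checks the realised minimum separation
(`min_branch_separation`) post hoc. Validation phantoms use a 12 µm root
radius at ratio 0.85 (all radii ≥ 2 voxels) and segment lengths of
45–75 µm.

What the phantoms do *not* emulate: curved vessels (segments are straight
chords), radius taper within a segment, loops/anastomoses (the tracer
handles cycles, tested on hand-built masks, but the generator grows
trees), image noise beyond the binary rendering used in the gap-closing
tests, and the point-spread and shading artefacts of real confocal
stacks. Passing the phantom suites therefore demonstrates the geometry
and topology machinery, not robustness to raw-microscope artefacts —
instrument-specific preprocessing is assumed to have happened upstream.

## Numerical choices and degenerate inputs

* Distance transforms are exact squared Euclidean (three-pass separable
  algorithm); no chamfer approximations anywhere.
* Component labelling scan order, the lexicographic tie-break in
  `largest_component`, the fixed ray sets, the sequential thinning
  order, and fixed 6-decimal formatting in the SpatialGraph writer make
  every stage deterministic; writers are byte-stable for identical
  input.
* Empty masks: `largest_component` warns and passes them through;
  `skeletonize` returns an empty skeleton; an empty vessel mask is an
  error in `distance_field` (the distance is undefined).
* A single isolated voxel is its own skeleton and traces to one node
  with no segments; a pure cycle traces to one anchor node with one
  self-loop.
* Grid spacing must be an integer multiple of the voxel size; anything
  else errors rather than silently interpolating.

## Problem sizes used in the validation suites

The shipped test-suite and acceptance-script runs use: 20 solid
validation phantoms (depths 4–6, domains 420–700 µm cubed, i.e. up to
~350³ voxels at 2 µm), 3 hollow phantoms with 10 % wall gaps, 20
random ≤ 32³ distance-field cases against an O(N·M) brute force, 50
random ≤ 12-node graphs against exhaustive path enumeration, and a 5×5
parallel-tube lattice for the histology checks. On a single CPU the
whole suite runs in a few minutes; the sizes were chosen as the smallest
at which the geometric error regimes discussed above are visible.

## Export formats

Amira SpatialGraph (ASCII AmiraMesh, `VertexCoordinates` /
`EdgeConnectivity` / `NumEdgePoints` / `EdgePointCoordinates` /
`thickness`, with per-point *radius* stored as thickness, which is the
common convention) with a bundled reader for round-trips; a minimal
CMGUI `exnode`/`exelem` dialect (1D linear elements over segment
endpoints — the layout is self-consistent but not claimed identical to
any particular historical file); a JSON schema
(`{voxel_size, nodes: [{id, pos, segs}], segments: [{id, nodes, points,
radii}]}`) that round-trips at full double precision; and CSV attribute
exports paired with a SpatialGraph per-point field for rainbow colour
mapping of diameters or branch counts in external viewers. No rendering
is performed by this package.

## Known limitations

* The gap-closing recovery saturates below 99 % for tubes near the
  two-voxel radius floor, as quantified above.
* Diameters inherit the ±1 voxel bias envelope of the distance-transform
  estimator; reported total lengths on phantoms are accurate to ≈ 7 %
  (skeleton staircase and junction displacement).
* The pHEV selection is purely morphological; it cannot detect HEVs that
  fall outside the diameter window, and its diameter distribution is
  truncated by construction.
* Branch counts require the user to name the feeder node; on a network
  whose feeder was not captured, counts are relative to whatever node is
  chosen.
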