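---
title: "Segmenting tiled biological structures with random-walk distance transforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting tiled biological structures with random-walk distance transforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilewalk)
```

## The problem

Many biological tissues are built from large numbers of similar repeating
units in direct contact: the mineralized tesserae that tile shark and ray
cartilage, the ossicles of echinoderm endoskeletons, the calcite prisms
of bivalve shell layers. MicroCT resolves these units, but because
adjacent units touch — through a narrowed neck ("constriction") or a
boundary too fine for the scan to resolve — intensity alone cannot
separate them. The practical route is: binarize the whole tissue, compute
a *distance transform* on the foreground, and split the tissue at the
valleys of that transform.

The standard Euclidean distance transform (EDT) records, per foreground
voxel, the shortest distance to background. That single nearest-neighbor
measurement makes it fragile: a handful of mis-binarized voxels (pores)
inside a structure create deep artificial valleys, and a constriction
that narrows the structure in only one dimension (a flat tile thinning at
its rim) barely registers. This package implements the alternative: the
**random-walk distance transform (RWDT)**, the expected number of steps a
random walk starting at a foreground voxel takes until it first reaches
background. Because the expectation integrates over *every* escape route,
the map reflects the global shape of each unit, and sparse noise perturbs
it only marginally.

## The walk model

A walk at voxel $v$ moves to one of its stencil neighbors uniformly at
random and is absorbed on first contact with background. The expected
absorption time $h$ solves the linear system

$$\deg(v)\,h(v) \;-\; \sum_{u \in N(v)\cap F} h(u) \;=\; \deg(v), \qquad
h \equiv 0 \text{ on background},$$

over the foreground $F$. Restricted to $F$ the system is symmetric
positive definite; `random_walk_distance()` solves it directly (sparse
Cholesky) below $2\times10^5$ unknowns and by Jacobi-preconditioned
conjugate gradients above, always verifying the relative residual against
`solver_tolerance` (default $10^{-8}$, well inside the admissible
$(0, 10^{-3}]$). `monte_carlo_walk_length()` simulates the identical walk
and is used in the tests as an independent oracle.

Model choices that the one-line definition of the transform leaves open,
and how this package resolves them:

* **Stencil.** Default 26-neighbor (full cube shell); 6 and 18 are
  available. The choice matters under noise: a single absorbing pore
  captures $1/\deg$ of the local flux, so under a 6-stencil one pore
  depresses the map by $\approx 1/6$ of its local value — enough to
  manufacture spurious peaks whose topological persistence exceeds the
  usual merge thresholds (0.15 of the normalized range). Under a
  26-stencil the same pore captures $1/26$, and pore-induced persistence
  stays around 0.04. The hand-solvable reference cases in the tests use
  the 6-stencil, for which the small systems are easily solved by hand
  ($h = 1$ for an isolated voxel; $h = 1.2$ for a face-adjacent pair;
  $h = 21/17$ and $24/17$ for the ends and center of a 1×1×3 bar).
* **Volume border.** Reflecting by default (out-of-volume neighbors are
  removed from the stencil): tissue frequently touches the scan border,
  and treating the border as background would fabricate absorption where
  none exists. An absorbing border is available by flag.
* **Step metric.** Steps count unit length regardless of voxel spacing or
  diagonal moves; the transform is graph-based and spacing-free. Only the
  EDT and physical volume/area measurements consume spacing.

The exact EDT is provided for comparison via the separable lower-envelope
algorithm (`euclidean_distance()`), exact to floating point — the test
suite checks it against a brute-force all-pairs oracle — with optional
anisotropic spacing.

## Segmentation: contour-tree region growing with persistence merging

`contour_tree_segment()` sweeps foreground voxels in decreasing map
order. Each local maximum founds a region; where regions meet (a saddle),
any region whose *persistence* — its peak value minus the saddle value —
falls below the threshold is merged into the adjacent region with the
highest peak. The persistence threshold is the single dial controlling
over- versus under-segmentation; 0 disables merging entirely. Thresholds
are interpreted on the min-max normalized map (`normalize_first = TRUE`),
the only scale on which a value such as 0.15 is meaningful.

Numerical conventions, chosen for determinism:

* Ties in map value are broken by ascending linear array index, making
  the sweep a pure function of its input.
* Regions with exactly zero persistence (fragments of one value plateau)
  always merge, so a plateau is one region and the threshold-0 label
  count equals the plateau-aware local-maximum count
  (`count_local_maxima()`). This matters for the quantized EDT, whose
  maps are full of exact ties.
* Saddle voxels are always assigned to the surviving adjacent region with
  the highest peak; no foreground voxel is left unlabeled, so every
  segmentation partitions exactly the input foreground.

For fragmented binarizations, the starfish-style **multi-threshold
ensemble** (`ensemble_rwdt()`) binarizes at each threshold of a list,
min-max normalizes each RWDT, and averages voxelwise; voxels that are
foreground at only some thresholds — threshold-fragile constrictions —
dip in the average. Thresholds whose mask admits no valid transform are
skipped with a warning and the average is taken over the maps actually
computed (with no failures this equals the divide-by-all convention).

## Post-processing

`apply_merges()` applies a manual merge list with union semantics (the
merged set keeps its smallest label). `directed_merge()` automates the
prismatic-layer case — gluing the stacked fragments of a columnar unit
without absorbing lateral neighbors — with three interpretable gates on
every touching label pair: centroid-difference angle to the growth axis
(default ≤ 30°), axis-perpendicular footprint overlap (≥ 0.5 of the
smaller footprint), and axis gap (≤ 3 voxels). The pass iterates to a
fixed point in ascending label order, so it is deterministic and
idempotent. These gates are this package's own design; they encode the
published intent (merge along growth, never sideways) with testable
parameters.

## Morphometrics

`build_rag()` defines neighborhood as face contact (6-connectivity) with
a `min_contact` dial — the strictest reproducible notion of "touching".
`tile_stats()` reports voxel counts, physical volumes, mean intensities
(a proxy for mineral density), centroids, and principal extents
($4\sqrt{\lambda_i}$ of the per-label coordinate covariance, a
rotation-invariant full-width proxy). `neighbor_histogram()` summarizes
the neighbor-count distribution; on a flat hexagonal tiling the interior
mean is exactly 6, while on curved anatomy topological defects shift the
mean below 6 — which is why no specific mean is asserted for real
tissue. `prism_profiles()` computes per-slice area-equivalent radii
$R(z)=\sqrt{A(z)/\pi}$, an ordinary-least-squares slope $dR/dz$, a
growing/shrinking class from the slope sign, and a *relative curvature*
$\overline{1/\bar R(z) - 1/R_i(z)}$ against the per-slice mean radius —
the critical-radius proxy of curvature-driven (Hillert) grain coarsening.
The exact x-axis of the published rate-versus-curvature trend is not
stated anywhere; the per-slice mean-radius definition is this package's
declared choice. `evaluate_segmentation()` scores a labeling against
ground truth by majority overlap (one-to-one, split, and merged counts;
a predicted label is "merged" when its majority truth label covers less
than 60% of it or when it is the top contributor to two or more truth
labels).

## Synthetic phantoms: what they emulate and what they do not

All tests run on generated volumes with exact ground truth
(`voronoi_tiling_phantom()`, `hexagonal_tiling_phantom()`,
`columnar_prism_phantom()`, `inject_pore_noise()`). Each phantom is a
pure function of its parameter record including the seed. Foreground
renders at 200 and background at 50 on an 8-bit-like scale, so global
thresholding at 125 is exact when image noise is off and distance
transform behavior is isolated from binarization behavior.

**Voronoi slab tiling** (the tessellated-cartilage stand-in): blue-noise
(best-candidate) seed points — the workflow assumes units of similar
size, which independent uniform points would violate — define planar
Voronoi cells extruded through a slab; the top and bottom
`constriction_fraction` of the slab thickness is carved away along every
inter-tile boundary, leaving a mid-thickness bridge. The study conditions
used by the tests are 25 tiles in a 16×128×128 volume, slab thickness 11,
constriction fraction 0.3 (3 voxels carved top and bottom, a 5-voxel
bridge), and 1% pore noise. These conditions express the flat-object
regime in which the two transforms genuinely diverge. For the Euclidean
transform the notch saddle (2–3 voxels) coincides with the typical
distance to the nearest pore at 1% density ($\approx 2.6$ voxels), so the
geometric valleys between tiles are indistinguishable from pore wells and
no merge threshold recovers the tiling — a constriction expressed in only
one dimension of a flat structure gives the Euclidean transform a weak,
linear contrast. The walk map's contrast at the same bridge is quadratic
in the thickness ratio (saddle ≈ $(2.5/5.5)^2 \approx 0.2$ of the peak)
and pore-induced dips stay near 0.04 under the 26-stencil, so the
published persistence threshold of 0.15 separates all tiles with a wide
margin even though pores compress the upper range of the map.

**Hexagonal tiling**: a regular pointy-top hexagonal grid with the same
carving; every interior tile has exactly six neighbors by construction —
the reference for neighbor-count code, not a claim about real anatomy.

**Columnar prisms**: one additively-weighted planar Voronoi (power
diagram) per slice, sharing sites across slices; weights evolve along the
growth axis by explicit Euler (one step per slice) under
$dw/dz = c\,(1/\bar R - 1/R_i)$, so columns thinner than the slice
average shrink and eventually vanish, and thicker ones grow. Defaults
(50 columns, 60×200×200, $c = 200$) were chosen so that a realistic
minority of columns vanishes within the volume while the
slope-versus-curvature trend is clearly expressed. One-voxel background
sheets separate columns except for periodic bridge voxels, emulating a
discontinuous, under-resolved boundary.

What the phantoms deliberately do **not** model: X-ray physics (beam
hardening, ring artifacts), curved anatomical surfaces and their
topological defects, spatially correlated binarization noise, and
intensity gradients within units. Passing tests therefore demonstrate the
algorithmic properties of the transforms and the segmentation machinery
under controlled geometry — not end-to-end performance on any real scan.

## Problem sizes and runtime choices

The test and acceptance workloads are sized for a single CPU: the tiling
comparison solves two systems of roughly $2\times10^5$ unknowns
(about a minute each with the 26-stencil), the Monte-Carlo cross-check
uses 10×10×10 masks with 20,000 walks per probe, and the Euclidean
brute-force oracle runs on 20³ masks. The direct/iterative solver
crossover at $2\times10^5$ unknowns keeps memory modest while the
conjugate-gradient path scales to multi-million-voxel masks.

## Known limitations

* The walk law (stencil, border handling, unit steps) is a declared model
  choice; other discretizations of "expected walk length to background"
  are defensible and would shift absolute map values (not, in our tests,
  segmentation outcomes at moderate persistence thresholds).
* Min-max normalization ties the persistence scale to two extreme voxels;
  a robust (quantile) normalization would be less seed-sensitive but is
  not what the published workflows describe.
* `directed_merge()` cannot split under-segmented labels; the workflow
  deliberately prefers over-segmentation because merging is cheaper than
  splitting.
* The evaluation's 60% majority-coverage rule for "merged" labels is a
  convention; counts near the boundary move with it.
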