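# tilewalk

High-throughput segmentation of **tiled biological structures** in 3D
grayscale volumes — tessellated cartilage in sharks and rays, echinoderm
dermal ossicles, the prismatic layer of bivalve shells, and any other
tissue built from thousands of similar units in direct contact.

Separating touching units is the hard step: they meet through narrow
constrictions or unresolved boundaries, so thresholding alone yields one
connected blob. The standard remedy — cut the blob at the valleys of a
distance transform — usually relies on the Euclidean distance transform
(EDT), which is noise-fragile: a few mis-binarized voxels inside a unit
carve artificial valleys that no merge threshold can undo. `tilewalk`
implements the **random-walk distance transform (RWDT)** instead: for
each foreground voxel, the expected number of steps of a uniform
nearest-neighbor random walk until it first reaches background,

    deg(v) h(v) − Σ_{u ∈ N(v) ∩ F} h(u) = deg(v),    h ≡ 0 on background,

a sparse symmetric positive-definite system solved exactly. Because the
expectation integrates over every escape route, the map encodes the
*global* shape of each unit and sparse pore noise barely moves it.

The package covers the full workflow:

* **IO** — multipage TIFF, directories of TIFF/PNG slices (natural-number
  ordering), and NRRD, with voxel-spacing metadata (`read_volume()`,
  `write_volume()`, `write_labels()`).
* **Pre-processing** — Gaussian local intensity normalization
  (`local_normalize()`).
* **Binary segmentation** — global thresholding and small-component
  removal (`threshold_mask()`, `remove_small_components()`).
* **Distance transforms** — `random_walk_distance()`, exact
  `euclidean_distance()`, min-max normalization, and the multi-threshold
  `ensemble_rwdt()` used for skeletons whose constrictions appear only at
  some binarization thresholds.
* **Over-segmentation** — contour-tree region growing with
  topological-persistence merging controlled by a single threshold
  (`contour_tree_segment()`).
* **Post-processing** — manual merge lists (`apply_merges()`) and
  directed merging along a growth axis for columnar prisms
  (`directed_merge()`).
* **Morphometrics** — region adjacency graphs, per-tile volume /
  neighbor-count / intensity statistics, prism radius profiles
  R(z) = √(A/π) with growth classification, and evaluation against
  ground truth (`build_rag()`, `tile_stats()`, `neighbor_histogram()`,
  `prism_profiles()`, `evaluate_segmentation()`).
* **Phantoms** — seeded generators of ground-truthed tiled volumes
  (`voronoi_tiling_phantom()`, `hexagonal_tiling_phantom()`,
  `columnar_prism_phantom()`, `inject_pore_noise()`) so the whole
  pipeline is testable without any scan data.
* **Pipeline runner** — `run_pipeline()` executes a config-described run
  and writes every intermediate, a timing log, and a manifest that
  reproduces the run bit-exactly. A command-line front end with one
  subcommand per stage ships in `inst/cli/tilewalk.R`.

## Worked example

Generate a 25-tile slab phantom with constricted contacts, corrupt the
mask with 1% pore noise, segment it with the walk transform, and compare
against ground truth:

```r
library(tilewalk)

b     <- voronoi_tiling_phantom(seed = 7)          # image + truth + mask
noisy <- inject_pore_noise(b$mask, 0.01, seed = 8) # binarization noise
dmap  <- random_walk_distance(noisy)               # expected steps to background
seg   <- contour_tree_segment(dmap, segmentation_params(persistence_threshold = 0.15))
evaluate_segmentation(seg, b$truth)
#> <tw_eval> truth 25, predicted 25: 25 one-to-one, 0 split, 5 merged

head(tile_stats(seg, b$image), 3)
#>   label voxel_count volume neighbor_count mean_intensity centroid_z centroid_y
#> 1     1       12359  12359              5            200   7.486811   13.65462
#> 2     2       10550  10550              6            200   7.469763   48.88000
#> 3     3        7145   7145              9            200   7.567460   81.76326
```

All 25 tiles are recovered one-to-one despite the noise (the `5 merged`
flags mark labels whose region-growing boundary leaked into a neighbor's
territory across a bridge — a boundary-placement diagnostic, not a lost
tile). Running the same
segmentation on `euclidean_distance(noisy)` instead and scanning the
whole persistence range never recovers the full tiling — the comparison
the acceptance script below reproduces. The per-tile table reports voxel
counts, physical volumes, neighbor counts (tile "sides"), and mean
intensity (a mineral-density proxy).

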