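---
title: "Methods: segmenting tessellated layers with tessella"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting tessellated layers with tessella}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tessella)
```

## The model

Tessellated calcified cartilage is a thin mineralized shell — a few tens of
micrometers thick — composed of thousands of polygonal tiles (tesserae)
separated by narrow unmineralized joints and pores. In µCT the tiles appear
bright against soft tissue, and adjacent tiles remain connected through
mineralized bridges whose in-plane width is narrow compared to the tile
diameter but comparable to (or wider than) the shell thickness.

That last geometric fact is why standard watershed segmentation fails. The
classical recipe seeds a watershed with the 3D Euclidean distance transform
$D_{3D}(x) = \min_{y \notin F} \lVert x - y \rVert$, whose value on a thin
sheet is capped at half the sheet thickness everywhere. Since the bridges
are about as wide as the sheet is thick, $D_{3D}$ is essentially flat across
tiles *and* bridges, and the watershed has no basins to separate.

`tessella` replaces $D_{3D}$ with a locally-planar 2D distance map
$\tilde D_{2D}$: at every foreground voxel the plane that locally best
approximates the sheet is estimated, and the distance to background is
measured *within that plane*. On a thin sheet this recovers the in-plane
distance to pores and joints — large at tile centers, small at bridges —
which is exactly the basin structure the watershed needs.

## Pipeline stages and parameters

### 1. Edge-stopping anisotropic diffusion — `smooth_anisotropic()`

Explicit finite-volume diffusion on the voxel grid with a hard edge-stopping
rule: the flux between 6-neighbors $p, q$ is $dt \cdot (I_q - I_p)$ if
$|I_q - I_p| \le t_s$ and exactly zero otherwise.

* `stop_threshold` ($t_s$, required): the edge-stopping threshold, in
  intensity units. Set it
  between the noise amplitude and the foreground/background contrast; the
  blocking is *exact* (a binary coefficient, not a soft weight), so contrast
  edges steeper than `t_s` are preserved bit-for-bit.
* `steps = 25`, `dt = 1/6`: 25 explicit steps at the largest time step that
  is unconditionally stable for the 6-neighbor stencil ($dt \le 1/6$).

Numerical conventions: the blocking coefficients are **re-evaluated at every
step** from the current image, not frozen from the input — a once-smoothed
gradient that drops below `t_s` starts diffusing on later steps. The scheme
is conservative (the global sum is preserved to machine precision, checked
to `1e-10` relative) and satisfies the discrete extremum principle.

```{r diffusion}
two <- array(c(0, 10), c(2, 1, 1))
smooth_anisotropic(two, diffusion_params(stop_threshold = 100, steps = 3))[, 1, 1]
# closed form: 5 -/+ 5 (1 - 2 dt)^k
5 + c(-5, 5) * (1 - 2 / 6)^3
```

### 2. Strip-restricted local thresholding — `segment_foreground()`

A voxel $x$ is foreground iff it lies in a strip $S$ around the layer and
$I(x) > t_n \cdot \mathrm{mean}(I \text{ over } B(x, l) \cap S)$, with
**strict** inequality. The strip is the set of voxels within Euclidean
distance `grow_radius` of the tolerant global threshold `t_g`; restricting
the box mean to $S$ keeps far-away background from diluting the local
statistics.

* `box_length` ($l$): odd, roughly 2–3 times the layer thickness.
* `t_n = 1`: the dimensionless ratio; 1 means "brighter than the local
  strip mean". The criterion is scale-invariant: multiplying the image by a
  positive constant leaves the mask unchanged.
* `t_g`: below the lowest expected foreground intensity, above background.
* `grow_radius`: at most about $l/2$ — strip voxels further than that from
  the layer see no foreground inside their box anyway.

Box means use 3D integral images and match the naive clipped-box loop
exactly. Enclosed background cavities (6-connected components not touching
the volume border) are filled afterwards.

### 3. Locally-planar 2D distance map — `distance_map_2d()`

At each foreground voxel $x$:

1. Cast `n` rays (default 1214, a deterministic Fibonacci-sphere set)
   from $x$ through the foreground until the first background voxel
   (Bresenham-style dominant-axis traversal). Rays that leave the grid or
   reach the ray cap contribute **no** hit point; fewer than 3 hits is an
   error signaling an unbounded region or a too-small cap.
2. Fit the least-squares plane to the hit points: the normal is the
   direction of least scatter about the centroid (smallest eigenvector of
   the 3×3 scatter matrix, sign-fixed so its largest-magnitude component is
   positive). The plane is translated to pass through $x$.
3. Cast `m` rays (default 361) at equal angles within the plane and return
   the distance to the nearest background hit. The in-plane basis is
   deterministic: the normal is crossed with the coordinate axis of its
   smallest-magnitude component, and the second basis vector completes the
   right-handed frame. If no in-plane ray meets background, the **cap value
   itself** is returned (the region is locally unbounded at that scale),
   and the default cap is `max(dim(mask))`.

Voxels are processed independently, so results do not depend on evaluation
order. On axis-aligned slabs with pores the map agrees with the exact
in-plane Euclidean distance transform to within 1 voxel for distances up to
20 — provided the slab's lateral walls are real background in the volume;
rays censored by the grid boundary carry no information, which is a
property of the estimator, not a bug, and matters only within a ray length
of the volume border.

### 4. Hierarchical watershed — `build_hierarchy()` / `extract_segmentation()`

The negated distance map is flooded once (26-connectivity, lowest value
first). Each regional minimum plateau seeds a basin; when two basins meet,
the saddle value is recorded as a merge event. Extraction replays the
events: basins $A, B$ with minima $m_A, m_B$ meeting at saddle $s$ merge iff

$$ s - \max(m_A, m_B) < T_p \quad (\text{strictly}) $$

or either basin currently holds fewer than $T_v$ voxels. The merged basin
keeps the deeper minimum, so later persistence computations see the merged
region's true depth. The **strict** inequality means a connection of
persistence exactly $T_p$ survives — `extract_segmentation(h, 3, 0)` on the
flooded profile $[-5, -1, -4]$ keeps two labels, while $T_p = 4$ merges
them.

Because the hierarchy is built once, sweeping $(T_p, T_v)$ is nearly free;
`persistence_curve()` tabulates label counts over a sweep and
`suggest_persistence()` picks the knee (largest second difference of the
smoothed curve). The label count is monotone non-increasing in both
thresholds. Extraction at $(0, 0)$ is the classical watershed: exactly one
label per 26-connected regional minimum plateau.

```{r watershed}
pv <- -generate_profile_1d(c(-5, -4), c(-1))   # distance profile 5, 1, 4
d <- array(pv, c(3, 1, 1))
h <- build_hierarchy(d, array(TRUE, c(3, 1, 1)))
c(split = max(extract_segmentation(h, 3, 0)),
  merged = max(extract_segmentation(h, 4, 0)))
```

* `t_v`: set below the smallest plausible tile volume (in voxels). It
  removes shallow fragments; setting it near the tile volume makes things
  *worse*, because genuine small tiles get absorbed by neighbors.
* `t_p`: sweep it (`persistence_curve()`) rather than guessing; on clean
  data the curve has a knee or plateau at the tile count.

### 5. Proofreading — `build_region_graph()` and the edit operators

`build_region_graph()` gives the region adjacency graph (vertices at label
centroids, edges weighted by face-contact area); `compute_stats()` adds
per-label volume, principal extents, neighbor counts and distances;
`flag_outliers()` ranks labels by robust z-scores (median/MAD, with an
infinite score when the MAD is zero and the value deviates).

All edits conserve the foreground voxel set exactly — `merge_labels()`,
`split_label_watershed()` (local re-watershed of one label using the
distance map), `split_label_spectral()` (Fiedler-vector bisection of the
label's voxel adjacency graph, capped at `cap` voxels), and
`merge_then_split()`, the one-call repair for a missing-pore defect. Every
edit is journaled and `replay_journal()` reproduces the edited field from
the original.

## The phantom, and its limits

`generate_phantom()` builds a synthetic tessellated shell: Poisson-disk
tile seeds on a flat slab (or spherical cap), nearest-seed (Voronoi) tile
assignment, cylindrical pores carved at the fraction of each inter-tile
border not occupied by the mineralized connection (`connection_fraction`),
optional intra-tile holes, plus intensity drift and Gaussian noise. The
truth object carries the label field, one landmark inside each tile, the
neighbor pairs, and the pore mask.

Defaults (`thickness = 3`, `tile_diameter = 12`, `pore_radius = 1.5`,
`connection_fraction = 0.5`, 9.78 µm voxels) reproduce the qualitative
regime of tessellated cartilage at µCT resolution — connections wider than
the shell thickness, tiles much wider than thick — not any particular
specimen's morphometry. The phantom is deliberately idealized: no
beam-hardening, no partial-volume blur beyond the intensity drift, convex
tiles only, constant thickness. Treat quantitative results on the phantom
as a validation of the *algorithms*, not a calibration for real scans.

## Evaluation conventions

* **Landmarks** are 0-based continuous $(x, y, z)$ coordinates; they are
  mapped to voxels by rounding to the **nearest** voxel center
  (`round()`, so 1.4 → voxel 1, 1.6 → voxel 2). A predicted label hit by at
  least one landmark is a true positive; a label hit by $n$ landmarks adds
  $n - 1$ false negatives (an under-segmented cluster needing splits); a
  label with no landmark is a false positive (an over-segmentation fragment
  needing a merge). Landmarks landing on background are reported as
  unassigned and excluded from the counts.
* **Rand index** (`rand_index()`) is reported as a percentage of agreeing
  voxel pairs inside the ROI, computed from the contingency table (equal to
  brute-force pair enumeration, which the tests check on ≤ 500-voxel
  volumes).
* **Variation of information** (`variation_of_information()`) is reported
  in **nats** by default (`units = "bits"` divides by $\ln 2$); the crossed
  4-voxel partition gives exactly $2\ln 2$. Per-label contributions are
  returned so over- and under-segmentation can be localized.
* `compare_2d_vs_3d()` runs the identical pipeline twice — only the
  distance map differs — and returns the precision/recall table over a
  persistence sweep for both variants.

## Problem sizes and budgets

All cores are C++ (Rcpp) with R orchestration, single-threaded:

* The default 128×128×48 phantom with $K = 100$ tiles runs the full
  pipeline plus an 81-point persistence sweep in well under a minute;
  `distance_map_2d` with $n = 1214$, $m = 361$ is the dominant cost and
  scales with the foreground voxel count times $(n + m)$ times the mean ray
  length.
* `distance_map_3d` is an exact $O(N)$ three-pass Euclidean transform
  (Felzenszwalb–Huttenlocher), fine at any size that fits memory.
* Brute-force oracles in the test suite (all-pairs EDT, pair-enumeration
  Rand/VI, exhaustive plateau counting) are kept at ≤ a few thousand
  voxels.
* `split_label_spectral()` builds a dense eigenproblem and is capped
  (default 1500 voxels per label); use the watershed split for big labels.
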