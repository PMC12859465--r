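---
title: "Quantifying osteocyte network integration across remodeling interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying osteocyte network integration across remodeling interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Bone is continuously remodeled in patches. Tissue deposited in different
remodeling cycles is separated by hyper-mineralized cement lines a few
micrometers thick, and the osteocyte lacunar-canalicular network (OLCN) —
ellipsoidal lacunae housing osteocyte cell bodies, connected by ~100-500 nm
canaliculi — must either stop at these interfaces or grow across them. In
phase-retrieved synchrotron nano-CT, voxel gray value (GV) is proportional
to mass density, so it tracks the local degree of mineralization: pores are
darkest, younger (less mineralized) matrix is darker than older matrix, and
cement lines are brightest. `olcn` implements three quantitative analyses
on such volumes, plus a synthetic phantom generator that supplies ground
truth for validating each of them:

1. **Regional mineralization**: per remodeling region, the mean GV of the
   mineral matrix divided by the mean GV of the lacunar interiors of that
   region (the *normalized mean GV*, which cancels low-frequency imaging
   artifacts), and an age ranking (1 = youngest = lowest normalized GV).
2. **Projected canalicular porosity** `pCan.P`: canaliculi segmented in
   minimum-intensity projections, assigned to regions, and pooled as
   `pCan.P = sum_i pCan.V(i) / sum_i pMin.V(i)` over projections `i`.
3. **Interface crossings** `N.Conn`: per candidate lacuna, the number of
   canalicular components of its connected cluster that intersect the
   dilation-minus-original band of the older neighboring region, within
   25 um of the lacuna.

## Conventions

Volumes are arrays in (slice z, row y, column x) order with isotropic voxel
size in nm. Indices are 1-based (idiomatic R); the physical coordinate of
voxel `i` along an axis is `(i-1) * voxel_size`, so physical distances are
always `voxel_size` times Euclidean index distances. Binary morphology uses
exact Euclidean ball (3D) / disk (2D) structuring elements realized through
a separable squared distance transform, so `dilate_ball(m, r)` is exactly
the set of voxels within distance `r` of `m`; "structuring element size"
parameters are therefore radii. Connectivity is 26 in 3D and 8 in 2D
throughout, so diagonal steps do not sever thin tubes. Voxels outside the
grid count as background, which deliberately erodes regions at the volume
faces (edge effects are meant to be excluded).

## Parameters that matter

| key | default | unit | role |
|---|---|---|---|
| `otsu_bins` | 256 | bins | histogram of the observed [min, max]; thresholds work identically for 8/16-bit and float data |
| `opening_radius_vox` | 7 | voxel | ball opening separating lacunae from canaliculi before labeling |
| `lacuna_min_voxels` | 1500 | voxel | lacunar size filter; a component of exactly 1500 voxels is retained |
| `region_erosion_px` | 50 | px | regional-mask erosion removing edge effects and cement lines |
| `b_dilation_px`, `c_erosion_px` | 10, 10 | px | safety margins around the low-intensity mask and inside lacunae |
| `window_slices`, `n_projections` | 130, 15 | slices | minimum-intensity projection windows (6.5 um at 50 nm voxels) |
| `tophat_radius_px` | 10 | px | black top-hat disk radius, comfortably wider than a canaliculus |
| `min_component_px` | 100 | px | 2D noise filter on canalicular components |
| `band_dilation_px` | 3 | px | interface band = dilate(older region) minus older region |
| `radius_um`, `proximity_um` | 25, 25 | um | counting radius and candidate-selection proximity; converted through the voxel size, never hard-coded in voxels |

The pixel-denominated defaults correspond to 50 nm voxels. The desk-scale
phantom configurations (`default_phantom_config` and the internal family
configs) scale them to the phantom voxel size where they encode physical
dimensions (e.g. the 2D noise filter keeps its 0.25 um^2 area, the region
erosion its few-um margin), and shrink the projection windows to the
phantom depth; everything else keeps the standard value.

## Algorithmic choices on genuinely open points

* **Otsu contract.** Threshold maximizing between-class variance over a
  256-bin histogram of the observed range; ties break to the lower
  threshold; "low-intensity" foreground means `value <= threshold`. A
  constant input is an error for volume thresholding but yields an empty
  mask in 2D canalicular segmentation (a featureless projection is valid).
* **Region-mask interpolation.** The dense mask is built from sparse manual
  slice labels by per-region signed-distance maps blended linearly between
  bracketing labeled slices; each voxel takes the region with maximal
  blended value (ties to the lower region id). Labeled slices are
  reproduced exactly; slices outside the labeled range copy the nearest
  labeled slice. Signed distances are capped at a large finite value so a
  region absent from one bracketing slice shrinks instead of producing
  infinities. Equivalence with the original toolchain's interpolation is
  not claimed — only the reproduction and determinism contracts.
* **Projection alignment.** Companion regional projections take, per pixel,
  the label at the argmin slice of the gray window (ties to the first
  slice), so a dark canaliculus pixel inherits the region where its minimum
  lives. Lacunar companions use presence (max label) across the window: a
  pore is dark if any slice holds it.
* **Lacuna priority.** A pixel covered by both the lacunar projection and
  the canalicular mask counts as lacunar. The black top-hat responds only
  inside dark structures narrower than its disk; at the tips of large
  lacunae it produces rim responses that would otherwise be double-counted
  as canaliculi.
* **Dark halo at junctions.** Conversely, the top-hat is structurally blind
  within about one disk radius of a wide dark blob's boundary (the disk
  still fits inside the dark union there), which would systematically
  disconnect canaliculi from their lacuna. When building a lacuna's
  cluster, the footprint is therefore extended by its *dark halo*:
  low-intensity pixels (projection-level Otsu) within the top-hat radius of
  the footprint. Dark pixels on the interface band are canalicular by
  construction, so the halo cannot fabricate crossings.
* **Other lacunae are removed** from a cluster projection before
  connectivity analysis, so a cluster stops at a neighboring lacuna instead
  of absorbing that lacuna's own network; only the target lacuna's
  connections are attributed to it.
* **Counting unit.** Crossings are the 8-connected components of
  cluster-intersect-band: two canaliculi merging before the band count
  once; one canaliculus grazing a wavy band in two disjoint places counts
  twice. The 25 um radius is measured in-plane from the projected lacuna
  surface (minimum pixel distance to the footprint), not from the centroid
  — a centroid rule would penalize large lacunae — and the same 25 um is
  the default proximity for candidate selection, which the source
  procedure leaves unquantified.
* **Statistics.** The group comparison of youngest vs older regional
  porosities uses a two-sample equal-variance Student's t-test (Welch via
  `var_equal = FALSE`), two-sided, with group medians reported alongside;
  describing a comparison of medians assessed by a t-test is internally
  tense, so the implementation tests means and reports medians rather than
  resolving the tension silently. Zero-variance degenerate groups are
  reported as exact separation (infinite statistic, p = 0) or exact
  equality (statistic 0, p = 1) with a flag instead of an error. The
  connection analysis is a Pearson correlation with the usual t-transform
  p-value, two-sided.

## What the phantom emulates — and what it does not

`generate_phantom` rasterizes, in draw order, mineral regions (GV
increasing young to old along y), a sinusoidal cement sheet of constant
thickness and elevated GV (the wave mirrors the groove pattern of aligned
resorption pits), tubular canaliculi (voxels within a radius of a
polyline), and ellipsoidal lacunae; pores overwrite everything; Gaussian
noise is added last and the result is quantized to the 16-bit integer
grid. Ground truth (region labels, lacuna labels, canalicular mask,
per-lacuna crossing counts split at 25 um, analytic porosities) is
computed on the noise-free rasterization, and declared tube topology is
verified at generation: a "crossing" must intersect the cement surface
exactly once, a "loop" or "intra-region" tube never, with clearance beyond
the cement half-thickness plus the tube radius.

Phantom gray levels keep the regional contrast small against the
pore-mineral contrast (default 150/165 vs pores at 60), as in
phase-retrieved data where regional age differences are subtle. This is a
validity condition, not a nicety: the initial Otsu step presumes the
histogram's dominant split is pores vs mineral, and with an unrealistically
sparse network or exaggerated regional contrast the between-class variance
of the *regional* split can win, misclassifying an entire region as
low-intensity. The tube-density phantom therefore defaults to a
low-intensity fraction of ~3%, in the range of real canalicular networks.
`validate_regions_against_gv` is the advisory guard for the related
failure on real data.

The phantom deliberately does not simulate phase-contrast physics,
partial-volume blur, ring or reconstruction artifacts, and it makes no
attempt to match real histograms. Canalicular radii are a free parameter
(literature range ~100-500 nm; fixture values 200-300 nm) because the
source imaging cannot measure them reliably. Consequently, green phantom
tests demonstrate the correctness of the *computational contracts* —
segmentation boundary semantics, mask algebra, counting, statistics — not
robustness to every artifact of real synchrotron data.

Loops are rendered by the generator (U-shaped tubes returning to their
lacuna short of the cement line) and are verified to contribute zero
crossings, but no loop *detector* is provided: identifying loops is a
visual, 3D assessment in the source workflow, not an algorithm.

## Problem sizes

The default validation phantom is 112 x 228 x 160 voxels at 100 nm (11 x
23 x 16 um) — large enough that every stage runs with physically
meaningful margins (regions survive the scaled erosion, four candidate
lacunae with 3/2/1/0 crossings, sub-filter noise blobs) while a full
pipeline run takes well under a minute. Validation families use 10
tube-density phantoms (porosity recovery), 6 (group test) and 8 connection
phantoms at 200 nm voxels whose wide field allows a crossing beyond the
25 um radius. These sizes are the package's validation conditions; the
pipeline itself is agnostic to volume size.

## Known limitations

* Projected porosities are overlay quantities, deliberately not corrected
  to 3D porosity; overlapping canaliculi in a projection are
  under-counted, so values compare regions rather than estimate true pore
  fractions.
* The 2D cluster analysis cannot follow a canaliculus in 3D across the
  cement line; a crossing is an intersection pattern in a projection.
* Lacuna-to-region assignment is a majority vote over mask A; lacunae
  straddling an interface are attributed wholly to one region.
* The Otsu-based masks assume standard contrast (pores dark); inverted
  contrast is the caller's responsibility.
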