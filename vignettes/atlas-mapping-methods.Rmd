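---
title: "Mapping micropopulation tracing sections into a common reference space: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping micropopulation tracing sections into a common reference space: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropop)
```

## The problem and the model

Microiontophoretic tracer injections label compact populations of tens of
thalamic projection neurons. The observable data are serial coronal
sections: per section, a grayscale image and — after pixel classification
— a 3-label map (axon / background / soma). Two registration products are
made interactively upstream and consumed here as files:

1. **Linear anchoring.** Each section is placed as a plane in the 10 µm
   reference volume by three vectors in voxel units: `o`, the position of
   the image's top-left pixel; `u`, spanning the full image width; `v`,
   spanning the full height. Pixel `p = (p_x, p_y)` (x rightward, y
   downward from the top-left corner) maps to
   `C(p) = o + (p_x / w)·u + (p_y / h)·v`. This normalization by the full
   image width/height is the package's fixed contract; anchors are tied to
   the downsampled geometry they were produced for, and segmented images
   must share that geometry exactly.
2. **Nonlinear refinement.** Marker pairs `(section point, template
   point)` in the section's pixel frame. The package builds a warp
   *directly in the section→template direction* — the inversion that lets
   a cleaned segmented image be pushed straight into the reference volume
   instead of rendering the template onto the section. The interpolant is
   piecewise-affine over a Delaunay triangulation of the marker section
   points with the four image corners added as fixed points: the minimal
   continuous interpolant that is exact at every marker, the identity with
   zero markers, and affine within each triangle. The upstream GUI does
   not document its own interpolant, so equivalence is asserted for this
   package's file dialects only, not byte-compatibility with GUI
   renderings.

Axis semantics throughout: x anterior→posterior, y superior→inferior,
z left→right; the full-scale grid is 1320 × 800 × 1140 voxels at 10 µm
with the origin at the anterior-superior-left corner. Voxel indices are
0-based and each voxel is the half-open cube `[i, i+1)` per axis, so
continuous coordinates are binned by `floor()`. Mirroring to the left
hemisphere is the reflection `z → n_z − 1 − z`, an involution that keeps
indices in bounds; "left" is `z < n_z / 2` because the origin sits at the
left corner.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| pixel budget | 15·10⁶ | px | the anchoring tools require inputs under 16 Mpx; the factor `n = max over sections of ceiling(sqrt(h·w/15·10⁶))`, floored at 1, is shared by the whole series so all sections land at one resolution |
| `min_object_px` | 12 | px | objects with fewer than 12 pixels are false positives of the pixel classifier |
| neighbour rule | squared distance ≤ 3 | voxel²/px² | "up to 3 orthogonal steps, judged by squared Euclidean distance"; in 2D this admits diagonals (distance² = 2) and excludes straight 2-px jumps (distance² = 4), i.e. 8-connectivity |
| `radius_factor` | 1.5 | — | the membership ball around the population medoid is 1.5 × the maximum medoid–soma distance, compensating incomplete sampling of the population by the tracer |
| section thickness | 50 | µm | sections are anchored as single planes; counts are **not** spread across neighbouring 10 µm planes, and inter-section gaps remain unfilled (spatial interpolation is out of scope) |
| coverage threshold | > 0 | px counts | a flat pixel counts as covered as soon as any axon pixel projects onto it; configurable |

Choices that were genuinely open, and how they were fixed:

* **Ceiling vs floor of the downsampling factor.** The per-image factor is
  the *ceiling* of `sqrt(h·w / 15·10⁶)`: the only reading that guarantees
  the 16 Mpx bound, and consistent with a series needing factors 4 and 5
  being downsampled at 1-of-5 throughout. Subsampling keeps pixel (0, 0)
  (phase 0) for reproducibility.
* **Summation across sections.** When two sections hit the same voxel,
  counts are summed — the reading consistent with "count the segmented
  pixels registered to a voxel".
* **Joint cleaning.** Components are found over axon and soma pixels
  together, then surviving pixels keep their original labels, because one
  size rule governs both label classes.
* **Out-of-rectangle warps.** Warped points leaving the image rectangle
  are clamped and counted rather than dropped, preserving the
  pixel-conservation ledger (`Σ voxel counts + out-of-volume pixels =
  Σ segmented pixels` at every stage).
* **Medoid weighting.** The medoid minimizes the *count-weighted* sum of
  distances by default (every segmented pixel votes); an unweighted
  variant over unique voxels is available by flag.
* **Membership ball closed.** A soma exactly at the radius is a member
  ("within this radius" read inclusively).
* **Overlap denominator.** Figure captions in this literature mix
  "percentage of targeted points" with "normalized by all points within
  the area"; the default normalizes by targeted in-area points (the three
  states then sum to 1), and `denominator = "area"` reproduces the
  all-points reading.
* **Parcellation for quantitative results.** ARA-style by default,
  configurable; swapping in an alternative parcellation (EUAL-style)
  changes only annotation and hierarchy, never grid geometry.
* **Layer groupings.** Distributions are computed over the six hierarchy
  layer tags {1, 2/3, 4, 5, 6a, 6b}; coarser groupings ("5 or 6") are sums
  of bins downstream.
* **Flat intensity vs projections.** Flatmap intensity *sums* counts over
  cortical depth (it reports numbers of detected axonal segments), while
  subcortical views take the *maximum* along the projection axis (they are
  maximum-projection plots). Both are stated explicitly because they
  differ.
* **SWC terminals.** Axon terminal points are leaf nodes of axon-typed
  (type 2) subtrees — the endpoints of terminal branches. A branch-order
  criterion would be an alternative; leaves were chosen as the
  assumption-free reading.

## Numerical choices

Triangulation uses Bowyer–Watson insertion with a strict in-circumcircle
predicate (tolerance scaled to the fourth power of the image span);
cocircular configurations such as the four image corners receive an
arbitrary but valid diagonal, which is immaterial because any
triangulation of the same point set yields a continuous exact
interpolant. Warp evaluation assigns each query point to the first
triangle whose barycentric coordinates are ≥ −10⁻⁹; points that fall
through numerically (on hull edges) use the nearest triangle's affine
map. Contradictory markers — one section point sent to two template
points — are a hard error. Ties in dominant-population and
nearest-experiment selection break lexicographically on experiment id.
Degenerate inputs are defined, not fatal: empty segmentations produce
empty clouds, a zero in-area axon count yields a zero layer table with a
warning, and an all-background image survives cleaning unchanged.
Anchoring scalars serialize with 17 significant digits so write/read
round-trips are bit-faithful.

## What the synthetic generator emulates — and what it does not

`make_reference_space()` builds a miniature (default 132 × 80 × 114,
1/10 linear scale) annotation/template pair with the same axis semantics
as the full-scale volume: a cortical shell of areas with six layer bands,
a "VPM"-role nucleus with a "PO" neighbour, and optional left-right
symmetry. `make_experiment()` plants a soma disk inside the nucleus and
laminar axon blobs (default 40/30/20/10 across layers 4, 2/3, 5, 6a),
renders raw 3-label section images whose pixels map onto the planted
voxels through the emitted anchoring and warp, and adds 1–11 px decoy
objects that straddle the cleaning threshold. `make_morphologies()`
places member somata strictly inside and non-members strictly outside the
membership ball. All generators are pure functions of their parameters
and seed.

The fixtures exercise every code path — file dialects, warps, cleaning,
voxelization, curation, analytics, integration — with exact known
answers. They do **not** emulate stain variability, classifier errors
beyond isolated decoys, anchoring errors (the emitted anchoring is
correct by construction), section-to-section misalignment, or realistic
axon morphology. Passing tests therefore demonstrate correctness of the
computational pipeline, not robustness to imperfect upstream registration
or segmentation — those errors enter through the interactive tools and
the classifier, both outside this package.

Problem sizes used by the test and acceptance suites — ten sections of
228 × 160 px per synthetic experiment, clouds up to 500 voxels for
exhaustive-oracle comparisons, 50 random images for the flood-fill
oracle, 1000 points for the warp oracle — were chosen as the smallest
sizes that still cover every geometric regime (multiple triangles,
hemisphere boundaries, threshold boundaries).

## Known limitations

* Inter-section gaps are not interpolated; registered clouds are sparse
  along the anterior-posterior axis by exactly the sectioning interval.
* Automatic registration, interactive anchoring and classifier training
  are out of scope by design; the pipeline validates the presence and
  consistency of anchoring files at an explicit pause point instead of
  invoking the external tools.
* Subcortical nuclei are visualized as maximum projections, not flatmaps
  (no accepted barreloid-resolved parcellation exists to unfold them).
* The dense flat-lookup array representation is sized for fixture-scale
  and 10 µm single-hemisphere use; a full-scale lookup would be held on
  disk (HDF5/NRRD) and windowed.

## Worked check

```{r}
space <- make_reference_space(seed = 42)
study <- make_experiment(space, seed = 7)
increments <- lapply(study$sections, function(sec) {
  seg <- clean_small_objects(recode_labels(sec$raw))
  warp <- build_warp(sec$markers, c(sec$anchor$width_px, sec$anchor$height_px))
  voxelize_section(seg, sec$anchor, warp, space)
})
record <- assemble_experiment(increments, "exp1")
record <- curate_injection_volume(record, space, nucleus_acronym = "VPM")
layer_distribution(record, space, area_acronym = "CTX-A1")
```

The recovered laminar percentages equal the generator's planted
40/30/20/10 profile exactly, as asserted by the test suite.
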