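---
title: "Segmenting root systems in undisturbed soil CT volumes: methods and design"
author: "rootct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting root systems in undisturbed soil CT volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

X-ray computed tomography resolves plant roots inside intact soil, but
turning a reconstructed gray-value volume into a root mask is the
bottleneck. Undisturbed field cores are particularly hard: they contain
cut, unconnected root segments from several plants, organic debris whose
gray values mimic roots, inhomogeneous moisture, and — most importantly —
*mixed voxels*. At every interface between a mineral aggregate and an
air-filled pore, partial-volume averaging produces voxels whose gray
value lies between the air and mineral modes, squarely in the range where
roots live. A single global threshold therefore cannot separate roots
from soil, and tracking approaches that assume one connected root system
fail on multi-plant cores.

`rootct` implements a five-step protocol that works by *elimination*
rather than by tracking: segment what is certainly mineral, inflate it
slightly so the mixed-voxel shell goes with it, subtract it, and only
then look for roots in the remaining pore space. Because no connectivity
assumption is made, unconnected root segments are recovered as readily as
a single intact system. A size filter removes what remains of debris and
noise.

## The five steps

1. **Mineral surface determination.** Operator-supplied example areas of
   air and mineral define an initial ISO-50 threshold (the midpoint of
   the two class means). The resulting surface is then refined locally:
   for every boundary voxel the smoothed gray profile is sampled along
   the local gradient direction, and the boundary is relocated to the
   gradient-magnitude maximum — the inflection point of a blurred edge.
   The classification of a voxel thus depends on its neighborhood, not
   only on its own gray value, which makes the result robust to a biased
   global threshold (we verify recovery from biases up to the search
   half-width of 3 voxels).
2. **Dilation.** The mineral ROI is dilated by a sub-voxel radius
   (default 1, sensible range 0.5–1) to absorb the mixed-voxel shell at
   aggregate–pore borders. Distances are measured to the mask *surface*
   taken half a voxel beyond foreground centers, so a radius of 0.5
   captures exactly the face-adjacent shell and a radius of 1 also the
   edge-adjacent voxels.
3. **Subtraction.** The dilated mineral ROI is subtracted from a
   whole-volume ROI (the grid minus a one-voxel frame, since frame voxels
   lack the neighborhoods needed for refinement). Only roots and pores
   filled with air and water remain; water is not distinguished from air.
4. **Root surface determination.** Step 1 is repeated inside the reduced
   domain with air/root example areas. Gradient profiles truncate at the
   domain edge, so mineral gray values never influence the root surface.
5. **Size filtering.** Connected components (26-connectivity by default,
   because roots a few voxels wide connect diagonally) smaller than
   10,000 voxels are deleted; a component of exactly the threshold size
   survives. The threshold is resolution-dependent and deliberately not
   rescaled with voxel size.

The pipeline is deterministic: identical volume and parameters give a
bit-identical mask.

### Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `dilationRadius` | 1 | voxels | width of the mixed-voxel shell removed with the minerals |
| `minComponentVoxels` | 10000 | voxels | noise/debris deletion threshold |
| `connectivity` | 26 | — | component neighborhood |
| `searchDistance` | 3 | voxels | half-width of the gradient search window |
| `smoothingSigma` | 1.0 | voxels | pre-smoothing for gradient estimation |

## Root diameters

Root thickness is computed as *local thickness* in the inscribed-sphere
sense: the diameter at a voxel is that of the largest sphere fully
contained in the mask that covers the voxel. The inscribed radius at a
candidate center is its Euclidean distance to the nearest background
voxel center minus half a voxel; a sphere covers a voxel when it overlaps
the voxel cube (center distance ≤ r + 0.5). Without the voxel-extent
term the maximal sphere of a digital tube never reaches the outermost
surface ring, which would split the surface histogram of a perfect
cylinder across several bins. Commercial wall-thickness tools use
proprietary ray-casting with tunable search angles; the inscribed-sphere
definition is deterministic, standard in porous-media imaging, and
coincides with ray methods on tubular structures, so no search-angle
parameter is exposed.

The diameter *distribution* is taken over surface elements — the boundary
voxels of the mask — with one-voxel-wide bins by default. `fineRootFraction`
sums the frequency below a cutoff (0.25 mm by convention), apportioning a
straddling bin linearly.

## The region-growing baseline

`regionGrow` is a 26-connected flood fill within a gray tolerance,
optionally adaptive (the reference is the running mean of accepted
voxels) and optionally restricted to a 3D search box, with explicit
accumulation across interactive steps. Two structural properties are
worth stating plainly:

* Flood fill cannot cross a pore gap, so a second, unconnected root is
  never recovered from seeds in the first — the core limitation the
  protocol avoids.
* In densely aggregated soil the partial-volume band around the
  aggregate-surface network *percolates*: at mineral fill ≈ 0.3 and
  above (blur sigma 1), any tolerance wide enough to cover the root
  interior also admits a thin connected band along aggregate surfaces,
  and unrestricted growth floods the whole sample. This is exactly why
  the interactive workflow needs per-step search-area restriction and
  tolerance adjustment. Our unconnectedness tests therefore use a
  low-aggregate phantom (fill 0.2, verified non-percolating), where the
  gap-crossing claim is testable without a search box.

## The phantom generator

`generatePhantom` builds the validation world: tapering tubes along
random-walk centerlines for roots (rasterized by a 3× supersampled
coverage test — a voxel is truth-foreground when at least half its
sub-samples fall inside the tube), overlapping random ellipsoids for
mineral aggregates up to a target fill fraction, small root-gray blobs
for organic debris (kept below the size-filter threshold, so the filter
is the mechanism under test), per-voxel Gaussian class noise, Gaussian
partial-volume blur, and optionally a container wall and a linear
moisture drift of the pore gray values. Gray means default to
air 5000 < root 18000 < mineral 45000 (PVC-like wall 43000) on the
16-bit scale, respecting the ordering seen in soil reconstructions and
the near-identity of PVC and mineral grays that makes PVC pots
convenient. Truth masks come from the pre-noise rasterization and are
pairwise disjoint.

One geometric choice deserves emphasis: aggregates keep a *rhizosphere
clearance* of 1.5 voxels around roots (`rootClearanceVoxels`). Field
roots predominantly grow through pores and biopores and carry a water
film; modelling flush mineral–root contact over half the root surface
would be unrealistic and would make the contact shell unrecoverable by
construction (the dilation of step 2 must eat it). Setting the clearance
to 0 restores flush contact for stress-testing.

What the phantoms do *not* emulate: physically based projection and
reconstruction (beam hardening beyond an optional drift, ring artifacts,
detector noise correlation), anisotropic voxels, root branching
hierarchies with realistic angles, and water menisci in pores. Passing
on phantoms therefore demonstrates the correctness of the protocol's
mechanics under controlled partial-volume and clutter conditions, not
performance on any particular scanner's data.

## Problem sizes and numerical choices

The validation suite runs the full protocol on a 256³ reference phantom
(three unconnected roots, twenty debris blobs, fill 0.5, blur 1.0), a
ten-phantom 192³ series for the volume-recovery regression, and smaller
phantoms for the mixed-voxel and unconnectedness contrasts; these sizes
keep a complete run in the tens of minutes on a single CPU while leaving
root radii (6–12 voxels) well above the resolution limit. Further
conventions: axis order is (slice, row, column) with 1-based coordinates
in the R API; gradient-profile ties resolve to the position closest to
the initial boundary; sub-voxel refinement uses a three-point parabolic
fit rounded back to the voxel grid; voxels with numerically zero
gradient keep their initial classification; distances use the exact
Euclidean transform. Float ingest clips 0.05% per tail by default before
the linear map to 16 bits, protecting against isolated reconstruction
outliers; the mapping of the original software is not documented, so
this is our choice.

## Known limitations

* Roots in flush contact with minerals (no pore clearance) lose their
  contact shell to step 2; this is inherent to the elimination strategy.
* Organic debris larger than the size threshold, or touching a root, is
  not removed; geometric shape filters are out of scope.
* The surface histogram counts boundary voxels, not area-weighted mesh
  elements; strongly anisotropic surfaces would be biased.
* Thresholds derive from example areas; no automatic histogram
  decomposition is attempted.
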