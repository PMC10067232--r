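---
title: "Patient-specific plate templating: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific plate templating: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateforge)
```

## The problem

Anterior pelvic ring fractures are commonly fixed with reconstruction
plates — metal plates with regularly spaced screw holes that must be bent to
follow the bone's curvature. Bending the plate against a full-size 3-D
printed pelvis is accurate but slow and expensive to print; bending it
against a small printed *plate template* — a replica of just the intended
plate shape — is far faster, provided the template can be derived reliably
from the patient's CT. `plateforge` implements that derivation as a
deterministic pipeline:

1. **Segmentation** — threshold the CT volume into bone, split connected
   fragments, erase irrelevant structures (e.g. femurs), and extract a
   triangulated surface per fragment.
2. **Virtual reduction** — mirror the intact hemipelvis across the
   mid-sagittal plane as a target, and rigidly reposition displaced
   fragments by landmark correspondence (Kabsch) into an anatomically
   reduced model.
3. **Path planning** — from an ordered series of operator-selected surface
   points, build a smooth on-surface path, bridge residual fracture gaps
   with straight chords (the *wrap* function), and match the path length to
   a whole number of plate units (the *mid-line* rule).
4. **Template generation** — pose one parametric plate unit per station with
   its profile parallel to the bone surface, push units outward where they
   would penetrate bone, and export the chained units as a print-ready STL.

Everything is millimetres; volumes use the LPS patient frame of CT.

## Models and algorithms

### Isosurface extraction

A fragment's surface is the 0.5-isosurface of its binary label indicator.
Two numerical facts shaped the implementation:

* Marching on a *hard* 0/1 indicator places every surface vertex at an edge
  midpoint, producing a staircase surface whose area systematically
  overestimates the true area — about 8.5 % for a sphere at 0.5 mm isotropic
  voxels and about 19 % at the CT-like spacing (0.8, 0.8, 3.0) mm. No
  resolution increase fixes this; it is an orientation-averaged bias.
  `extract_surface()` therefore (a) anti-aliases the indicator with a small
  Gaussian (`anti_alias_sigma`, default 1 mm) so iso-crossings interpolate
  sub-voxel positions, and (b) relaxes the mesh with Taubin smoothing
  (10 passes of \(\lambda = 0.5\), \(\mu = -0.53\)), which removes the
  residual staircase without the volume shrinkage of plain Laplacian
  smoothing. With these defaults, sphere-phantom surface area is within
  ~2.5 % and enclosed volume within ~3.5 % of analytic at both spacings.
  Setting both parameters to zero recovers the raw midpoint isosurface.
* The cell polygonization is **marching tetrahedra** on the Freudenthal
  six-tetrahedron decomposition of each cell. Unlike classic marching
  cubes it has no ambiguous cases and needs no 256-entry lookup table; the
  decomposition is conforming across cells, so the output is watertight by
  construction, and each triangle is wound outward at emission time.

### Clearance and the anti-penetration threshold

The safety property of the whole system is that the template never
penetrates the bone: `min_clearance(template, bone)` must stay at or above a
`clearance_threshold` (default 0.2 mm; the unit's nominal `standoff` from
bone is 0.5 mm). Clearance between meshes is measured as an exact
triangle–triangle intersection test (any intersection means zero) followed
by point-to-triangle distances from deterministic surface samples. Inside
`resolve_penetration()` the estimate is deliberately *symmetric*: distances
are taken both from unit-surface samples to the bone and from nearby bone
vertices to the unit. The second direction is exact for the piecewise-planar
unit and catches bone spikes that slip between unit samples — without it, a
sampled clearance can overestimate the true one by half the sample spacing.
Units that violate the threshold are translated along the surface normal by
the smallest sufficient offset, found by bisection to 1e-3 mm; orientation
is never changed, preserving the parallel-to-surface alignment.

### Frames along the path

Unit *i* of *n* sits at arc length \((i - 0.5)\,L\). Its tangent is the
local central difference of the path; its normal is the bone's smooth
surface normal at the closest surface point — barycentric interpolation of
area-weighted vertex normals, not the raw face normal, because a face
normal tilts by half the tessellation step (measured 5.6° on a 1.5 mm
torus mesh, versus the 2° alignment requirement). Normals are sign-matched
to the previous frame to prevent flips, Gram–Schmidt-orthogonalized against
the tangent, and completed right-handed (\(b = t \times n\)). Across bridge
stations (off-bone chords) the normal is linearly interpolated between the
bounding on-surface frames.

### The mid-line rule

With path length \(S\) and unit length \(L\), the residual \(r = S \bmod L\)
is compared with the unit mid-line \(L/2\): if \(r < L/2\) the path is
cropped to \(\lfloor S/L \rfloor\) units, otherwise it is lengthened
tangentially (re-projected onto bone where possible) to
\(\lceil S/L \rceil\) units. Interpretations fixed here: "mid-line" is read
as half the unit length (the transverse mid-line through the screw hole);
the tie \(r = L/2\) exactly rounds *up*, because lengthening never truncates
coverage of the fracture; and a path shorter than \(L/2\) still yields one
unit. The adjusted length equals `unit_count * L` to 1e-6 mm.

### Path construction

The operator's anchor points are projected to the surface, joined by a
uniform interpolating Catmull–Rom spline (interpolation — rather than
approximation — honors the surgeon's chosen points), sampled at
`sample_spacing` (0.5 mm), re-projected, and relaxed by endpoint-fixed
Laplacian smoothing with re-projection after each pass. Anchors are *soft*:
they may drift up to `2 * sample_spacing` during smoothing. Samples farther
than `wrap_distance` (5 mm) from the bone are left off-surface and flagged;
`wrap_path()` replaces each maximal off-surface run with a straight chord
between its bounding on-surface samples. A path whose entire inter-anchor
span is off-surface is rejected with a pointer to the reduction step. The
whole module is free of randomness: identical inputs give bit-identical
paths.

### Virtual reduction

"Manual repositioning" is realized non-interactively as landmark-pair
alignment: the least-squares rigid transform by SVD of the cross-covariance
with reflection correction (Kabsch). Collinear landmark sets are rejected.
An ICP refinement (`icp_refine()`) exists for sparse landmarks but is off by
default so the pipeline stays deterministic. The mirror plane defaults to
the mesh centroid's sagittal plane (`midsagittal_plane()`) and is always
overridable, since no canonical definition exists for a fractured pelvis.

## Tunable parameters

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `sample_spacing` | 0.5 | mm | path sampling step |
| `smoothing_lambda` / `smoothing_iterations` | 0.5 / 10 | — | Laplacian path relaxation (0 disables) |
| `wrap_distance` | 5.0 | mm | gap distance that triggers bridging |
| `projection_tolerance` | 0.1 | mm | "on surface" certification distance |
| `unit_length` × `width` × `thickness` | 12 × 10 × 2.8 | mm | plate unit block |
| `hole_diameter` / `hole_segments` | 3.6 / 32 | mm / — | screw hole |
| `standoff` | 0.5 | mm | nominal plate–bone gap |
| `clearance_threshold` | 0.2 | mm | minimum allowed plate–bone distance |
| `anti_alias_sigma` / `smooth_iterations` | 1.0 / 10 | mm / — | extraction smoothing |
| voxel `spacing` | (0.8, 0.8, 3.0) | mm | CT-emulating phantom grid |
| bone / background HU | 1200 / −100 | HU | phantom intensities |

The unit catalog ships four entries named for the vendor families that a
clinical unit library would contain; **their dimensions are repository
defaults emulating a generic 3.5 mm pelvic reconstruction plate, not vendor
data**. The anti-penetration threshold's magnitude (0.2 mm) is likewise a
repository default: the source system names such a threshold but not its
value.

## What the synthetic phantoms do and do not establish

`make_phantom()` generates spheres, torus segments, swept elliptical tubes
(a superior-pubic-ramus *analog*: 15 × 12 mm section swept along a 60 mm
arc) and open flat grids; `voxelize_phantom()` renders them into
two-intensity volumes at CT-like spacing; `fracture_phantom()` cuts them
with a plane and displaces one fragment by a known rigid transform. All
ground truth is exact and all randomness flows through explicit seeds, so
segmentation accuracy, reduction recovery, path behaviour and the
no-penetration property are verifiable to tight tolerances.

What a green test therefore establishes: geometric and algorithmic
correctness on smooth, noise-free, two-intensity anatomy analogs. What it
does not establish: behaviour on real CT (beam hardening, noise, partial
volume at thin cortical bone, metal artifacts), on anatomically realistic
pelvis geometry (the swept tube has no foramina, crests or symphysis), or
the clinical quality of any particular anchor-point selection. Fan-capped
fracture cross-sections assume near-convex cuts, which holds for the
shipped phantoms but not for arbitrary geometry.

## Numerical choices and degenerate inputs

* STL vertices deduplicate by *exact* coordinate equality (deterministic
  topology); `weld()` exists for tolerance merging. Binary STL round-trips
  are bit-exact (float32); ASCII is written at `%.17g` for the same
  property at double precision.
* Closest-point ties at shared edges/vertices resolve to the lowest face
  index; the spatial acceleration (per-triangle bounding-box rejection in
  the C++ kernel) is contractually equivalent to the exhaustive scan, and
  tested to be.
* Threshold bounds are inclusive at both ends, so windows behave
  deterministically at exact HU values; foreground connectivity defaults to
  26 so fragments touching only at corners across 3 mm slices are not
  over-split.
* Zero-area facets are written to STL with a zero normal and a warning;
  empty solids read back as empty meshes with a warning.
* Bisection tolerance for penetration resolution is 1e-3 mm with an upper
  bound of twice the unit diagonal; exceeding it is an error naming the
  station (pathological geometry), not a silent clamp.

## Known limitations

* Volume ingest is NRRD-only; DICOM series and NIfTI must be converted
  externally. (No DICOM/NIfTI reader exists in the supported dependency
  set, and the phantom generator — the package's only in-repo data source —
  writes NRRD.)
* Units are posed independently and concatenated, not hinged or
  Boolean-unioned; FDM slicers handle the overlapping shells, and inter-unit
  bend angles are recorded in the export sidecar so the surgeon can check
  that bends fall between screw holes, but the package does not enforce it.
* No geodesic (shortest-path-on-mesh) computation: the path is the
  projected, smoothed spline through the operator's points, which is one
  consistent realization of an "optimal path" rather than a variational
  optimum.
* No simulation of the physical plate bending, screw trajectories, fixation
  mechanics, or printer slicing.
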