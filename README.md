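# plateforge

Patient-specific reconstruction-plate **template** design from CT-derived
bone surfaces, in R.

Pre-bending a pelvic reconstruction plate against a full-size 3-D printed
pelvis is accurate but slow and expensive. A far faster route is to print
only a *plate template* — a small replica of the intended plate shape — and
bend the metal plate against that. `plateforge` computes such templates:
starting from a volumetric image (or a synthetic phantom), it segments bone,
virtually reduces the fracture, builds a smooth on-surface path through an
ordered series of operator-selected surface points, matches the path length
to a whole number of plate units, poses one parametric screw-hole unit per
station with its profile parallel to the bone surface — guaranteed not to
penetrate it — and exports the chained units as a print-ready binary STL.
Everything is deterministic and in millimetres.

## The core procedure

For a bone surface mesh \(M\) and ordered anchor points \(p_1,\dots,p_m\):

1. **Path**: project anchors onto \(M\); interpolate with a Catmull–Rom
   spline sampled at 0.5 mm; re-project and relax with endpoint-fixed
   Laplacian smoothing. Runs farther than `wrap_distance` (5 mm) from the
   bone — residual fracture gaps — are bridged by straight chords (*wrap*).
2. **Mid-line rule**: with path length \(S\) and unit length \(L\), let
   \(r = S \bmod L\). If \(r < L/2\) crop to \(\lfloor S/L\rfloor\) units;
   if \(r \ge L/2\) lengthen tangentially to \(\lceil S/L\rceil\) units,
   so the adjusted length is exactly a whole number of units.
3. **Frames**: unit \(i\) sits at arc length \((i-\tfrac12)L\) with tangent
   from the path, normal from the smooth surface normal at its contact
   point (sign-matched to the previous unit to prevent flips), binormal
   \(b = t \times n\).
4. **Anti-penetration**: each unit is placed with its underside at
   `standoff` (0.5 mm) along the normal; if its clearance to the bone falls
   below `clearance_threshold` (0.2 mm), it is translated outward along the
   normal by the smallest sufficient offset (bisection to 1e-3 mm). The
   assembled template satisfies
   `min_clearance(template, bone) >= clearance_threshold` by construction,
   verified independently in the test suite.

Upstream, segmentation is inclusive-bound HU thresholding, 26-connected
component splitting, label erasure, and watertight isosurface extraction
(marching tetrahedra with anti-aliasing and Taubin smoothing — see the
vignette for why raw binary marching overestimates surface area by up to
19 % at CT spacing). Virtual reduction provides plane mirroring and
landmark-based rigid alignment (Kabsch, SVD with reflection correction).
A synthetic module generates spheres, tori, swept elliptical tubes
(superior-pubic-ramus analog), CT-like two-intensity voxel phantoms, and
plane-cut fractures displaced by known rigid transforms, so the entire
pipeline is testable without patient data.

## Worked example

Synthetic end to end: ramus-analog phantom → CT-like volume → segmentation
→ surface → 8 noisy "surgeon clicks" along the outer crest → template.

```r
library(plateforge)

bone_mesh <- make_phantom("swept_tube", resolution = 1.5)
vol <- voxelize_phantom(bone_mesh)          # 0.8 x 0.8 x 3.0 mm CT analog
vol
#> <voxel_volume> 133 x 91 x 10, spacing (0.8, 0.8, 3) mm

comps <- split_components(threshold_segment(vol, low = 300))
bone <- extract_surface(comps, 1)
bone
#> <surface_mesh> 26838 vertices, 53672 faces
#>   bbox [-33.06, 67.08] x [-0.04, 67.23] x [-6.00, 6.00] mm

crest <- function(t) { a <- t * 120 * pi / 180
                       c(67.5 * cos(a), 67.5 * sin(a), 0) }
anchors <- sample_anchors(crest, 8, noise_sd = 0.5, seed = 7)
path <- build_path(bone, project_anchors(bone, anchors))
path
#> <surface_path> 282 samples, 139.61 mm, 0 bridge sample(s)

ml <- match_length(path, unit_length = 12, bone)
ml$unit_count                    # 139.61 mod 12 = 7.61 >= 6 -> lengthen
#> [1] 12
arc_length(ml$adjusted_path)
#> [1] 144

frames <- compute_frames(ml$adjusted_path, bone, ml$unit_count, 12)
tpl <- assemble_template(frames, plate_unit_spec(), bone)
tpl
#> <plate_template> 12 unit(s) of 'generic', min station clearance 0.200 mm

export_template(tpl, "template.stl")       # + template.json sidecar
```

Reading the numbers: the 139.61 mm path has residual 7.61 mm past the 11th
unit — more than half a 12 mm unit — so the path is *lengthened* to
12 × 12 = 144 mm (the mid-line rule). Every unit's station clearance is at
least 0.200 mm, the anti-penetration threshold; units needing more room
(e.g. over ridges) are pushed outward along their surface normal, never
tilted. The STL is printable directly; the JSON sidecar records frames,
offsets, clearances, screw axes and inter-unit bend angles.

A command-line launcher is in `inst/cli/plateforge`
(`segment`, `plan-plate`, `make-phantom`, `run` subcommands; JSON config;
manifest with md5 hashes written next to the outputs).

## Units and conventions

Millimetres everywhere (STL carries no units; DICOM spacing is mm). Patient
LPS frame. The shipped unit catalog's four entries are named for vendor
families but carry **repository-default dimensions** (a generic 3.5 mm
pelvic reconstruction plate: 12 × 10 × 2.8 mm, 3.6 mm hole), not vendor
data.
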