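---
title: "Reconstructing microground specimens: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing microground specimens: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgrindr)
```

## The measurement process being modelled

Serial microgrinding reconstructs 3D anatomy from a resin-embedded specimen
by repeatedly grinding a thin layer off the block face, surface-staining the
freshly exposed plane, and photographing it. The method resolves both hard
and soft tissue — bone, cartilage, vessels, mucosa — where micro-CT only
separates calcified from non-calcified material; its price is that every
analysed plane is destroyed by the next grinding run, so all 3D structure
must be recovered from the photograph stack plus a small amount of metadata:

* three vertical wooden sticks drilled into the resin before grinding, whose
  circular cross-sections appear in every image (fiducial marks A, B, C);
* per run, the remaining specimen thickness measured with a digital caliper
  at three positions next to the marks, quantized to 1 um.

Because the grinding machine can sit slightly skewed, the removed layer is
generally a *wedge*, not a slab: in the middle-ear application that
motivates this package the abrasion per run is about 35 um near the
ossicles and up to about 94 um in the periphery. The three thickness
readings determine each cut plane exactly, including this inclination,
which is why the package treats every slice as a full 3D plane
`z(x, y) = g_x x + g_y y + c` rather than a constant height.

Throughout the package: coordinates are right-handed in micrometres, `z` is
depth ground away (zero at the first-run surface), and pixel/voxel centres
sit at `(i - 0.5) * size`.

## Pose recovery

`plane_from_abrasion()` solves the exact 3x3 linear system
`z(anchor_i) = depth - thickness_i`. This is interpolation, not regression:
with three unknowns and three readings the residual at the anchors is zero
by construction, and the caliper's 1 um quantization is the dominant error
(±0.5 um at the anchors). A non-monotone mean plane height across runs is a
hard error — it can only arise from mislabeled or corrupted inputs.

`detect_fiducials()` classifies pixels against the stain colour model,
keeps disk-like connected components of plausible area, and estimates each
centre by an algebraic circle fit through the 0.5-level contour of the
fiducial class posterior. The sub-pixel information lives in the one-pixel
partial-volume ramp at the disk edge (a camera pixel integrates light over
its footprint); the 0.5 crossing of that ramp tracks the true circle, so
the fit is unbiased to well below 0.1 px in practice. Labels A/B/C are
assigned purely geometrically (A = lowest `x*1e6 + y`, then
counter-clockwise), because on real photographs the sticks are
indistinguishable by colour.

`estimate_inplane_transform()` is a closed-form 2D Procrustes similarity
over the three point pairs. Scale estimation is on by default and clamped
to ±2 %: photography distance may drift between runs, but a larger apparent
scale change indicates a problem, and an unclamped three-point similarity
will happily absorb detection errors into scale. A fit requiring a
reflection is always an error — a ground surface cannot be mirrored. The
RMS residual is reported even though three points fit exactly up to noise;
a drifting residual is the cheapest alarm for a wobbling stick.

## Segmentation

The stain model is a per-class Gaussian in RGB (means and covariances,
0-255 scale). The default palette mimics a Mann-Dominici-type surface
stain: eosinophilic pink/orange bone matrix, metachromatic violet
cartilage, dark red vessel lumina, blue soft tissue, pale amber resin,
brown wood. `fit_stain_model()` estimates these from labelled sample pixels
(>= 50 per class, covariance ridge 0.25) and warns when two class means are
closer than 20 intensity units.

`classify_pixels()` takes the per-pixel maximum-likelihood class and then
applies a majority filter (default radius 1 px). The filter suppresses
salt-and-pepper noise at the cost of biasing the apparent width of
structures thinner than about two pixels — relevant for the thinnest
vessels, and the reason the filter radius is an exposed parameter.
Likelihood ties break to the lowest class code in the documented order
(resin, bone, cartilage, vessel, soft tissue, fiducial).

Uncoloured epoxy lets structures just below the surface shimmer through.
The simulator models this with an exponentially attenuated blend
(opacity 0.35 at the surface, attenuation length 60 um, probed to 150 um);
the classifier deliberately assigns such pixels to the *surface* class
(resin) — a blend weight below one half keeps them on the resin side of the
maximum-likelihood boundary — and exposes them separately as the
`deep_evidence` attribute instead of attempting any 3D deconvolution.

`extract_contours()` traces sub-pixel iso-contours of the class indicator
at level 0.5 on the pixel-centre grid, discards components below
`min_area_um2` (default 200 um^2, roughly two pixels at the working
magnification — indistinguishable from stain debris), normalizes
orientation (outer rings counter-clockwise, holes clockwise) and maps
everything through the slice pose into block coordinates. Manual contour
files in the same CSV dialect are supported so a study can also trace
structures by hand, as the original CAD workflow did.

## Reconstruction

The primary path is `rasterize_stack()` followed by
`surface_from_volume()`. Every voxel takes the class of the pixel on the
nearest plane along z, *provided* that plane passes within half the local
inter-plane gap; ties go to the shallower run. This zero-order fill is a
deliberate choice: the material between planes was destroyed unobserved, so
the reconstruction never invents intermediate shapes, at the cost of a
cap bias of order gap/2 at the top and bottom of structures. With
`flat = TRUE` the same machinery ignores the plane tilt (each slice stacked
at its mean measured height), which serves as the naive-baseline comparator
for the tilt-aware fill.

Iso-surfaces are extracted by marching tetrahedra on the Kuhn six-tetrahedra
subdivision of each voxel cell. That subdivision is face-compatible between
neighbouring cells, so the emitted mesh is watertight without a case table;
watertightness (every edge shared by exactly two consistently wound
triangles) is verified and flagged on every mesh rather than assumed.
Components below `min_component_voxels` (default 8) are dropped as
segmentation specks. Optional Taubin lambda/mu smoothing (0.5 / -0.53) is
volume-preserving to well under 1 % over 20 iterations.

`loft_contours()` retains the direct contour-to-surface path: rings on
successive planes are matched by centroid distance gated by their
equivalent radii, resampled, cyclically aligned, stitched with triangle
strips, and capped at chain ends with ear clipping. Where structures merge
or split there is no canonical stitch; detected branchings (and any stitch
that fails the watertightness check) fall back to rasterizing the contours
and extracting the iso-surface, which handles arbitrary topology. The
default reconstruction voxel is `min(pixel_size, median gap / 3)`: the
volume error is dominated by the ~35 um plane spacing, not by the 5 um
pixels.

## Morphometry

Mesh volumes are signed tetrahedron sums against the origin
(`mesh_volume_tetra()`); the signed sum makes the result translation
invariant, and non-watertight input is an error, not a warning. Reports
print volumes in um^3 and mm^3 side by side deliberately: published ossicle
volumes are sometimes quoted in units that are inconsistent by nine orders
of magnitude, and keeping both units visible stops such a mix-up from
propagating silently.

The not-calcified fraction is
`100 * (vessel + cartilage + soft) / (bone + vessel + cartilage + soft)`
computed over the structure's strict interior: non-bone voxels not
reachable from the volume border (flood fill, 6-connectivity). The mucosal
layer outside the bone surface is thus excluded. A limitation follows from
the strictness: a channel that pierces the bone clear through on both ends
is topologically open and drops out of the interior; real nutrient canals
open at foramina, so fractions on heavily pierced specimens are lower
bounds. The calibrated validation phantom keeps its channel fully internal
for exactly this reason.

Channel diameters use the spec'd estimator: the medial axis is the ridge of
the 3D Euclidean distance transform (voxels whose distance is not exceeded
in their 26-neighbourhood) and the local diameter is twice the distance
value there. On a cylinder whose axis lies on a voxel-centre lattice line
this is within one voxel of truth across the 14-83 um range of interest at
5 um voxels; an off-lattice axis can add another ~half voxel of
quantization, which is why the validation cylinders are lattice-aligned and
the voxel size is reported alongside every distribution.

Wall thickness is local thickness (largest inscribed sphere diameter,
computed by sphere-painting from the medial voxels — those whose inscribed
sphere is not contained in a neighbour's — largest first, completed by the
2 x EDT lower bound where no painted sphere reaches). The
diffusion screen flags voxels whose distance to the nearest non-class voxel
exceeds `diffusion_limit_um` (default 150 um, the literature value for
lamellar bone, exposed as a parameter precisely because it is a quoted
value, not a measured one). Distances to the surface use the half-voxel
boundary convention (the class boundary lies halfway between foreground and
background voxel centres). A structure is "fully diffusion-supplied" when
nothing is flagged — the quantitative form of the argument that thin
stapedial crura (~103-134 um) need no internal vessels.

## The phantom simulator, and what it does not emulate

`make_ossicle_phantom()` builds analytic specimens (spheres, ellipsoids,
capsules, cylinders with tissue classes; overlap precedence vessel >
cartilage > bone > soft tissue so channels are never occluded), and
`simulate_grinding()` renders the full measurement process: wedge-shaped
cut planes, 1 um caliper quantization at the three marks, in-plane camera
jitter (translation and rotation), per-class Gaussian stain noise
(default sd 5 intensity units), anti-aliased fiducial disks, and resin
show-through of structures up to 150 um below the surface. Nominal
abrasion defaults to 35 um per run; the `tilt` parameter is the per-run
gradient *increment*, because a fixed gradient produces parallel planes and
therefore uniform abrasion — only an accumulating skew reproduces a
persistent 35 vs 94 um spread between the marks and the periphery.
`tilt_for_spread()` calibrates the increment so each run removes exactly
35 um at mark A and 94 um at the far block corner. Grinding stops when a
fiducial anchor would be ground through, since at that point the caliper
measurement protocol breaks down; where the wedge has already left the
block bottom, the image shows air.

Ground truth (true poses and per-run label rasters) accompanies every
simulation, which is what makes the end-to-end acceptance checks possible:
sphere volume recovery through the full pipeline, tilt-aware versus
flat-stacking error, pose recovery under jitter, a calibrated 1 %
not-calcified fraction (channel radius chosen so
`pi r^2 L = 0.01 * (4/3) pi R^3` exactly), and the diffusion screen against
the closed-form core fraction `((R - limit)/R)^3`.

The simulator does *not* emulate: optical point-spread or defocus, specular
reflection and grinding-paper scratch texture, stain batch variation or
fading, deformation of the block, or biological shape variability. Passing
the phantom suite therefore demonstrates that the *reconstruction
mathematics* is correct under realistic geometric and radiometric noise; it
does not certify segmentation accuracy on real stained surfaces, where the
Gaussian colour model is an operational stand-in for expert tracing (manual
contour import exists for exactly that case).

## Numerical choices and validation scales

* Oracle volumes (`analytic_class_volumes()`) use dense 2 um voxelization,
  evaluated in z-slabs; halving the oracle voxel moves volumes by < 0.5 %.
* Convergence is monitored with measures that actually respond to the
  refinement: signed volume errors of the nearest-plane fill cancel almost
  exactly (the fill is nearly unbiased), so gap refinement is assessed by
  the symmetric-difference volume against the analytic phantom, and voxel
  refinement by the iso-surface mesh-volume error against the closed form.
  Both halve, or better, per refinement level.
* Validation problem sizes: blocks of 1.2-2.0 mm, 5 um pixels
  (240-400 px images), 10-66 grinding runs, reconstruction voxels 5-20 um.
  These sizes keep the full suite in the minutes range on one CPU while
  leaving every estimator several resolution elements of headroom; the
  methods contain nothing that is specific to these scales.
* Determinism: every stochastic component (placement jitter, abrasion
  noise, stain noise) is driven by one seed; identical configuration and
  seed reproduce byte-identical artifacts, which the suite asserts on the
  report JSON and the NRRD volume.

## Known limitations

* Nearest-plane fill biases structure caps by up to half a gap; cap-heavy
  morphologies (flat plates parallel to the grinding plane) are measured
  less accurately than elongated ones.
* The strict-enclosure interior excludes through-piercing channels from the
  not-calcified fraction (see above).
* The Gaussian colour model assumes stains separate in RGB; laboratories
  with different protocols should fit their own model from labelled samples
  rather than rely on the built-in palette.
* Lofting gives exact prisms for matched rings but delegates all branching
  topology to the rasterized path; no attempt is made to produce
  CAD-quality NURBS surfaces.
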