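# microgrindr

3D reconstruction and morphometry from serial microgrinding images.

## The problem

Serial microgrinding resolves both hard and soft tissue at micrometre
scale — bone, cartilage, blood vessels, mucosa — where micro-CT only
separates calcified from non-calcified material. A resin-embedded specimen
(the motivating application is the human middle-ear ossicular chain) is
ground away in runs of roughly 35 um; each freshly exposed block surface is
stained and photographed, and is then destroyed by the next run. Three
vertical wooden fiducial sticks appear as disks in every photograph, and a
digital caliper records the remaining specimen thickness next to each stick
after every run.

`microgrindr` turns such a stack back into quantitative 3D anatomy:

1. **Registration** — each slice's in-plane pose comes from a closed-form
   three-point Procrustes similarity over the detected fiducial centres,
   and its cut plane `z(x,y) = g_x x + g_y y + c` from the exact 3x3 solve
   of the three caliper readings, so *inclined* grinding planes (machine
   skew: ~35 um abrasion at the specimen, up to ~94 um in the periphery)
   are handled, not just parallel slabs.
2. **Segmentation** — per-class Gaussian colour model for the surface
   stain, maximum-likelihood pixel classification with a majority filter,
   sub-pixel contour extraction; manual contour import for expert tracing.
3. **Reconstruction** — tilt-aware nearest-plane fusion of the posed label
   maps into a voxel volume, then watertight iso-surfaces by marching
   tetrahedra (plus a direct contour-lofting path).
4. **Morphometry** — tetrahedral mesh volumes
   `V = |sum_t det(v1, v2, v3)/6|`, not-calcified interior fractions,
   vessel-channel diameters from the distance-transform medial ridge
   (`d = 2 * EDT`), local wall thickness, and a diffusion screen flagging
   tissue farther than 150 um from the nearest surface.
5. **Phantom simulator** — analytic specimens with ground truth run through
   a virtual grinding/staining/photography process (wedge planes, 1 um
   caliper quantization, camera jitter, stain noise, resin show-through),
   so the whole pipeline is validated end-to-end against closed forms.

## Worked example

Simulate grinding of a bundled phantom (a bone sphere of radius 500 um with
an axial vessel channel), then register, segment, reconstruct and measure:

```r
library(microgrindr)

cfg <- system.file("extdata", "config_two_sphere.yaml", package = "microgrindr")
report <- run_pipeline(cfg)
report
#> Morphometry of 'two_sphere_test' (voxel 10 um)
#>   bone            5.217e+08 um^3  (0.521739 mm^3)
#>   vessel          2.071e+06 um^3  (0.002071 mm^3)
#>   fiducial        1.672e+07 um^3  (0.016719 mm^3)
#>   not calcified: 0.000 %
#>   vessel diameter (um): min 44.7 / median 44.7 / max 44.7
#>   wall thickness median 438.6 um; >150 um core: 19.93 %
```

Reading the numbers: bone + vessel is 5.238e8 um^3, within 0.05 % of the
analytic sphere volume 4/3 pi 500^3 = 5.236e8 um^3, reconstructed through
the complete simulated measurement process (35 um grinding, stain noise,
classification, registration, voxel fusion). The vessel median diameter
44.7 um estimates the channel's true 50 um to within one reconstruction
voxel. The not-calcified fraction is 0 here because this demo channel
pierces the sphere clear through — a topologically open canal is excluded
by the strict interior rule (the `sphere_channel` phantom, whose channel is
fully internal and calibrated to exactly 1.0 %, is recovered at ~1.01 %).
The wall screen reports 19.9 % of the bone farther than 150 um from a
surface: a solid half-millimetre sphere is (unlike thin ossicle walls) too
thick to be supplied by diffusion alone.

Artifacts land in the configured output directory: slice TIFFs and the
abrasion CSV, `poses.json`, per-run label PNGs and contour CSVs,
`volume.nrrd`, `surface_<class>.stl/.ply`, `report.json`/`report.csv`, and
`run.log` with per-stage checksums. A thin command-line front end with
subcommands `simulate | register | segment | reconstruct | measure |
compare | all` is installed at `inst/exec/microgrind`.

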