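# fidseg

Automatic detection and pose estimation of a four-marker MRI fiducial device
in 3D MR volumes.

## The problem

MR–ultrasound image fusion needs a rigid link between the MR volume's
coordinate frame and the physical world. A passive fiducial device provides
it: four liquid-filled cylindrical wells (12.7 mm inner diameter and depth),
three arranged as a scalene triangle with side lengths 50.7, 69.2 and
88.9 mm and a fourth raised 12.7 mm above the base centroid. If the four
markers can be segmented automatically in the MR volume, the device pose —
group center-of-mass **c**ₘ and base-plane normal
**n** = (B−A)×(C−A)/‖(B−A)×(C−A)‖, reported as spherical angles (θ, φ) in
the LPS patient frame — anchors anything mechanically registered to the
device, such as an electromagnetic probe-tracking sensor.

The difficulty is acquisition heterogeneity: clinical abdominal protocols
range from 0.7 to 1.9 mm in-plane, 1.7 to 10 mm slices, 0 to 2 mm slice
gaps, and arbitrary scan-plane obliquity. `fidseg` is aimed at medical
physicists and image-analysis researchers who need marker localization that
works across that whole range without per-sequence tuning, plus a synthetic
test bed to quantify it.

## The algorithm

`segment_fiducial()` runs five stages, all in physical units (mm, mm³) so
that anisotropic and oblique grids are handled uniformly:

1. **Noise threshold N_T** — valley of the bin-width-1 intensity histogram
   above the background peak (the derivative sign change between the noise
   mode and the first signal mode).
2. **Reference threshold R_T** — mean intensity of 26-connected components
   with volume strictly inside (0.5, 3)·V_marker, where
   V_marker = π(12.7/2)²·12.7 ≈ 1608.5 mm³.
3. **Iterative signal/size discrimination** — thresholds ST_n = (n/4)·R_T,
   n = 7…2; components strictly inside (0.35, 1.3)·V_marker are merged into
   a composite mask unless the union would exceed 1.3·V_marker (the new set
   is then discarded).
4. **Shape gate** — candidates with any per-axis extent above 26.9 mm
   (1.5 × the marker space diagonal) are removed.
5. **Constellation matching** — 4-subsets of intensity-weighted candidate
   centers-of-mass are matched against the six template separations
   {88.9, 69.2, 51.9, 50.7, 44.2, 30.3} mm at a tolerance growing from
   ±1 mm; minimal-RMS match wins and fixes the A–D labels.

The result carries the marker COMs, device COM, normal, (θ, φ), the
matching tolerance used, a least-squares rigid fit to the template frame,
and per-stage diagnostics.

A synthetic MR generator (`rasterize_scene()`, `table1_suite()`,
`repeatability_suite()`) emulates the protocol geometries — partial-volume
integration over the excited slice thickness, slice gaps, oblique planes,
rectified Gaussian noise, integer quantization — over a body-like
background with marker-sized blob confusers, and evaluation helpers
(`detection_rate()`, `spacing_accuracy()`, `repeatability()`) reproduce the
validation analyses.

## Worked example

Simulate a thin-slice (LAVA-like, 0.7 × 0.7 × 1.7 mm) scan of the default
scene and detect the device:

```r
library(fidseg)
tpl <- fiducial_template()
vol <- rasterize_scene(tpl, scene_pose(seed = 1),
                       acquisition_spec("lava"), seed = 7)
det <- segment_fiducial(vol, tpl)
summary(det)
#> <fiducial_detection>
#>   sequence: lava
#>   device COM (LPS mm): (68.62, 17.80, 31.13)
#>   orientation: theta = 89.99 deg, phi = -90.00 deg
#>   matched at tolerance 1 mm, RMS separation error 0.056 mm
#>   marker centers-of-mass (LPS mm):
#>         x      y      z
#> A  20.024 20.950 18.011
#> B 108.920 20.948 18.012
#> C  76.951 20.954 57.399
#> D  68.600  8.353 31.079
#>   noise threshold N_T = 41 (histogram peak at 1)
#>   reference threshold R_T = 334.4
#>   candidates: 47 connected sets at N_T, 4 after iterations, 4 after shape gate
```

The scene places the device base-flat in a coronal plane with the apex
pointing Anterior, so the expected orientation is (θ, φ) = (90°, −90°); the
detection reproduces it to 0.01°. The true device COM is
(68.61, 17.83, 31.11) mm: every marker is localized to well under a tenth
of the in-plane voxel. `coef(det)` returns the labeled marker COMs,
`residuals(det)` the per-marker residuals of the rigid template fit (all
below 0.08 mm here), and `plot(det)` draws the matched constellation.

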