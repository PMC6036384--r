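---
title: "Detecting a four-marker MRI fiducial device: model, algorithm, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a four-marker MRI fiducial device}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fusing live ultrasound with a previously acquired MR volume requires a rigid
link between the two coordinate frames. A passive fiducial device — four
liquid-filled cylindrical wells arranged as a scalene triangle with one well
raised above the base centroid — provides that link: if the four markers can
be localized automatically in the MR volume, the device pose defines the MR
frame relative to anything mechanically coupled to the device (for example an
electromagnetic probe-tracking sensor). The hard part is that clinical
abdominal protocols span a wide range of acquisition geometries: in-plane
resolutions from 0.7 to 1.9 mm, slice thicknesses from 1.7 to 10 mm, slice
gaps from 0 to 2 mm, and axial, coronal, or arbitrarily oblique scan planes.
A detector has to work across all of them without per-sequence tuning.

`fidseg` implements the device model, the detection algorithm, the pose
computation, a synthetic MR acquisition generator, and the evaluation
machinery to measure detection rate, spacing accuracy, and pose
repeatability on synthetic scans.

## Device model

The template is built from the manufactured dimensions: base triangle sides
50.7, 69.2, 88.9 mm; apex marker 12.7 mm above the base centroid; marker
wells 12.7 mm in inner diameter and depth. Canonically the base lies in the
z = 0 plane, vertex A at the origin, B on +x, C at positive y, apex D on +z.
Because written sources do not identify which physical well carries which
printed label, labels are fixed by opposite-side ordering (A faces the
shortest base side), and the orientation normal is sign-corrected toward the
apex so that the reported pose never depends on base labeling.

Two derived quantities drive the detection gates:

* the marker signal volume `v_marker = pi * (12.7/2)^2 * 12.7 ≈ 1608.5 mm^3`
  (computed from the stated inner dimensions; it is user-overridable because
  a filled well's effective signal volume may differ from nominal), and
* the marker space diagonal `sqrt(12.7^2 + 12.7^2) ≈ 17.96 mm`, whose
  1.5-multiple (26.9 mm) bounds candidate extents in the shape gate.

The six pairwise separations of the ideal constellation are
{88.9, 69.2, 51.92, 50.7, 44.23, 30.31} mm — all distinct, which is what
makes unambiguous labeling of a matched constellation possible.

## Detection algorithm

`segment_fiducial()` composes five stages; every stage raises a classed
condition naming itself on failure, so a non-detection is always
attributable.

**Noise threshold.** The voxel-intensity histogram (bin width 1; this is why
volumes must carry integer intensities — rescaling would distort ratios) has
a dominant low-intensity mode from air/noise and signal modes above it. The
background peak is the global maximum over the lower half of the occupied
intensity range, excluding the I = 0 bin (reconstruction can make exact zero
artificially massive). The noise threshold `N_T` is the valley above that
peak: walking upward, the running minimum bin is tracked until some bin at
least doubles it (or any occupied bin appears after an empty valley bin),
which marks the onset of the next signal mode; the threshold is the
running-minimum bin. On an idealized monotone descent this is exactly the
first non-negative forward difference — the discrete sign change of the
histogram derivative — but the doubling criterion does not false-trigger on
Poisson fluctuations of the noise mode, which matters for small-matrix
acquisitions (a 1.9 mm localizer grid has an order of magnitude fewer
voxels than a 0.7 mm volume). A 3-bin moving-average smoothing is available
(`smooth_histogram`) but off by default.

**Marker-sized sets and reference threshold.** 26-connected components
(voxels sharing a face, edge, or corner) of the noise-thresholded volume are
measured in mm^3 — voxel count times dx·dy·dz, with dz the reconstructed
inter-slice spacing — because voxel volumes differ by a factor of ~40 across
the protocol and raw counts are not comparable. Components with volume
strictly inside (0.5, 3) × `v_marker` define the reference signal threshold
`R_T`, the mean original intensity of their voxels: a robust estimate of the
characteristic marker signal level even when markers carry partial-volume
shells.

**Iterative signal/size discrimination.** Thresholds `ST_n = (n/4) R_T`,
n = 7…2, are applied in decreasing order; at each level, components with
volume strictly inside (0.35, 1.3) × `v_marker` are merged into a composite
mask, but only if the union with any overlapping or adjacent composite
object stays within 1.3 × `v_marker` — otherwise the new set is discarded
and the composite keeps the earlier, tighter version of the object. The
descending schedule captures bright markers early and faint,
partial-volume-attenuated markers late, while the growth-rejection rule
prevents low thresholds from bloating an object past marker size.

**Shape gate.** Candidates whose extent along any logical axis exceeds
26.9 mm (1.5 × marker diagonal) are removed; this kills elongated structures
that happen to pass the volume windows. Extents are per-axis
(`(max − min + 1) · spacing`), the reading that matches a per-axis bounding
measurement; a 3D-diagonal reading was considered and rejected because the
per-axis form is the stricter and simpler of the two and passes a rasterized
default cylinder at any orientation with margin.

**Constellation matching.** The intensity-weighted centers-of-mass of the
surviving candidates (original intensities, world mm) are searched for a
4-subset whose six sorted pairwise distances each agree with the template
separations within a tolerance τ, starting at 1 mm and growing in 1 mm
steps. Among subsets matching at the same τ, the one with minimal RMS
distance error wins, and labels A–D are assigned by the error-minimizing
permutation — unique for the scalene default geometry. The schedule is
capped at `match_tol_max` = 10 mm: through-plane COM quantization on
thick-slice acquisitions can displace a marker by up to half the slice
spacing (5 mm for a 10 mm localizer), so genuine matches must remain
reachable above 5 mm, while an unbounded search would eventually accept
arbitrary clutter; the cap is configurable.

**Pose.** The device location is the unweighted mean of the four marker
COMs — the markers are physically identical, and intensity-weighting the
group would make the pose depend on the pulse sequence. The orientation is
`unit((B − A) × (C − A))`, sign-corrected toward the apex, reported as
spherical angles in LPS: θ = acos(n_z) in [0°, 180°], φ = atan2(n_y, n_x) in
(−180°, 180°]; at the poles φ is undefined and reported as 0 with a flag. A
labeled least-squares rigid fit (SVD Procrustes with det = +1) to the
template provides the full transform and an RMS residual.

## Coordinate conventions

All positions are world millimetres in LPS. Voxel indices are 0-based and
node-centred; the affine maps index (i, j, k) to mm, NIfTI's RAS affines are
converted on load/save, and DICOM series are assembled honouring
ImageOrientationPatient / ImagePositionPatient with the inter-slice spacing
taken from successive slice positions (thickness + gap). Gapped stacks are
represented as contiguous grids with dz = thickness + gap; the gap's
information loss is a property of the acquisition and is modelled in the
generator, not the container. Native grids are segmented as-is — no
isotropic resampling — since every quantity the algorithm gates on is
computed in physical units.

## The synthetic test bed

No imaging data ship with the package; the generator stands in for phantom
and volunteer scans. `rasterize_scene()` integrates a continuous scene over
each voxel's sensitive volume — full in-plane footprint, through-plane only
the excited slice thickness, so slice gaps genuinely discard signal — using
4 point samples per axis (64 per voxel; ≤ 2% volume error for the default
cylinder on the coarsest protocol grid). Gaussian noise is added on a
magnitude floor (`|signal + noise|`), an adequate stand-in for Rician
magnitude noise at these signal-to-noise ratios, then intensities are
rounded and clamped to [0, 4095], a DICOM-like integer range.

The default scene is a body-like ellipsoid (semi-axes 60 × 30 × 38 mm) of
tissue signal containing 30 seeded ellipsoidal blobs spanning 0.2–4 ×
`v_marker` and 0.5–1.5 × the tissue level — deliberately marker-sized
confusers — with the device lying base-flat in a coronal plane on the
anterior surface, apex pointing Anterior (the anticipated orientation
angles are θ = 90°, φ = −90°). Signal levels default to air 0, tissue 120,
marker 400, noise σ = 10; these are plausible integer scanner units chosen
once for the test bed, not measured values. The device housing holds the
wells a few millimetres off the skin, which the scene reproduces: markers
must not be 26-connected to the body, or the marker-size gate would see one
giant component.

Two suites reproduce the validation designs at desk scale. `table1_suite()`
emits one volume per protocol preset — localizer 1.9/1.9/10 mm; coronal
SS-FSE 0.9/0.9/6+1; in-phase and opposed-phase 0.7/0.7/6+1 (two echoes,
same geometry); LAVA 0.7/0.7/1.7; FIESTA 0.7/0.7/4+2; SPGR 0.7/0.7/5+1;
FR-FSE 0.7/0.7/7+1 — eight image sets, with the localizer represented by
its axial plane. `repeatability_suite()` emits axial plus two oblique planes
(10° about x, 20° about y — the physical experiment's oblique angles are
not documented, so these are package choices, configurable) at two table
positions 30 mm apart, device and field of view moving together, with the
commanded shift recorded in metadata and removed during comparison. The
field of view is 130 × 100 × 80 mm, the smallest box that holds the body
and device with margin; it keeps a full 8-preset replicate near 15 s of
compute, and the evaluation defaults (5 replicates × 8 presets; 2 × 6
repeatability volumes; 5 thin-slice replicates, 30 pair measurements) were
sized to the same end.

What the generator does **not** emulate: pulse-sequence contrast physics
(relaxation of the marker solution, fat/water phase), coil sensitivity
profiles, bias fields, breathing and organ motion, and tissue textures
beyond piecewise-constant ellipsoids. Passing tests therefore demonstrate
the geometric and statistical robustness of the pipeline — partial volume,
slice gaps, obliquity, quantized noise, marker-sized clutter — not
robustness to physiological artifacts; results on real scans depend on
those too.

## Numerical choices and degenerate inputs

* Thresholding is inclusive (`>=`), natural for integer intensities.
* Size windows are strict inequalities; objects exactly on a boundary are
  excluded (tested at exact edges).
* Candidate processing order is (volume, first voxel in raster order), so
  composite assembly and matching are platform-reproducible.
* Candidates touching the volume boundary are retained but flagged
  (markers at the edge of the field of view are partial).
* Histograms with fewer than two occupied bins, monotone histograms, empty
  composites, and sub-4 candidate sets all fail with classed conditions
  naming the stage.
* Intensity rescaling by an integer factor leaves detections unchanged up
  to histogram-valley discretization on a quantized histogram; the property
  is exercised on noise-free volumes where the remaining discrepancy is
  confined to partial-volume shell voxels and moves marker COMs by well
  under 0.1 mm.
* All randomness flows through explicit seeds; suite volumes derive
  per-volume seeds from one master seed.

## Known limitations

Only the four-marker device is supported — no three-marker fallback, manual
seeding, or multi-sequence averaging of detections. DICOM support is
read-only and minimal (explicit-VR little-endian, single-frame series,
geometry tags); NIfTI is the primary interchange format. The matcher
enumerates 4-subsets, which is exact but quadratic-to-quartic in candidate
count; it is intended for the post-gate regime of tens of candidates, not
thousands.
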