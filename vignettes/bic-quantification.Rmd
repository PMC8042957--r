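---
title: "Measuring bone-to-implant contact on 2D micro-CT slices"
author: "microBIC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring bone-to-implant contact on 2D micro-CT slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

The bone-to-implant contact ratio (BIC) of a screw-type implant is the
percentage of the thread profile length in direct contact with bone,
evaluated on a 2D plane containing the implant's long axis. `microBIC`
measures it in five stages: axis estimation, longitudinal reslicing,
tri-class segmentation, groove-wise contact scoring with an interface
exclusion band, and multi-angle averaging. Each stage is a separate
exported function so intermediate objects (slices, label images, traced
profiles) can be inspected.

The pipeline assumes: a single metallic implant far brighter than bone;
an approximately straight implant axis (the axis model is a line, not a
curve); and reconstructions on — or rescalable to — the 8-bit 0–255
intensity convention, because the default thresholds are expressed on
that scale.

## Parameters that matter

* **Bone window** `[bone_min, bone_max]`, default **[60, 90]** (8-bit
  intensity). This window was established for newly formed bone against
  histological reference sections; it is deliberately narrow because
  low-mineralized bone overlaps soft tissue in intensity, which is also
  why an automatic ISO-50% histogram threshold is not offered. The window
  is inclusive at both ends; the wording "min/max" does not dictate
  openness, and inclusive bounds make boundary behavior testable
  (intensity 60 is bone, 59 is background).
* **Implant threshold** `implant_min`, default **200**. No published
  value exists for the metal class; titanium reconstructs far above the
  bone window ceiling, so any cut between 90 and the metal plateau works.
  200 leaves margin for partial-volume softening at the metal edge.
* **Exclusion layers** `exclusion_layers`, default **1** voxel. Residual
  beam hardening brightens a shell of voxels around the metal into the
  bone window; excluding one layer at the junction removes it from
  contact assessment. The metric is chessboard (one layer = the full
  8-neighborhood shell), matching the visual meaning of "one voxel layer".
  The band is built in-plane (2D), since the measurement itself is
  per-slice.
* **Grooves per side**, default **4**, counted from the implant top
  (the end with the smaller axial coordinate; an offset flag covers the
  opposite mounting). Grooves are delimited by successive thread crests;
  partial grooves at the implant ends are never measured.
* **Slice angles**, default **0°, 45°, 90°, 135°** about the axis, with
  `angleOffsetDeg` mapping an external 0° reference (e.g. a histology
  plane) onto volume coordinates. The implant-level summary is the
  unweighted mean of the per-slice values.
* **Per-slice pooling**: pooled lengths (Σ contact / Σ total) by
  default, because it weights grooves by their actual profile length;
  `"groove-mean"` (mean of per-groove ratios) is available since the
  original protocol does not state which rule was used.

## Numerical choices

Reslicing interpolates the *grayscale* volume trilinearly and thresholds
afterwards; interpolating labels would create stair-step contact
artifacts. When the estimated axis is grid-aligned, the sampling origin
snaps to the voxel lattice so orthogonal slices reproduce coordinate
planes exactly. Out-of-volume samples take intensity 0. Trigonometry at
multiples of 90° uses `cospi`/`sinpi` so those planes are exact.

Axis estimation is the principal axis of the supra-threshold voxel
cloud — an automated replacement for manual marker-based alignment, not
an emulation of it. On constructed phantoms it recovers tilts up to 5°
within 0.02°.

Contact probing steps outward from each boundary element of a groove
path, past the exclusion band, and calls the element "contact" iff the
first pixel beyond the band is bone. Probe directions are the outward
normals quantized to the pixel grid; at concave corners (where a thread
flank meets the valley wall) a purely axial probe would run parallel to
the wall inside its exclusion band forever, so corner elements are
deflected one step toward the radial direction — the 8-neighborhood
quantization of the corner normal. Boundary length is counted in
pixel-edge units (1 px per element); sub-pixel contour smoothing is out
of scope.

Statistics are two-sided throughout (the convention under which every
re-derived printed p-value matches its source at 2-decimal rounding);
SDs use the n−1 denominator; table-style rounding is half-away-from-zero
to 2 decimals with full precision retained alongside. Correlation
strength labels use |r| < 0.40 weak, < 0.70 moderate, ≥ 0.70 strong —
cut-offs inferred to be consistent with all published labels
(0.74/0.81/0.71 strong, 0.46/0.41 moderate, 0.30 weak), since none were
stated. One published inconsistency is worth noting: the TCP-group
correlation p-value appears both as 0.35 (text) and 0.36 (table); the
closed-form recomputation from r = 0.46, n = 6 gives 0.359, i.e. 0.36.

## The phantom: what it emulates, and what it does not

The generator builds a threaded cylindrical implant (defaults: Ø 4 mm,
8.5 mm length, 20 µm isotropic voxels) in a cortical bone shell, with a
prescribed spatially varying contact pattern and analytic ground truth.

Design choices:

* **Annular rings instead of a helix** at the thread pitch. In a
  longitudinal plane rings and a helix are visually equivalent, but rings
  make the thread profile identical in every plane, so the analytic
  per-plane BIC is exact rather than approximate. Thread pitch (800 µm)
  and depth (320 µm) are free generator parameters — typical dental
  implant values, not measured ones — and the crest axial thickness is
  fixed at half the pitch.
* **Contact is defined on the thread-profile arc** (the exposed surface
  between consecutive crests), not the cylinder envelope, matching the
  groove-wise histomorphometric definition. The contact indicator is
  piecewise constant on an angular × groove grid (default 36 sectors of
  10°); sampled maps draw one seeded permutation per groove and truncate
  it, so contact sets are nested in the target fraction and ground-truth
  BIC is monotone in it.
* **Intensities** background 20, bone 75 (the bone-window center),
  implant 230 reproduce the default threshold regime. Where the map says
  "no contact" a **3-voxel background gap** separates bone from the
  implant surface: the probe position at one exclusion layer sits up to
  ~2.5 px (in-plane Euclidean) from the true surface once interpolation
  shifts the labeled boundary, so a 2-voxel gap could graze bone on
  oblique slices while 3 voxels cannot. This keeps the prescribed
  pattern exact under discretization.
* **Halo model**: residual beam hardening only brightens, so the halo
  raises every shell voxel to *at least* the halo intensity
  (`max(value, haloIntensity)`, default 75) rather than adding a
  constant — addition would push bone voxels in the shell *out* of the
  bone window, turning a purely inflationary artifact into a mixed one,
  which is not what a bright rim does. With the default settings the
  entire one-voxel shell classifies as bone, exactly the failure mode
  the exclusion layer is designed to absorb.
* **Ceramic granules** (off by default) emulate residual β-TCP
  microspheres: bone-intensity spheres of 30 µm radius (≈ 60 µm
  diameter, the middle of the 45–75 µm manufacturing range) placed within
  400 µm of the implant surface — the defect gap where the ceramic
  carrier resides. The confound experiment uses 4000 granules per
  phantom: the delivered carrier volume (0.1 ml at ~1 g/ml ceramic
  loading) corresponds to far more microspheres than that, so 4000 is a
  conservative residual after four weeks of degradation. Granules are
  deliberately indistinguishable from bone under the default thresholds;
  the analytic truth excludes them while the measurement counts them,
  reproducing the mechanism by which residual ceramic depresses the
  histology-vs-micro-CT correlation.

What the phantom does **not** model: projection physics (no filtered
backprojection, no polychromatic beam), trabecular microarchitecture,
implant surface roughness, partial-volume contact below one voxel, or
the registration uncertainty between a histology plane and its matching
micro-CT plane. Passing the phantom suite therefore demonstrates the
correctness of the geometry, segmentation, exclusion and scoring logic
under controlled artifacts — not robustness to every feature of real
scans, where threshold calibration against histology remains the
critical manual step.

## Problem sizes and runtimes

The full-resolution default (20 µm voxels, ≈ 272 × 272 × 456 grid) is
practical for single analyses. The validation suite scales the same
geometry by voxel size instead of truncating it: unit tests run at 80 µm
(≈ 80 × 80 × 130, every thread feature still ≥ 4 voxels) and the
acceptance checks at 40 µm (≈ 144 × 144 × 236, the 128³–256³ regime).
Because geometry is specified in micrometres, the groove count (10) and
contact patterns are identical across scales; measured-vs-analytic
agreement is exact at both test scales.

## Known limitations

* The annular-ring thread makes per-plane truth exact but cannot probe
  helix-specific effects (a real thread's profile shifts by half a pitch
  between opposite sides).
* BIC is 2D and per-slice; 3D BIC over the full implant surface is out
  of scope.
* The axis model is a straight line; bent implants or strongly tilted
  mountings beyond a few degrees would need a registration step first.
* Histology images themselves are not processed; the histology side of
  agreement analyses enters as externally measured values (or, in
  validation, as the phantom's analytic truth).
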