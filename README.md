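# microBIC

Quantification of implant osseointegration from 2D micro-CT slices.

## The problem

The bone-to-implant contact ratio (BIC) — the fraction of the implant
thread profile in direct contact with bone —

```
BIC = 100 % × L_contact / L_thread
```

is the standard measure of how well a screw-type implant has
osseointegrated. The gold standard is histomorphometry on a stained
section cut along the implant's long axis, but sectioning is destructive
and yields a single plane. Micro-CT is non-destructive and can be resliced
through the implant axis at any rotation angle, at the cost of metal
artifacts at the bone–implant interface and of thresholds that must
separate newly formed bone from soft tissue and metal.

`microBIC` implements a complete measurement pipeline for volumes of
threaded implants in bone:

1. **Axis estimation** (`estimateAxis`): principal-axis analysis of the
   supra-threshold (metal) voxels.
2. **Longitudinal reslicing** (`extractLongitudinalSlice`): trilinear
   resampling of the grayscale volume on planes containing the axis at
   0°/45°/90°/135° (any angles, plus a user offset to match an external
   reference plane such as a histology section).
3. **Tri-class segmentation** (`classifySlice`): background / bone /
   implant by windowed thresholding — bone window [60, 90] and implant
   ≥ 200 on the 8-bit scale by default.
4. **Groove-wise BIC** (`traceImplantProfile`, `selectGrooves`,
   `measureBIC`): trace the lateral thread profile, select the upper four
   grooves of each side, exclude one voxel layer at the interface
   (chessboard metric) to suppress residual metal artifacts, and score
   every boundary element by probing outward for bone. Per-slice values
   pool boundary lengths; `meanBIC` averages the slices into the
   implant-level multi-angle mean.
5. **Agreement statistics** (`pearsonFromPairs`, `pairedTFromPairs`,
   `pearsonPFromR`, `pairedTFromSummary`, `buildAgreementTable`):
   two-sided paired t-tests and Pearson correlations between modalities,
   computable from raw pairs or from printed summary statistics
   (mean difference ± SD, or r with n).

A synthetic phantom generator (`phantomConfig`, `sampleContactMap`,
`buildPhantom`, `addArtifacts`) produces implant-in-bone volumes with a
prescribed contact pattern and *analytic* ground-truth BIC, plus residual
artifacts (bright interface halo, additive noise, ceramic granules that
segment as bone), so the whole pipeline is validated against known truth.

## Worked example

```r
library(microBIC)

cfg <- phantomConfig(voxelSizeUm = 80)           # coarse, fast demo grid
cm  <- sampleContactMap(0.5, granularity = 36, seed = 7)
ph  <- buildPhantom(cfg, cm)
truthPerPlane(ph$truth)
#>   angle_deg bic_percent
#> 1         0        25.0
#> 2        45        37.5
#> 3        90        37.5
#> 4       135        50.0

ax <- estimateAxis(ph$volume)
results <- lapply(c(0, 45, 90, 135), function(a) {
  sl <- extractLongitudinalSlice(ph$volume, ax, a)
  li <- classifySlice(sl)
  measureBIC(li, selectGrooves(traceImplantProfile(li)))
})
meanBIC(results)
#> ImplantBIC: angles {0, 45, 90, 135}, per-angle BIC {25.00, 37.50, 37.50, 50.00} %, mean 37.50 %
```

The measured per-angle BICs equal the analytic truth: on a noise-free
phantom the pipeline is exact, and the multi-angle mean (37.5 %) is the
implant-level summary. Published agreement statistics re-derive from
printed summaries alone:

```r
pearsonPFromR(0.74, 6)$p_value_2dp        # 0.09
pairedTFromSummary(5.07, 9.44, 6)$p_value_2dp  # 0.25
```

A command-line front end for every stage (simulate / reslice / segment /
measure / stats) is in `inst/scripts/bicquant.R`.

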