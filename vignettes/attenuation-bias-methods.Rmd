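---
title: "Methods: simulating attenuation-correction bias in lung PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating attenuation-correction bias in lung PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thoraxAC)
```

## The problem

Quantitative PET reports tracer uptake as the standardized uptake value,
SUV = tissue activity concentration / (injected dose / body weight).
Computing activity concentration requires correcting each line of
response (LOR) for photon attenuation with the factor
exp(-&int;&mu;&nbsp;dl), where &mu; is the 511 keV linear attenuation
coefficient (LAC). PET/CT derives &mu; per voxel from CT Hounsfield
units, so it captures the patient's actual lung density — including the
gravity-dependent anterior-to-posterior density gradient of supine
lungs — and bone. Segmentation-based attenuation correction in
integrated PET/MR instead assigns one fixed LAC per tissue class (air
0, lung 0.0224, fat 0.0854, soft tissue 0.1 cm^-1^), which flattens the
lung gradient and treats bone as soft tissue. This package simulates
the resulting regional SUV bias on a digital thorax at desk scale with
four attenuation-map arms:

1. **CTAC** — continuous CT-derived LACs (reference),
2. **CTAC_MRLUNG** — CTAC with all lung voxels set to the fixed lung
   class LAC,
3. **CTAC_MRLUNG_NOBONE** — additionally, every voxel with LAC
   > 0.10 cm^-1^ set to the soft-tissue class LAC,
4. **MRAC** — the pure four-class segmentation map.

Emission data are always attenuated by the CTAC map (the "physical
truth"); only the correction map varies. Differences between arms
therefore isolate what the attenuation model does to regional SUV.

## The phantom

`generateThoraxPhantom()` renders an axial thorax: an elliptical body
(default lateral/AP semi-axes 150/105 mm) with an 8 mm subcutaneous fat
layer, two elliptical lungs (semi-axes 52/68 mm, centres 72 mm off the
midline), a spine cylinder (radius 16 mm, centre 50 mm posterior of the
volume centre, so that it overlaps the depth range of the posterior
lung bands), and posterior-lateral rib arcs (a thin shell of the inner
body ellipse, radial fractions 0.88–0.96, restricted to the posterior
three quarters). Anterior is the smaller row index; voxels are 2.6 mm
isotropic on a 256&times;256 grid, matching the resolution at which
segmentation-based attenuation maps are produced.

The lung HU field is the phantom's point: each lung's normalized
anterior&rarr;posterior depth is split into three bands whose means are
calibrated to the targets −779 / −746 / −685 HU (a 94 HU gradient).
Within each band the HU varies linearly in depth with the slope implied
by the neighbouring targets, re-centred on the band's mean voxel depth
so the band mean equals its target *exactly* irrespective of the lung
outline. (A single global linear profile cannot reproduce three
non-collinear band means; piecewise re-centring keeps the gradient
while making the calibration exact. The small slope discontinuities at
band edges are invisible to every downstream consumer, which works at
band or ROI granularity.) Optional Gaussian HU noise (default SD 25 HU,
a typical low-dose CT parenchyma spread) is added to all non-air
voxels. Other tissues: soft 40 HU, fat −90 HU, bone 700 HU (a mixed
cortical/trabecular average).

Ground-truth activity is uniform within compartments, specified in SUV
units (lung 0.4, soft 1.0, fat and bone 0.3) and converted to Bq/mL
through the default 351.8 MBq dose and 70 kg weight. Lung uptake is
deliberately uniform so that any reconstructed anterior–posterior SUV
gradient is attributable to attenuation correction alone; an optional
`activityGradient` parameter can emulate the small real posterior
uptake excess if desired.

What the phantom does **not** emulate: true airway/vessel texture,
respiratory motion, lobar anatomy, the comma-shaped posterior lung
recesses, scatter and randoms, and contrast-agent effects. Passing
tests therefore demonstrate the attenuation-model mechanism, not
absolute clinical SUV accuracy.

## Attenuation maps

`huToLac()` is the piecewise bilinear transform used by PET/CT
scanners, anchored so −1000 HU maps to exactly 0, with the 120 kVp
parameters: slope 9.6&times;10^-5^ cm^-1^/HU below the 47 HU break and
5.1&times;10^-5^ above it, the upper intercept derived from continuity.
All four parameters are exposed in `bilinearTransform()` because
vendors differ slightly.

`growLungMask()` is thresholded region growing: face-connected flood
fill from seed voxels through voxels with HU strictly below the
threshold (default −300 HU). On a noise-free phantom it reproduces the
lung labels exactly; the threshold is generous enough that ±25 HU noise
never detaches lung voxels (lung ≤ −600 HU) nor breaches the body wall
(fat −90 HU).

`replaceLungLac()` and `stripBone()` implement arms ii and iii;
`stripBone()` uses a strict `>` at 0.10 cm^-1^ and both operations are
idempotent. `buildSegmentationMuMap()` maps labels to class LACs with
bone deliberately classified as soft tissue. A voxelwise
difference-histogram QC (`muMapDifferenceHistogram()`) reports the
fraction of body voxels whose map difference is within a tolerance
fraction of the soft-tissue LAC.

## Projection and reconstruction

A 2-D parallel-beam geometry (default 168 angles over [0, &pi;), 256
radial bins of 2.6 mm) replaces the scanner's 3-D geometry: the studied
effect is in-plane and a transparent system model is worth more at desk
scale than vendor realism. The projector is ray-driven with bilinear
image sampling at a fixed step (default half a pixel); the
backprojector scatters with identical weights, so the pair is adjoint
to machine precision — the property OSEM's convergence theory assumes.
Line integrals are computed in mm and converted to cm for attenuation.

`simulateEmission()` scales the attenuated forward projection so the
expected total equals `totalCounts` (default 3&times;10^6^ per slice, a
typical whole-body-protocol true-count level for one thoracic plane)
and draws Poisson counts with a fixed seed.

`osemReconstruct()` implements ordered-subsets expectation maximization
for the attenuated-Poisson model: for subset *S* with attenuation
factors *a*,

x &larr; x &middot; A^T^~S~(a~S~ &middot; y~S~ / (a~S~ &middot; A~S~x)) / A^T^~S~ a~S~

with angle-interleaved subsets (subset *k* takes angles *k*, *k*+21,
…), a uniform positive initial image, and division guards (&epsilon; =
10^-12^; bins with zero data and zero model contribute nothing, so an
all-zero sinogram collapses to the zero image). Defaults mirror the
clinical protocol: 2 iterations, 21 subsets, then one 4 mm FWHM
Gaussian post-filter in image space (separable kernel, truncated at
3&sigma;, edge-renormalized so flat fields stay flat). `suvScale()`
divides by the simulation's count calibration and by dose/weight.

## Regional analysis

`placeROIs()` reproduces the 12-ROI scheme: per lung, two ROI columns
(a medial "hilum" column and a lateral "basal" column at ±40% of the
lung half-width — on a single-slice phantom the two levels share the
axial slice, so they are realized as distinct in-plane columns) with
three 10 mm ROIs at 20% / 50% / 80% of the lung's anterior–posterior
extent, nudged inward when needed so every ROI voxel stays inside the
mask. ROIs are placed once, on the lung mask, and copied to all four
arms. `roiMean()` averages voxels whose centres fall inside the disc.

`relativeDifference()` is (SUV~X~ − SUV~CTAC~)/SUV~CTAC~ &times; 100,
computed **per ROI** and then averaged (averaging per-ROI differences
and differencing region means give different numbers; the per-ROI
convention matches how such tables are built). `regionalSummary()`
pools left+right and both levels per depth position (12 ROIs &rarr; 3
regions), reports mean ± SD per region and arm — with the SD both
across ROIs and across per-subject means, since either aggregation is
defensible — and tests regional contrasts with one-way ANOVA plus
pooled-variance pairwise t-tests, Bonferroni-multiplied and capped at
1. Degenerate inputs are resolved by convention: identical groups give
p = 1, zero variance with unequal means gives p = 0.

`mldScreen()` splits each lung into three equal-extent segments and
flags mean lung density strictly below −950 HU. With fewer than three
slices the in-plane anterior–posterior axis serves as the cranio-caudal
surrogate.

## The cohort experiment

`runExperiment()` chains everything per subject: phantom draw (distinct
derived seed; anatomy axes jittered by a 3% SD truncated Gaussian to
stand in for inter-subject variation), the four maps, one emission
simulation, four reconstructions, one ROI placement, the MLD screen,
then pooling. It is bit-deterministic given the master seed, tags
errors with subject and stage, and records a config hash in the
provenance block. Because subjects are i.i.d. draws from one phantom
family, cohort SDs are narrower than inter-patient SDs and must not be
compared to clinical tables.

## Numerical and design choices

- Coordinates: 0-based voxel maths internally, 1-based R indices at the
  API; "anterior" = smaller row index; world mm from the grid centre.
- Ray step: spacing/2. At this step the central-LOR integral through an
  anti-aliased 20 cm disc is accurate to a few tenths of a percent —
  comfortably inside the 1% check tolerance; binary-rendered edges cost
  about 1%, which is why analytic fixtures are anti-aliased.
- The band calibration uses mean-depth re-centring rather than fitting,
  so noise-free band means are exact by construction and the calibration
  test tolerance (3&sigma;/&radic;n) is entirely a noise allowance.
- Subset count must divide the angle count (168 = 8&times;21); with one
  subset the algorithm reduces to MLEM update-for-update, which the
  test suite verifies against an independently coded MLEM loop.
- Test problem sizes are chosen for speed as package policy: unit tests
  run at 64–128 pixels with 42–84 angles; only the acceptance-level
  cohort run uses the full 256-pixel, 168-angle, 5-subject setting.

## Known limitations

- 2-D only: the scanner's 3-D (oblique-LOR) geometry, slice mashing and
  axial smoothing are not modelled; absolute SUVs differ from any
  scanner and only differences between arms are meaningful.
- No scatter, randoms, normalization, PSF or time-of-flight modelling.
- The bone-proximity effect is convergence-sensitive. When the
  correction map under-states attenuation in a compact region (stripped
  bone), EM at high effective convergence localizes the resulting
  deficit in that region itself, leaving nearby lung ROIs almost
  unchanged, whereas at low effective convergence the deficit spreads
  along the affected LORs into the surrounding lung. A 2-D 256&times;256
  problem after 2 iterations &times; 21 subsets is effectively much
  closer to convergence than a clinical 3-D reconstruction at the same
  nominal settings, so the additional posterior underestimation caused
  by bone stripping is reproduced in sign but is much smaller here than
  in patient data, and can be overwhelmed by cohort sampling noise.
  Re-running the experiment with fewer effective updates (e.g.
  `reconConfig(iterations = 1L, subsets = 3L)` with a matching angle
  count) shows the clinical-scale effect. This is a property of the
  2-D stand-in, not of the bone model.
- The emphysema screen on the default phantom is a negative control by
  construction (all lung HU far above −950); pathological cases must be
  configured explicitly.
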