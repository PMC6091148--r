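---
title: "Methods: threshold volumetry of vascular calcium in paired CT and MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold volumetry of vascular calcium in paired CT and MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the measurement
model, the parameters that matter, what the synthetic phantoms do and do
not emulate, and the numerical choices made where the design was open.

## The measurement model

Calcium volume is measured per vessel segment by pure threshold
volumetry. Both volumes are first resampled to 0.5 mm isotropic
resolution; thresholding and counting happen only on that grid, never on
the native anisotropic one, so CT and MR volumes from different scanners
are counted in identical voxels of 0.125 mm³.

**CT rule.** A voxel inside the segment ROI is calcium iff its intensity
is strictly above `ct_hu_cutoff` (default 560 HU). This cutoff separates
dense calcium (set well above 600 HU) from contrast-enhanced lumen
(~300 HU). The strict inequality is a deliberate boundary convention: a
voxel at exactly 560 HU is lumen, which makes exact unit tests possible.

**MR rule.** Calcium has near-zero proton-density in-phase signal, so a
voxel is calcium iff its intensity is strictly below `μ − kσ`, where μ and
σ are background statistics and k = 3 in the ilio-femoral region, k = 2 in
the aorto-iliac region (background signal there is more variable because
of bowel and respiratory motion). The reference region for (μ, σ) is the
ROI itself, estimated in two passes: pass 1 uses all ROI voxels; pass 2
re-estimates (μ, σ) after removing the voxels pass 1 classified, and
re-classifies once. The re-estimation exists because dark calcium inflates
σ and would otherwise suppress its own detection; exactly one re-pass
keeps the procedure deterministic. σ uses the n−1 sample denominator.

Two properties of this rule matter for interpreting every result in the
package:

1. *False-positive floor.* With Gaussian background noise, a fraction
   ≈ Φ(−k) of calcium-free ROI voxels is classified (Φ(−3) ≈ 1.35·10⁻³).
   No minimum-size or connected-component filtering is applied — the
   method accepts and quantifies isolated noise voxels, so an empty 5-cm
   segment ROI of ~25 000–30 000 voxels reads a few mm³. This makes the ROI
   radius a first-order parameter: the package uses lumen radius (3 mm)
   plus a ~2 mm wall margin, i.e. 5.05 mm, the tight ROI a practitioner
   would draw.
2. *Identifiability limit.* If calcium occupies more than roughly 10 % of
   the ROI, the pass-1 threshold `μ₁ − 3σ₁` falls below the calcium signal
   itself and the rule classifies nothing. The phantom generator therefore
   caps the per-segment calcium burden at 260 mm³ (≈ 6.5 % of the ROI) —
   a genuine limitation of background-relative thresholding, not of the
   implementation.

**Severity.** Groups on the CTA volume: [0, 100) mm³ none/mild, [100, 300)
moderate, [300, ∞) severe. The printed clinical bands are gapped integer
ranges (0–99, 100–299, ≥ 300); measured volumes are multiples of
0.125 mm³, so the package uses half-open continuous intervals that agree
with the printed bands at every integer.

## Resampling

Resampling is separable Catmull-Rom cubic interpolation along all three
axes (tricubic): volumetry is three-dimensional and slices are anisotropic
(1.3 mm at 1.5 T), so through-plane interpolation must be cubic too. New
voxel centres are laid out in physical coordinates from the input origin
(`origin + j · 0.5 mm`), making resampled grids comparable across
modalities; the output grid extends to cover the input extent within one
target voxel. Catmull-Rom reproduces constant and affine intensity fields
exactly and interpolates the data (resampling an already-isotropic volume
is the identity).

Edge policy: query points outside the input extent take the nearest-edge
value; the cubic stencil's out-of-range neighbours are linearly
extrapolated ghost cells. Clamping the stencil instead would break affine
exactness in the outermost voxel ring; linear extrapolation preserves it
and cannot manufacture out-of-field values darker than the local edge
trend, which matters because the MR rule would classify artificial dark
voxels as calcium.

## The phantom generator

`phantom_cohort()` renders paired CT/MR exams of straight vertical vessel
segments (two limbs with proximal/distal 5-cm femoral segments, or five
parallel aorto-iliac segments) with ellipsoidal intimal calcium deposits
seated at the lumen–wall interface (radial offset 2.3 mm, semi-axes
2.05–2.45 mm radially and 3–5 mm along the vessel, i.e. ~53–126 mm³
per deposit; 0–3 deposits per segment). Segment totals then span the
clinical severity range from zero to several hundred mm³. Deposits keep a
9 mm margin from segment ends so that their interpolated footprint stays
inside their own ROI.

- **CT model** (`soft_hu` 50, `lumen_hu` 300, `calcium_hu` 1200): a
  piecewise-constant HU field convolved with an isotropic Gaussian PSF of
  FWHM `psf_fwhm_mm` (default 1.0), plus seeded Gaussian noise (SD 10 HU).
  Blooming — the apparent enlargement of dense calcium under a fixed
  threshold — emerges from the PSF: the blurred edge of a 1200 HU deposit
  crosses 560 HU outside the true surface. One interpretable parameter
  reproduces the mechanism; no projection/reconstruction physics is
  simulated.
- **MR model** (background mean 100, calcium fraction 0, noise SD 10
  = 10 % of background): uniform intermediate background with deposit
  cores at zero signal. The surface-water layer (default 0.4 mm) erodes
  each deposit analytically — semi-axes reduced by the layer thickness —
  which is exact for spheres and a close approximation for the mildly
  anisotropic ellipsoids used. Noise is Gaussian, not Rician: the
  background sits far above the noise floor, where the two coincide.
- Rendering grid: the default `c(1, 1, 1.3)` mm is the native MR
  resolution (1 mm in-plane, 1.3 mm slices at 1.5 T). Passing
  `c(0.5, 0.5, 0.5)` renders directly at the analysis resolution.

Two standard experiments use different rendering grids on purpose. The
*recovery* experiment (12 exams, artifacts and noise off or noise at 10 %
of background) renders at 0.5 mm so that resampling is the identity and
edges are crisp: recovery then isolates the threshold rule itself, which
is exact on noise-free data and FP-floor-limited under noise. The
*directional-bias* experiment (12 exams, PSF 1.0 mm, layer 0.4 mm, noise
on) renders at the native grid and exercises the full clinical pipeline
including interpolation; its expected signature is CT ≥ truth per segment,
MR ≤ CT per segment (noise off), negative pooled Bland–Altman bias,
MR-on-CTA slope < 1 and high pooled r. Rendering anisotropically *and*
noise-free is a regime the rule handles poorly — with no noise, the pass-2
σ collapses to the interpolated edge spread and the threshold climbs into
the edge ramp, overestimating volumes substantially. Real acquisitions
always carry noise, which keeps the threshold pinned near μ − kσ of the
noise distribution; the phantoms mirror that.

What passing these tests does *not* show: performance on real anatomy
(curved, branching, stenosed vessels), registration-free comparability of
truly independent CT and MR exams, field-strength-dependent susceptibility
physics, beam hardening, or reader behaviour. The phantoms share only the
statistical structure the analysis assumes.

## Agreement statistics

All estimators are closed-form and deterministic:

- Pearson r with the Fisher-z interval (`tanh(atanh r ± z₁₋α/₂/√(n−3))`);
  at |r| = 1 the interval degenerates to the estimate.
- ICC(A,1): two-way random effects, single measurement, absolute
  agreement, from the two-way ANOVA mean squares, with the McGraw–Wong
  F-based interval. This form is used because "agreement" is meant as
  distinct from correlation: a constant offset between MR and CTA lowers
  ICC while leaving r at 1.
- Bland–Altman: differences are MR − CTA; limits are bias ± 1.96 SD (n−1).
- Weighted Cohen's κ on the fixed 1–5 scale with linear distance weights
  |i−j|/4 (quadratic available), CI from the Fleiss–Cohen–Everitt
  large-sample variance. Linear weights are the conventional default for
  ordinal Likert data.
- Interpretation scale as half-open intervals: (−∞, 0.40) poor,
  [0.40, 0.60) fair, [0.60, 0.75) good, [0.75, ∞) excellent — the printed
  clinical scale is gapped (0.40–0.59, 0.60–0.74), and half-open intervals
  give every real value exactly one label consistent with it.

Segments are treated as independent units in all confidence intervals, as
in the clinical analysis this package models; within-patient correlation
of segments is not modelled, and the CIs are accordingly anti-conservative
for clustered data.

The test suite checks every estimator against independent brute-force
oracles (explicit sum formulas, an `aov()`-based ANOVA table, an explicit
contingency tabulation) to 1e-10 on random inputs, and the rating
generator against the closed-form κ of its known confusion structure.

## Projections

Axis-aligned thin-slab MinIP/MIP uses direct voxel min/max over the slab —
bit-exact, hence the tested algebraic properties (per-pixel bounds,
monotonicity in thickness, split-slab associativity). Oblique normals
resample planes through the volume by trilinear interpolation and require
an isotropic grid. Default slab thickness is 8 mm, the middle of the 4–15
mm display range; the slab centre defaults to the volume centre or the
centroid of a supplied calcium mask.

## The stack-of-stars ordering experiment

The simulator models the hybrid trajectory exactly at desk scale: each
acquired line is the analytic Fourier sample set of the object *as it is
at that line's timestamp*, along a radial spoke (uniform angles over π) at
one Cartesian through-plane frequency. Motion is a feathered central
sub-region translating sinusoidally in-plane (amplitude 3 mm, period 4 s)
between static bright "vessel" rods. Reconstruction is the standard
two-stage adjoint: inverse DFT across partitions, then |k|-ramp
density-compensated gridding per slice (DC weight Δk/4; no iterative
reconstruction). Ghost energy is the reconstructed energy outside the
dilated static support over the energy inside.

The loop orders differ only in how time maps onto k-space. The artifact
contrast requires the timing asymmetry of the real protocol, where views
far outnumber partitions (~1200 vs ~40–128): the legacy views-inner single
shot then spans *seconds* per partition — longer than a bowel-motion
period — so partitions are mutually inconsistent and the moving region
ghosts coherently along the partition direction across the whole field,
while the updated partitions-inner block lasts a fraction of a period,
freezing the object per view and relegating motion to incoherent low-level
angular streaks. The package defaults (`n_views` 96, `n_partitions` 12,
`line_time` 0.08 s → view block ≈ 7.7 s ≈ 2 periods, partition block
≈ 0.96 s ≈ period/4) reproduce that regime at desk scale; with symmetric
loop durations (e.g. equal-length fast loops) the contrast shrinks and can
even invert, because in-plane streaks from angular inconsistency then
outweigh the absent partition ghosts. With zero motion amplitude the two
orderings yield identical reconstructions (their line sets are
permutations), which the suite asserts to 1e-9.

## Problem sizes and determinism

The standard experiments use 12-exam cohorts on grids of roughly
105×53×217 voxels (analysis resolution) and a 48×48×12 or 64×64×12
simulator grid with 96 views — sizes chosen so every experiment runs in
seconds to a few minutes on one CPU while keeping ≥ 10⁵-voxel ROIs for the
tail-probability checks. Every random stage (phantom sampling, rendered
noise, rating simulation, k-space noise) is seeded explicitly and restores
the caller's RNG state; identical seeds give bit-identical outputs, which
the demo pipeline asserts end to end.

## Known limitations

- Straight-cylinder vessels and axis-aligned ellipsoid deposits only; no
  registration between modalities (comparisons are per-segment, not
  per-voxel).
- The MR rule's false-positive floor and its high-burden identifiability
  limit are inherent to background-relative thresholding (see above).
- The analytic erosion of the MR dark core is exact only for spherical
  deposits.
- The SoS simulator omits pulse-sequence timing realism (TR/TE, in-phase
  echo condition), coil sensitivities, golden-angle schedules and
  susceptibility physics; its finding is the ordering contrast, not
  absolute artifact magnitudes.
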