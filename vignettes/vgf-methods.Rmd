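---
title: "Quantifying volumetric glandular fraction from cone-beam breast CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying volumetric glandular fraction from cone-beam breast CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dedicated cone-beam breast CT (CBBCT) images the uncompressed pendant
breast with a point X-ray source and a flat-panel detector rotating a full
360 degrees around it. Because the reconstruction is fully 3D at isotropic
resolution, it supports a quantitative density measure: the volumetric
glandular fraction (VGF), the volume of fibroglandular tissue divided by
the total breast volume (fibroglandular + adipose) after excluding the
skin. Breast density is an established breast-cancer risk factor, so a VGF
that is *reproducible across reconstruction algorithms* matters: risk
models calibrated on standard filtered-backprojection images should remain
valid when scanners move to low-dose iterative or learned reconstructions.

This package implements the full computation chain needed to study that
question under controlled conditions: synthetic breast phantoms with exact
ground truth stand in for patient projection data, which are not publicly
available. Every stage - projection, reconstruction, segmentation,
statistics - is real, tested code; only the object being imaged is
synthetic.

## The phantom generator: what it emulates, and what it does not

`generatePhantom()` builds a pendant breast as a half-ellipsoid aligned to
the rotation axis: in-plane semi-axis `breast_radius_mm` (default 45 mm)
and axial semi-axis `chestwall_to_nipple_mm` (default 80 mm), values scaled
from clinical cohort statistics (chest-wall diameter 13.1 ± 2.3 cm,
chest-wall-to-nipple 9.7 ± 2.8 cm) to fit the default 96³ grid at 1.1 mm
pitch. A skin shell of `skin_thickness_mm` (default 1.5 mm) is carved by
morphological erosion; its discrete thickness is `round(t / pitch)` voxels,
at least one. Fibroglandular tissue is a union of randomly placed spheres
(radii 3-10 mm), accepted or rejected until the realized VGF is within
0.05 of the target; overshooting placements are rejected, and after 100
fresh attempts the target is declared unreachable. This gives exact label
bookkeeping - `true_vgf` is a voxel count ratio, not an estimate.

Attenuation defaults are adipose 0.22, fibroglandular 0.28, skin
0.30 cm⁻¹, inside the display window conventionally used for CBBCT
attenuation images ([0.21, 0.33] cm⁻¹); published tissue-level values are
not part of the display convention, so these are representative choices,
fixed once. Per-phantom target VGFs in cohort studies are drawn uniformly
from [0.08, 0.45], inside the clinically reported VGF range of roughly
0.04-0.5.

What the phantom does *not* emulate: ductal trees and realistic glandular
texture, polyenergetic beam hardening, scatter, detector blur and
electronic noise, motion. Passing the end-to-end tests therefore shows the
*pipeline* recovers known composition under ideal-physics projections with
Poisson noise; it does not validate the segmentation against anatomically
realistic texture.

## Geometry and projection model

The scan geometry is a circular full-scan trajectory: source at
`sid_mm = 650`, detector at `sdd_mm = 923` (representative CBBCT
proportions; the clinical system's distances are unpublished), view angles
equally spaced on [0°, 360°). Two profiles are provided: a desk-scale
default (120 views, 128 × 128 detector at 1.6 mm) that keeps a full study
in minutes on one CPU, and `clinicalGeometry()` (300 views, 0.388 mm
detector elements) matching the published acquisition.

The forward model is monoenergetic: line integrals of attenuation (cm⁻¹)
along source-to-detector-cell rays, sampled with trilinear interpolation
at a step of half the voxel pitch. The matched backprojector is the exact
matrix transpose (same samples, same weights), so the operator pair passes
an adjoint identity at numerical precision - a property OS-SART relies on.
Noise is applied after the line integral: transmitted counts are
Poisson with mean `photons_per_ray * exp(-p)`, clamped at one count, and
re-logged. There is no electronic-noise term; this is the simplest model
that produces the variance structure the denoising comparisons need.

Coordinate conventions (right-handed frame, isocenter at the volume
center, detector axes u in-plane / v axial, angles counterclockwise from
+z) are documented once in `src/raytrace.cpp` and used everywhere.

## FDK reconstruction

`fdkReconstruct()` is the standard Feldkamp-Davis-Kress chain: cosine
weighting `D / sqrt(D² + u² + v²)`, row-wise ramp filtering on the virtual
detector through the isocenter, and voxel-driven backprojection with the
`(sid / (sid - s))²` distance weight scaled by half the angular increment.
The ramp filter is built in the spatial domain - `r(0) = 1/(4Δ²)`,
`r(odd k) = -1/(πkΔ)²`, zero at even lags - and applied via FFT with
zero-padding to at least twice the row length, so the impulse response is
exactly the band-limited kernel. DC content in the interior of a row is
suppressed to below 1% of its level; the edges of a finite constant row
ring, as they must for any ramp implementation, which is irrelevant for
projections that taper to zero inside the field of view. The default
apodization is a Hann window (the clinical filter is unpublished;
Ram-Lak is available). On a noiseless uniform cylinder the central-slice
plateau is recovered to well under 1%.

## Iterative reconstruction (ASD-POCS with OS-SART)

`fristReconstruct()` follows the adaptive steepest descent - projection
onto convex sets scheme: each outer iteration applies one OS-SART pass
(ordered view subsets, round-robin by angle stride for angular balance,
fixed order for determinism), clamps negatives, then takes
`tv_steps_per_iteration` steepest-descent steps on smoothed isotropic
total variation (ε = 1e-8 guards the non-smooth point). Each TV sub-step
moves the image by exactly `α · ‖Δx_data‖` in Euclidean norm - the
original ASD-POCS balance between the data step and the regularity step.
The budget ratio α (default 0.2) is reduced by `alpha_red = 0.95` whenever
the data residual grows beyond a tolerated band (an increase by more than
a factor `1 / r_max = 1/0.95`); this progressively hands control back to
the data term as the iteration approaches the data-consistency set. These
adaptation constants are common literature values - the published
framework specifies the scheme, not the constants.

Desk-scale defaults are 20 iterations with 10 subsets and relaxation
λ = 1; high-quality clinical-scale reconstructions are reported at 80-100
iterations, and `fristConfig(clinical = TRUE)` sets 100. Initialization is
the FDK image of the same data, which removes most of the transient. With
`tv_steps_per_iteration = 0` and one subset the loop reduces exactly to
plain SART, which the tests exploit as an oracle equivalence.

## Half-view splitting

`splitProjections()` partitions views by 0-based acquisition index into
even and odd halves (a 300-view scan gives 150 + 150), and `splitFDK()`
reconstructs each half - the data preparation used by Noise-to-Noise
self-supervised denoising, which trains on pairs of independently noisy
images of the same object. The trained network itself (and the fully
supervised multi-scale residual dense network) is out of scope here:
`splitMean()`, the voxel-wise average of the pair, serves as the
deterministic surrogate "fourth method" in comparisons, and its
`SPLIT_MEAN` tag records the substitution. One consequence worth stating
plainly: because FDK is linear and filters each view independently, the
average of the two interleaved half-scan reconstructions equals the
full-scan FDK *exactly*. The surrogate therefore preserves the pipeline
topology and the noise bookkeeping of the halves (independent noise,
variance halving in the mean), but adds no nonlinear behavior of its own.

## Segmentation and VGF

Segmentation operates on the reconstruction in three steps.
`breastMask()` thresholds against air (default 0.1 cm⁻¹, about half of
adipose), keeps the largest 6-connected component, and closes it
morphologically. `removeSkin()` erodes the mask by
`ceiling(skin_thickness / pitch)` voxels; the end-to-end wrapper
`segmentVolume()` erodes one extra voxel by default because the
reconstruction kernel spreads the bright skin shell about one voxel
inward - without the margin, blurred skin voxels contaminate the interior
and bias VGF upward.

`kfcmSegment()` then clusters the interior intensity vector with
two-cluster kernel fuzzy C-means using a Gaussian kernel
`K(x, v) = exp(-(x - v)²/σ²)` on voxel intensity only - deliberately no
spatial regularization, since voxel intensity is the stated feature.
`σ = "auto"` uses the standard deviation of the interior intensities,
which also makes the labels invariant to increasing affine intensity
rescalings. The fuzzifier defaults to m = 2. Centers are initialized
deterministically at 25% and 75% of the robust intensity range (1st-99th
percentile): an initialization at intensity *percentiles of mass* (e.g.
the 25th/75th percentiles of the data) was evaluated first and fails for
strongly imbalanced tissue fractions - in an almost entirely fatty breast
both percentiles fall inside the adipose mode, and the algorithm converges
to a split of the adipose noise peak rather than the tissue modes.
Range-based initialization places one center near each mode regardless of
class balance and leaves the balanced case unchanged. Hard labels go by
maximum membership, ties to adipose (the conservative, lower-density
call); the higher center is fibroglandular. VGF is the hard-label count
ratio, excluding skin and air from both numerator and denominator.

On the default desk-scale conditions (96³ phantom, 120 noisy views at 1e5
photons/ray, FDK + Hann), the end-to-end absolute VGF error is well inside
the ±1.9 percentage-point accuracy envelope established for this
segmentation approach on physical phantoms; `scripts/acceptance.R`
recomputes this from scratch.

## Statistics

`compareMethods()` reproduces the clinical analysis pipeline on a matched
phantoms × methods VGF matrix: per-method median/IQR/range summaries,
Shapiro-Wilk normality per method (delegated to the standard library
routine), then the omnibus test chosen by the rule *any method non-normal
at α = 0.05 → Friedman, else repeated-measures ANOVA*. The any-rule
matches the clinical analysis path, where all four reconstructions
rejected normality. Friedman is implemented in-package with within-row
mid-ranks and the standard tie-correction factor (the base-library
implementation omits the correction; the two agree exactly on tie-free
data, which the tests check). Rows that are entirely tied carry no
information and yield statistic 0, p = 1. On the Friedman path, Dunn's
post-hoc comparisons are restricted to the k−1 comparisons against the
control reconstruction, `z = (R̄_j − R̄_c) / sqrt(k(k+1)/(6n))` on mean
ranks with Bonferroni adjustment capped at 1; the exact multiplicity
family used by commercial statistics packages is not standardized, so it
is surfaced as an option (`adjust = "none"` available). Adjusted p-values
above 0.999 are displayed as ">0.999". Every choice is written into the
report's decision trail.

`runReproducibilityStudy()` wires the whole chain together on a seeded
cohort: identical projections per phantom feed every method, which is what
makes the matched design (and Friedman's within-row ranking) appropriate.

## Numerical and design choices

- **Problem sizes.** Module tests run at 32³-64³ grids with 60-120 views;
  the end-to-end accuracy condition runs at 96³ with 120 views; the
  cohort study uses twenty 48³ phantoms. These are the package's desk
  defaults, chosen to keep a full study at the minutes scale on one CPU;
  clinical profiles (0.273 mm pitch, 300 views, 100 iterations) are
  reachable through configuration but not exercised by the tests.
- **Determinism.** All randomness is routed through explicit seeds; the
  pipeline derives per-stage seeds as
  `seed·7919 + stage_code·1299709 + id·104729 (mod 2³¹-ish prime)`, so any
  stage can be re-run in isolation from the manifest.
- **Degenerate inputs.** Zero volumes project to zero; constant rows
  ramp-filter to zero; constant volumes have zero TV gradient (descent is
  a no-op); constant intensity vectors are rejected by KFCM and the
  normality test with explicit errors; empty masks and over-eroded masks
  fail loudly.
- **Ties.** KFCM membership ties label as adipose; Friedman uses
  mid-ranks with tie correction; fully tied rows give p = 1.
- **Known limitations.** No scatter/beam-hardening/detector blur in the
  forward model; the skin-removal operator is plain erosion with a
  configurable thickness (the clinical skin-segmentation method is not
  published in detail, and the interface accepts a drop-in replacement);
  VGF uses hard labels, not partial-volume memberships; the learned
  reconstruction methods are represented only by the split-mean surrogate.
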