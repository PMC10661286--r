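# cbbctVGF

Volumetric glandular fraction (VGF) from dedicated cone-beam breast CT
reconstructions, end to end: synthetic pendant-breast phantoms with exact
ground truth, cone-beam projection with Poisson noise, analytical and
iterative reconstruction, kernel fuzzy C-means tissue segmentation, and the
nonparametric repeated-measures statistics used to ask whether VGF is
reproducible across reconstruction algorithms.

## Who this is for, and why

Breast density is an established breast-cancer risk factor. Cone-beam
breast CT (CBBCT) images the uncompressed pendant breast fully in 3D, so
density can be quantified directly as the **volumetric glandular
fraction**,

```
VGF = Vg / (Vg + Va)
```

the fibroglandular tissue volume over the total breast volume
(fibroglandular + adipose) after excluding the skin. As scanners move from
the standard Feldkamp–Davis–Kress (FDK) filtered backprojection toward
low-dose iterative and learned reconstructions, risk models calibrated on
FDK-derived VGF are only portable if VGF is reproducible across
algorithms. This package provides a tested simulation-and-analysis
pipeline for studying exactly that question on phantoms with known
composition — useful to researchers developing CBBCT reconstruction or
density software who need ground truth that patient data cannot provide.

## What is implemented

- **Phantoms** (`phantomSpec()`, `generatePhantom()`): half-ellipsoid
  pendant breast, thin skin shell, fibroglandular tissue as random soft
  spheres placed until a target VGF is met; exact voxel-count ground truth.
- **Projection** (`makeGeometry()`, `forwardProject()`,
  `addPoissonNoise()`): circular full-scan cone-beam geometry, ray-driven
  line integrals (Rcpp), exactly matched adjoint backprojector, Poisson
  transmission noise.
- **FDK** (`fdkReconstruct()`): cosine weighting, FFT ramp filtering
  (Hann or Ram-Lak), weighted voxel-driven backprojection.
- **Iterative reconstruction** (`fristReconstruct()`): ASD-POCS scheme —
  OS-SART data steps over ordered view subsets, steepest-descent steps on
  smoothed total variation with an adaptive step balance, non-negativity,
  FDK initialization.
- **Half-view splitting** (`splitProjections()`, `splitFDK()`,
  `splitMean()`): odd/even view partition and paired half-scan FDK
  reconstructions — the data preparation of Noise-to-Noise self-supervised
  denoising — with the split mean as a deterministic surrogate method.
- **Segmentation** (`breastMask()`, `removeSkin()`, `kfcmSegment()`,
  `segmentVolume()`): air thresholding + largest component, skin erosion,
  two-cluster kernel fuzzy C-means on voxel intensity, hard labels, VGF.
- **Statistics** (`compareMethods()`, `runReproducibilityStudy()`):
  median/IQR/range summaries, Shapiro–Wilk normality per method,
  Friedman's test (with tie correction) or repeated-measures ANOVA chosen
  by the normality screen, and Dunn's post-hoc comparisons against the
  control reconstruction.
- **Pipeline** (`pipelineConfig()`, `runPipeline()`): seeded, resumable
  orchestration writing NIfTI volumes, `vgf.csv`, `report.json`, and a
  manifest; a thin CLI lives at `inst/cli/cbbct`.

## Worked example

A desk-scale run (48³ voxels, 60 views, ~20 s on one CPU):

```r
library(cbbctVGF)

spec <- phantomSpec(grid_shape = c(48, 48, 48), voxel_pitch_mm = 2.2,
                    target_vgf = 0.25, seed = 42)
ph <- generatePhantom(spec)
ph
#> LabeledVolume: 48 x 48 x 48 voxels @ 2.2 mm
#>   voxels: air 78772, skin 4532, adipose 21614, fibroglandular 5674
#>   true VGF: 0.2079

geom <- makeGeometry(views = 60, rows = 96, cols = 96,
                     detector_pitch_mm = 2.13)
proj <- addPoissonNoise(forwardProject(ph, geom), photons_per_ray = 1e5,
                        seed = 7)
rec <- fdkReconstruct(proj, dim(muVolume(ph)), voxelPitch(ph))
seg <- segmentVolume(rec)
seg
#> SegmentationResult: VGF = 0.2217 (Vg 5234 / Va 18375 voxels)

abs(seg@vgf - trueVGF(ph))
#> 0.0138   # 1.38 percentage points
```

The phantom's `true VGF` is an exact voxel count (the sphere placement
stops inside a ±0.05 band around the requested target, hence 0.208 for a
0.25 target). The estimated VGF comes from the full chain — noisy
projections, FDK reconstruction, skin removal, KFCM clustering — and here
lands within 1.4 percentage points of truth. At the package's default
scale (96³ voxels, 128² detector) the error over ten seeded phantoms
ranges from about 0.4 to 1.3 points.

For a full method comparison:

```r
st <- runReproducibilityStudy(cohort_size = 20, seed = 11)
st$report        # summaries, normality, omnibus test, Dunn post-hoc
```

## Scope notes

The forward model is monoenergetic with no scatter or detector blur; the
learned reconstruction methods studied in the CBBCT literature are
represented by the deterministic split-mean surrogate (training neural
networks is out of scope); clinical profiles (300 views, 0.388 mm
detector, 0.273 mm voxels, 100 iterations) are reachable via
configuration but the shipped tests run at desk scale. See
`vignettes/vgf-methods.Rmd` for the full model description, parameter
rationale, and limitations.
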