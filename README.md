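# lidmetrics

Automated eyelid morphometry from binary segmentation masks.

Oculoplastic assessment rests on a few standard photograph-derived
quantities: **MRD1** and **MRD2** (the vertical margin–reflex distances from
the corneal light reflex to the upper and lower eyelid margins), the
curvilinear **eyelid lengths** between the medial and lateral canthi, the
**corneal outer-boundary length**, and — for curved-lid pathology such as
thyroid eye disease (elevated MRD1) or ptosis (reduced MRD1) — the full
**contour** of the palpebral fissure. Measuring these by hand is slow and
rater-dependent. `lidmetrics` implements the measurement geometry that turns
segmentation masks (sclera, cornea, light reflex, and a 9.0 mm forehead
calibration marker), whatever produced them, into calibrated millimetre
measurements and a contour-based abnormality screen. It is aimed at
researchers building or validating automated eyelid-analysis pipelines.

The core pieces:

* **Calibration** — mm/px from the marker's equivalent-circle diameter:
  `mm_per_px = 9.0 / (2√(A/π))`.
* **Quadrant (corner-corrected) digital length** — boundary lengths are
  measured on the taut polygon of the pixel-edge ("crack") boundary, with
  every 90° corner replaced by a quarter-circle arc of radius 0.5 px
  (length π/4). A single pixel measures π (a circle of diameter 1), a 2×2
  block 4 + π, and digitized disks converge to πd (≤ 1% error from radius
  50 px). This avoids the √2 staircase bias of raw pixel perimeters that
  makes digital lengths overshoot curved eyelids.
* **MRD1/MRD2** — vertical distances from the light-reflex centroid to the
  margin chains, interpolated at the reflex column.
* **Radial contour profile** — 360 one-degree rays from the intersection of
  the intercanthal line with its orthogonal through the reflex, in the frame
  rotated so the intercanthal line is horizontal; distance to the margin per
  degree, in mm.
* **Partition screening** — the 360 degrees grouped into
  k ∈ {4, 8, 16, 24, 32, 64, 128, 256} segments (90.0°…1.4° intervals);
  per-segment normative intervals mean ± 1.96·SD fitted on normals; any
  subject with one abnormal segment is flagged, and a sweep over k yields the
  sensitivity curve that motivates the conventional 24 partitions
  (15° intervals).
* **Agreement statistics** — ICC(2,1) with the poor/fair/good/excellent
  bands, and Bland–Altman mean difference with 95% limits of agreement.
* **Synthetic scenes** — an analytic eye (parabolic lids through both
  canthi, corneal and reflex discs, canthal tilt, marker) rasterized
  pixel-exactly, with ground truth computed from the curves, so every stage
  is validated against known geometry. Abnormalities are raised-cosine
  radial "bumps" addressable by degree.

## Worked example

```r
library(lidmetrics)

# a synthetic left eye: MRD1 3.0 mm, MRD2 6.0 mm, 4 degrees of canthal tilt
scene <- generateScene(sceneParams(mrd1Mm = 3.0, mrd2Mm = 6.0,
                                   canthalTiltDeg = 4))
res <- measureScene(scene)          # oracle backend: the scene's own masks
res$calibration
#> Calibration: marker 90.1 px = 9 mm -> 0.099888 mm/px
res$measurements
#> EyelidMeasurements (mm): MRD1 2.997  MRD2 5.993
#>   upper lid 28.78  lower lid 31.31  cornea boundary 12.85
```

The marker (90 px across at the true 0.1 mm/px) calibrates the scale; the
planted MRDs are recovered within 3 µm-per-px quantization, and the eyelid
lengths land within 1% of the analytic parabola arc lengths. The contour
profile reads 14.02 / 2.96 / 13.71 / 6.05 mm at 0°/90°/180°/270° — the two
canthus distances, MRD1-like height and MRD2-like depth of this fissure.

Screening a small cohort:

```r
cohort <- cohortProfiles(20, 2, seed = 7,
  variation = list(mrd1 = c(mean = 3.1, sd = 0.25),
                   mrd2 = c(mean = 5.8, sd = 0.25),
                   width = c(mean = 28, sd = 0.5), tilt = c(mean = 4, sd = 0.5)),
  bumpSpec = list(nBumps = 1L, widthDeg = 10, amplitudeRange = c(5, 7)))
model <- fitNormative(cohort$profiles[!cohort$isAbnormal], makeScheme(24))
flagAbnormal(cohort$profiles[[21]], model)
#> AbnormalityReport [S021]: ABNORMAL (1/24 segments)

verificationSweep(cohort$profiles, cohort$isAbnormal, ks = c(4, 8, 16, 24, 32))
#>    k interval_deg sensitivity specificity
#> 1  4         90.0         0.5        0.90
#> 2  8         45.0         1.0        0.85
#> 3 16         22.5         1.0        0.85
#> 4 24         15.0         1.0        0.85
#> 5 32         11.3         1.0        0.80
```

Subject S021 carries a 5.3 mm contour bump at 325°; the 24-partition screen
flags exactly the segment containing it. Sensitivity rises with partition
count and saturates by 8–24 partitions on this cohort; specificity is
computed empirically (the fitting normals can exceed their own ±1.96 SD band
about 5% of the time per segment).

The methods vignette (`vignettes/eyelid-morphometry.Rmd`) documents the
geometry, conventions, tolerance models and design choices in full.

## Command line

```sh
Rscript inst/cli/lidmetrics.R synth   --n-normal 10 --n-abnormal 2 --seed 7 --out scenes/
Rscript inst/cli/lidmetrics.R measure --scenes scenes/ --backend oracle --out results.csv
Rscript inst/cli/lidmetrics.R verify  --scenes scenes/ --ks 4,8,16,24,32,64,128,256 --out sweep.csv
Rscript inst/cli/lidmetrics.R run     --scenes scenes/ --out out/ --normative
```
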