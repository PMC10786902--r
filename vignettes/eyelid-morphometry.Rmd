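---
title: "Automated eyelid morphometry: models, conventions and design choices"
author: "lidmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated eyelid morphometry: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidmetrics)
```

## The measurement problem

Clinicians grade eyelid position with a handful of standard quantities:
MRD1 and MRD2 (the vertical distances from the corneal light reflex -- the
camera-flash glint on the cornea -- up to the upper and down to the lower
eyelid margin), the curvilinear lengths of the two eyelid margins between the
medial and lateral canthi, and, increasingly, the full contour of the
palpebral fissure. Diseases push these numbers in characteristic directions:
thyroid eye disease (Graves' orbitopathy) retracts the upper lid and raises
MRD1, ptosis drops it. Manual measurement on photographs is slow and
rater-dependent, so the pipeline implemented here takes binary segmentation
masks of the sclera, cornea, light reflex and a forehead calibration marker
-- however they were produced -- and turns them into calibrated millimetre
measurements and a per-degree contour screening test.

`lidmetrics` implements the measurement geometry, the contour model, the
normative screening, the method-comparison statistics, and a synthetic scene
generator that stands in for clinical photographs so that every stage can be
validated against exact analytic ground truth.

## Raster conventions

Masks are logical matrices in row-major image order: row 1 is the top image
row and y grows downward. Pixel $(r, c)$ (0-based) occupies the unit square
$[c, c+1) \times [r, r+1)$; its center is $(r + 0.5, c + 0.5)$. Boundary
("crack") vertices live on the integer corner lattice. "Vertical" always
means the image column direction: the acquisition protocol keeps the head
upright and no pose correction is attempted. All exported points are
`c(row, col)` in these coordinates.

## Preprocessing

Photographs arrive as $1200 \times 797$ RGB frames with one eye in each
vertical half and the calibration marker in the middle half of the width.
`splitImage()` cuts columns $[0, \lfloor W/2 \rfloor)$ and
$[\lfloor W/2 \rfloor, W)$ for the eyes and
$[\lfloor W/4 \rfloor, \lfloor 3W/4 \rfloor)$ for the marker crop.
`resizeWithPadding()` produces the square $512 \times 512$ network input:
the longer side is scaled to 512, the shorter side by the same factor
(rounded to the nearest pixel), the content anchored top-left, and the
remainder zero-padded on the right or bottom. The returned transform inverts
the operation exactly; masks travel back with nearest-neighbour resampling
(`maskToOriginal()`) so they stay binary. All measurement happens in
original-image coordinates after that inversion, so the marker calibration
and the eye measurements share a single scale. (Whether measurement is done
in resized or original coordinates is a free choice; original coordinates
avoid compounding two resamplings.)

## Segmentation backends

Measurement is decoupled from segmentation by a backend contract
(`segmentTargets()`): a backend returns one binary mask per requested class.
Three desk-scale backends ship: the *oracle* (the synthetic scene's own
masks), a *color-rule* backend (nearest reference color on the flat-color
rendering, largest-component cleanup, with reflex-colored pixels counted as
cornea since the glint sits on the cornea), and an *external* backend that
reads mask PNGs from a directory. A trained semantic-segmentation network
would plug in behind the same contract; none ships here because no weights
are distributable. Masks are scored with `meanIoU()` (per-class
intersection-over-union, empty-union classes scoring 1 by the vacuous
convention). Before measurement each mask is reduced to its largest
8-connected component, since every class is a single anatomical object.

## Millimetre calibration

The physical reference is a circular forehead sticker of known 9.0 mm
diameter. Its pixel diameter is estimated as the equivalent-circle diameter
$2\sqrt{A/\pi}$ of the segmented marker -- more robust to single-pixel
boundary noise than a Feret diameter -- and the scale is
`mm_per_px = 9.0 / diameter_px`. Every downstream millimetre quantity is a
pixel quantity times this one number, so measurements are invariant to the
acquisition scale (tested at 0.08--0.125 mm/px).

## Digital length: the quadrant (corner) correction

Summing pixel-edge lengths along a digitized boundary overestimates smooth
curves badly: a 45-degree run costs $|\cos\theta| + |\sin\theta| = \sqrt 2$
times its true length, and no local corner patch on the raw crack edges can
repair that bias for all slopes. The package therefore measures lengths on
the *taut polygon* of the crack boundary -- the convex hull of the boundary
vertices, the classical convergent perimeter estimator for digitized convex
shapes -- and then applies the quadrant correction: every 90-degree corner of
the polygon (two adjacent half-edges, total 1 px) is replaced by a
quarter-circle arc of radius 0.5 px, length $\pi/4$. The rule is pinned by
its limits: a single pixel becomes a circle of diameter 1 (perimeter
$\pi$), a $2 \times 2$ block a rounded square ($4 + \pi$), a straight chain
keeps its length, and digitized disks converge to $\pi d$ (relative error
0.98% at radius 50 px, 0.27% at 200 px, shrinking like the half-pixel
digitization inflation $\approx 0.5/R$).

Open margin chains are measured the same way: the hull path between the two
chain endpoints on the chain's side of the hull, with the corner rule applied
to its interior turns (`marginLength()`). Eyelid margins and the corneal
outline are convex by anatomy, which is what makes the taut polygon the right
substrate; a pathological concavity is bridged by the hull, so margin length
is a lower bound there. The contour screening below, not the margin length,
is the tool that detects such deformations.

## From masks to measurements

`measureEye()` runs the pipeline for one eye:

1. corneal outer boundary length = quadrant perimeter of the cornea mask
   times the scale;
2. palpebral fissure = hole-filled union of the sclera and cornea masks;
3. canthi = horizontal endpoints of the sclera (vertically median pixel in
   the extreme column on ties), labeled medial/lateral by an eye-side tag
   (for an unmirrored photo of the left eye the lateral canthus is
   image-left);
4. margins: the fissure's crack boundary is cut at the two canthus vertices
   (each canthus snapped to the column-extreme boundary vertex within 2 px,
   so the cut point is the tip of the canthal wedge); the sub-chain holding
   the topmost vertex is the upper margin;
5. eyelid lengths = corner-corrected taut lengths of the two margins;
6. the light-reflex center = foreground centroid of the reflex mask;
7. MRD1/MRD2 = vertical distances from that center to the margins along its
   image column, linearly interpolated along the chains.

An absent light reflex is an error, not a silent zero (such photographs are
excluded from acquisition), and a reflex covered by the upper lid (negative
MRD1 beyond one pixel) is out of measurement range by design. On synthetic
scenes the recovered MRDs sit within 2 px-equivalents of the analytic truth
and margin lengths within 3% (typically 0.06 mm and 0.7% at 0.1 mm/px).

## The radial contour profile

Linear metrics miss curvature. The contour model samples the fissure
boundary at one-degree resolution about the *intercanthal reference frame*:
the intercanthal line joins the two canthi; the line orthogonal to it through
the light reflex meets it at the reference origin; the frame is rotated so
the intercanthal line is horizontal (real faces carry a canthal tilt, with
the lateral canthus usually higher). For each degree $d$, a ray cast from
the origin (0 degrees toward the lateral canthus, 90 toward the upper lid,
counterclockwise in the rotated frame) measures the distance to the margin
polyline in millimetres. Degrees 0 and 180 therefore measure the two
canthus distances, and MRD1/MRD2 are deliberately *not* part of the profile.

Two origin conventions circulate: the foot of the reflex perpendicular and
the intercanthal midpoint. They coincide for a reflex centered between the
canthi and differ otherwise; the package defaults to the reflex-foot
definition and exposes `origin = "intercanthal_midpoint"` as a switch.
Profiles are compared in raw millimetres with no per-subject size
normalization -- a documented caveat: a large normal eye can exceed a
normative band fitted on small eyes.

### Quantization tolerances

Comparing profiles across rasterizations (e.g. under a global scene
rotation) needs a tolerance model, not a single number. The radial error at
degree $d$ is the boundary displacement (up to about 1 px per rasterization,
2 px when two independent rasters are compared) divided by
$\sin\psi(d)$, where $\psi$ is the angle between the ray and the margin
tangent ($\tan\psi = \rho / (d\rho/d\theta)$ from the polar curve). Near the
canthi the rays graze the margin and the tolerance widens accordingly. A
second term covers the frame direction itself: each canthus vertex is
quantized by up to a pixel, tilting the frame by up to $2q/W$ radians
($W$ = intercanthal width in px) and acting through the polar slope. Under
this model a 10-degree rigid rotation of the whole synthetic eye changes no
measured profile value by more than the per-degree tolerance (observed
maximum deviation about 0.34 mm, at the canthus where the tolerance is
widest; away from the canthi deviations stay near 2 px-equivalents).

## Partitions and normative screening

The 360 degrees are grouped into $k$ equal segments
(`makeScheme(k)`; segment $i$ covers $[\,i \cdot 360/k, (i+1) \cdot 360/k)$).
The base case $k = 4$ is exactly the four quadrants cut by the intercanthal
line and its orthogonal; the conventional sweep is
$k \in \{4, 8, 16, 24, 32, 64, 128, 256\}$, i.e. intervals of 90.0, 45.0,
22.5, 15.0, 11.3, 5.6, 2.8 and 1.4 degrees (printed to one decimal, halves
away from zero: $360/32 = 11.25 \to 11.3$). A segment's value is the mean of
its member degrees' distances (the aggregation is a design choice; per-degree
screening is the $k = 360$ scheme).

`fitNormative()` fits, per segment, the normal cohort's sample mean and SD
($n-1$ denominator) and accepts values in mean $\pm z \cdot$SD with
$z = 1.959964$ (the central 95% range of a normal distribution). Because
"95% range" could equally mean empirical percentiles,
`method = "percentile"` fits the 2.5--97.5 percentile interval instead. A
segment outside its interval is abnormal; a subject with at least one
abnormal segment is an abnormal subject (`flagAbnormal()`).
`verificationSweep()` repeats the fit-and-flag experiment over the $k$ sweep
and reports sensitivity (flagged abnormals over all abnormals) and empirical
specificity. Under the labeling convention in which the normals *define* the
range, no false positives are possible by construction; the package computes
specificity empirically rather than asserting it, and on finite cohorts the
fitting normals do occasionally exceed their own $\pm 1.96$ SD band
(per-segment flag rate just under 5%, as expected).

### Sizing the planted abnormalities

With mean aggregation, a raised-cosine bump of width $w = 10^\circ$ and
amplitude $a$ contributes $a \cdot w/2 = 5a$ degree-millimetres; fully inside
a 15-degree segment it shifts the segment mean by $a/3$. Flagging a subject
whose own baseline deviates by $\sim N(0, \sigma)$ against a
$1.96\sigma$ band therefore needs $a/3 \gtrsim (1.96 + 4)\sigma$, i.e.
$a \gtrsim 18\sigma$, for the flag to be guaranteed rather than merely
likely; at $a = 10\sigma$ about 9% of subjects escape. The detection
experiments accordingly plant bumps of 5--7 mm amplitude against a cohort
whose per-segment SD is about 0.25--0.35 mm -- clinically the scale of severe
retraction or ptosis. A bump straddling a segment boundary splits its energy
between two segments; the single-segment guarantee applies to contained
bumps, while straddling ones are caught at finer partitions (the sensitivity
curve rises monotonically in $k$ and saturates from 16--24 partitions under
these conditions, mirroring the conventional choice of 24 partitions /
15-degree intervals).

## Agreement statistics

Validating an automated method against a reference rater uses ICC and
Bland-Altman machinery. `iccAgreement()` computes single-measure ICC from
the two-way mean squares -- ICC(2,1), absolute agreement, by default, since
interchangeability of two measurement systems is the question; the
consistency variant ICC(3,1), which forgives a constant offset, is available
via `type = "consistency"`. Bands follow the conventional cutpoints (poor
< 0.40, fair 0.40--0.60, good 0.60--0.75, excellent 0.75--1.00). The
implementation is cross-checked in the tests against an independent
reference implementation on a frozen fixture. `blandAltman()` returns the
mean difference, the 95% limits of agreement (mean $\pm 1.96$ SD of the
paired differences) and a t-based CI for the mean difference;
`pairedCompare()` reports both the Wilcoxon rank-sum and the paired t-test,
since both circulate for this comparison and the choice depends on the
difference distribution.

## The synthetic scene generator

`generateScene()` replaces clinical photographs: a palpebral fissure bounded
by two parabolas through both canthi (apexes `mrd1Mm` above and `mrd2Mm`
below the light reflex), a corneal disc and central reflex dot, a canthal
tilt elevating the lateral canthus, and the 9.0 mm marker disc on the
forehead. Abnormalities are raised-cosine radial deformations ("bumps") of
the fissure boundary in polar coordinates about the reference origin --
localized, smooth and addressable by degree. Masks are exact rasterizations
(a pixel is foreground iff its center is inside the analytic region); ground
truth (true MRDs, analytic arc lengths by fine quadrature on a 0.025-degree
grid, the exact 360-degree polar profile, abnormal degrees, canthus
positions) is computed from the curves, never from the rasters. A
`rotationDeg` parameter rigidly rotates the eye geometry for equivariance
checks; the analytic profile is exactly rotation-invariant by construction.

Default conditions are a $1200 \times 797$ px frame at 0.1 mm/px with a
normal adult fissure (MRD1 3.0, MRD2 6.0, width 28 mm). Cohort generation
(`generateCohort()`, or the memory-lean streaming variant
`cohortProfiles()`, which derives identical per-scene seeds) jitters MRD1/
MRD2/width/tilt per subject; the default jitter follows the normal-population
spreads (MRD1 $3.1 \pm 0.8$, MRD2 $5.8 \pm 1.1$ mm), truncated below so the
reflex stays visible and the corneal disc stays inside the aperture --
mirroring the acquisition rule that photographs without a visible reflex are
excluded.

Two deliberate idealizations matter for interpreting test results. First,
the default corneal disc (2.0 mm radius) is smaller than a real cornea so
that it is fully visible and its true boundary length is an exact
circumference; the *morphometry-validation* cohort instead uses the
anatomically realistic 5.5 mm radius inside a correspondingly deep fissure
(MRD1 $6.5 \pm 0.8$, MRD2 $7.5 \pm 1.1$ mm), because a 2% boundary-length
check is only meaningful for an unoccluded disc and the half-pixel
digitization inflation alone is $\approx 0.5/R$ (2.5% at 20 px, 0.9% at
55 px). In real photographs the lids occlude the upper and lower cornea and
the measured outline is the visible (clipped) boundary. Second, the
*detection* cohort uses tight jitter (per-segment SD $\approx$ 0.3 mm) so
that planted bumps are an unambiguous $\gtrsim 18\sigma$ signal; real
populations vary several times more, and detection power there depends on
effect size relative to that variability. Passing tests demonstrate the
geometry and the screening machinery, not photographic segmentation
performance -- flat-color rendering with optional Gaussian noise has none of
the texture, lash shadows, specular gradients or pose variation of clinical
images.

## Numerical choices and degenerate inputs

* Partition arithmetic is exact for $k \mid 360$; other $k$ get segments
  differing by at most one degree via $\lfloor d \cdot k/360 \rfloor$.
* Canthus ties (several foreground pixels in an extreme column) resolve to
  the vertically median pixel; vertex snapping ties resolve by distance,
  then row, then column -- deterministic reruns are bit-identical.
* A zero-SD normative segment accepts only exact equality with its mean.
* Empty masks error early with the offending structure named; a multi-part
  mask is reduced to its largest component with a warning.
* Scene I/O is lossless for masks (0/255 PNG) and truth (JSON at full float
  precision); `runPipeline()` is fail-soft per subject, recording failures
  in the manifest while the batch continues.
* Problem sizes in the shipped experiments -- 50 validation scenes, a
  100 + 20 detection cohort, disks up to radius 200 px -- were chosen so the
  full suite exercises every guarantee at desk scale.

## Known limitations

* Margin length is hull-based and thus a lower bound across concave
  deformations; the contour profile is the detection tool there.
* Raw-millimetre profiles are not size-normalized across subjects.
* The normative experiment fits on labeled normals; pooling patients into
  the fit (the ambiguity in "the normal distribution for 300 subjects") is
  possible by passing the full profile list to `fitNormative()`.
* No pupil-center fallback exists when the light reflex is absent, and
  negative MRD1 is out of range.
* The color-rule backend is a desk-scale stand-in tied to the renderer's
  palette; real images need a trained segmentation model behind the backend
  contract.
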