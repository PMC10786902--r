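# Shared fixtures, built in code.

# compact frame for unit tests: same scale and fissure as the full frame,
# smaller canvas so mask operations stay fast
smallParams <- function(...) {
  sceneParams(imageWidthPx = 600L, imageHeightPx = 420L,
              eyeCenter = c(260, 160), markerCenter = c(70, 450), ...)
}

# pixel-center digitization of a disk of radius R px
rasterDisk <- function(R, side = 2 * ceiling(R) + 20) {
  ctr <- side / 2
  i <- seq_len(side) - 0.5
  outer((i - ctr)^2, (i - ctr)^2, `+`) < R^2
}

# crack (pixel-edge) perimeter: number of foreground/background adjacencies
crackPerimeter <- function(mask) {
  m <- mask
  padded <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  padded[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  inner <- padded[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)]
  sum(inner & !padded[1:nrow(m), 2:(ncol(m) + 1L)]) +
    sum(inner & !padded[3:(nrow(m) + 2L), 2:(ncol(m) + 1L)]) +
    sum(inner & !padded[2:(nrow(m) + 1L), 1:ncol(m)]) +
    sum(inner & !padded[2:(nrow(m) + 1L), 3:(ncol(m) + 2L)])
}

# per-degree quantization tolerance (mm) for comparing profiles of two
# independently rasterized scenes: radial boundary displacement (q px per
# comparison) divided by the sine of the ray/margin incidence angle, plus the
# frame-direction jitter from canthus quantization acting through the polar
# slope.  psi and the slope come from the analytic truth profile.
profileTolMm <- function(truthProfileMm, mmPerPx, fissureWidthPx, q = 2) {
  rho <- truthProfileMm
  fwd <- abs(c(rho[-1], rho[1]) - rho) / (pi / 180)
  bwd <- abs(rho - c(rho[360], rho[-360])) / (pi / 180)
  drho <- pmax(fwd, bwd)
  psi <- atan2(rho, drho)
  q * mmPerPx / sin(psi) + (2 * q / fissureWidthPx) * drho
}

# study conditions for the abnormality-detection experiment: a tight normal
# cohort (per-segment SD ~0.3 mm) with high-amplitude 10-degree bumps.
# Amplitudes are sized so the segment-mean shift (amplitude / 3 after
# averaging a 10-degree raised cosine over a 15-degree segment) clears the
# z = 1.96 normative band plus any plausible subject baseline (~4 SD):
# amplitude >= ~18x the cohort SD guarantees subject-level flagging
detectionVariation <- function() {
  list(mrd1 = c(mean = 3.1, sd = 0.25), mrd2 = c(mean = 5.8, sd = 0.25),
       width = c(mean = 28, sd = 0.5), tilt = c(mean = 4, sd = 0.5))
}

detectionBumpSpec <- function() {
  list(nBumps = 1L, widthDeg = 10, amplitudeRange = c(5, 7))
}

# deep-fissure conditions for morphometry validation: anatomically realistic
# cornea (5.5 mm radius) fully visible inside the aperture
validationBase <- function() sceneParams(corneaRadiusMm = 5.5)

validationVariation <- function() {
  list(mrd1 = c(mean = 6.5, sd = 0.8), mrd2 = c(mean = 7.5, sd = 1.1),
       width = c(mean = 28, sd = 1.5), tilt = c(mean = 4, sd = 2))
}

# build a ContourProfile directly from a numeric vector (for the statistics
# of the partition/normative machinery, no rasters involved)
syntheticProfile <- function(distancesMm, id = "synthetic") {
  frame <- buildFrame(list(medial = c(0, 10), lateral = c(0, -10)), c(0, 0))
  new("ContourProfile", distancesMm = distancesMm, frame = frame,
      subjectId = id)
}
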