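#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Parameters of a synthetic eyelid scene
#'
#' Describes one synthetic face-crop scene: frame geometry, true millimetre
#' scale, palpebral fissure shape (MRD1/MRD2, fissure width, canthal tilt),
#' corneal and light-reflex discs, the forehead calibration marker, and any
#' contour bump deformations used to plant abnormalities.
#'
#' Geometry conventions: the corneal light reflex sits at \code{eyeCenter};
#' the two canthi are placed symmetrically about it so the intercanthal line
#' passes through the reflex; the lateral canthus lies toward the image left
#' and is elevated by \code{canthalTiltDeg}.  Each eyelid is a parabola
#' through both canthi whose apex sits \code{mrd1Mm} above (upper lid) or
#' \code{mrd2Mm} below (lower lid) the reflex.  Bumps are raised-cosine
#' radial deformations of the fissure boundary, addressed by degree about the
#' reference origin.  \code{rotationDeg} rigidly rotates the whole eye
#' geometry about \code{eyeCenter} after construction (used for rotation
#' equivariance checks).
#'
#' @slot imageWidthPx,imageHeightPx frame size in pixels.
#' @slot mmPerPxTrue true scale (mm per pixel).
#' @slot eyeCenter numeric(2), (row, col) of the light-reflex center, px.
#' @slot mrd1Mm,mrd2Mm margin-reflex distances, mm.
#' @slot fissureWidthMm horizontal canthus-to-canthus extent, mm.
#' @slot canthalTiltDeg lateral canthus elevation, degrees.
#' @slot corneaRadiusMm,reflexRadiusMm disc radii, mm.
#' @slot markerCenter numeric(2), (row, col) of the marker disc, px.
#' @slot markerDiameterMm physical marker diameter (9.0 mm by default).
#' @slot bumps data.frame with columns center_deg, width_deg, amplitude_mm.
#' @slot noiseSd Gaussian pixel noise added to the rendered image.
#' @slot rotationDeg rigid rotation of the eye geometry, degrees.
#' @slot seed integer RNG seed for rendering noise.
#' @export
setClass("SceneParams", representation(
  imageWidthPx = "integer", imageHeightPx = "integer",
  mmPerPxTrue = "numeric", eyeCenter = "numeric",
  mrd1Mm = "numeric", mrd2Mm = "numeric", fissureWidthMm = "numeric",
  canthalTiltDeg = "numeric", corneaRadiusMm = "numeric",
  reflexRadiusMm = "numeric", markerCenter = "numeric",
  markerDiameterMm = "numeric", bumps = "data.frame",
  noiseSd = "numeric", rotationDeg = "numeric", seed = "integer"))

setValidity("SceneParams", function(object) {
  p <- object
  msg <- character(0)
  if (p@imageWidthPx < 8L || p@imageHeightPx < 8L)
    msg <- c(msg, "imageWidthPx/imageHeightPx must be >= 8")
  if (p@mmPerPxTrue <= 0) msg <- c(msg, "mmPerPxTrue must be positive")
  if (p@mrd2Mm <= 0) msg <- c(msg, "mrd2Mm must be positive")
  if (p@mrd1Mm + p@mrd2Mm <= 0)
    msg <- c(msg, "mrd1Mm + mrd2Mm must be positive (fissure must be open)")
  if (p@fissureWidthMm <= 0) msg <- c(msg, "fissureWidthMm must be positive")
  if (p@corneaRadiusMm <= 0) msg <- c(msg, "corneaRadiusMm must be positive")
  if (p@reflexRadiusMm <= 0) msg <- c(msg, "reflexRadiusMm must be positive")
  if (p@reflexRadiusMm >= p@corneaRadiusMm)
    msg <- c(msg, "reflexRadiusMm must be smaller than corneaRadiusMm")
  if (p@markerDiameterMm <= 0) msg <- c(msg, "markerDiameterMm must be positive")
  if (length(p@eyeCenter) != 2L || length(p@markerCenter) != 2L)
    msg <- c(msg, "eyeCenter and markerCenter must be (row, col) pairs")
  if (nrow(p@bumps) > 0) {
    req <- c("center_deg", "width_deg", "amplitude_mm")
    if (!all(req %in% names(p@bumps))) {
      msg <- c(msg, "bumps needs columns center_deg, width_deg, amplitude_mm")
    } else {
      if (any(p@bumps$width_deg <= 0)) msg <- c(msg, "bump width_deg must be positive")
      if (any(p@bumps$amplitude_mm == 0)) msg <- c(msg, "bump amplitude_mm must be nonzero")
      if (any(p@bumps$center_deg < 0 | p@bumps$center_deg >= 360))
        msg <- c(msg, "bump center_deg must lie in [0, 360)")
    }
  }
  # marker disc must stay clear of the eye region
  if (length(p@eyeCenter) == 2L && length(p@markerCenter) == 2L) {
    s <- p@mmPerPxTrue
    eyeReach <- (p@fissureWidthMm / 2 +
                 max(abs(p@mrd1Mm), p@mrd2Mm) +
                 max(0, if (nrow(p@bumps)) max(abs(p@bumps$amplitude_mm)) else 0)) / s
    d <- sqrt(sum((p@eyeCenter - p@markerCenter)^2))
    if (d < eyeReach + p@markerDiameterMm / (2 * s))
      msg <- c(msg, "marker disc overlaps the eye region (markerCenter too close)")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' A synthetic scene: rendered image, ground-truth masks, and truth record
#'
#' @slot image numeric array height x width x 3 in [0, 1]; may have zero
#'   extent when the scene was generated with \code{renderImage = FALSE}.
#' @slot masks named list of logical matrices: sclera, cornea, light_reflex,
#'   marker, all in full-frame coordinates.
#' @slot truth list: true measurements computed from the analytic curves (see
#'   \code{\link{generateScene}}).
#' @slot params the \code{SceneParams} the scene was generated from.
#' @export
setClass("Scene", representation(
  image = "array", masks = "list", truth = "list", params = "SceneParams"))

setValidity("Scene", function(object) {
  msg <- character(0)
  need <- c("sclera", "cornea", "light_reflex", "marker")
  if (!all(need %in% names(object@masks)))
    msg <- c(msg, "masks must contain sclera, cornea, light_reflex, marker")
  dims <- unique(lapply(object@masks, dim))
  if (length(dims) > 1L) msg <- c(msg, "all masks must share dimensions")
  if (all(need %in% names(object@masks))) {
    m <- object@masks
    if (any(m$light_reflex & !m$cornea))
      msg <- c(msg, "light_reflex mask must be contained in cornea mask")
  }
  tr <- object@truth
  if (length(tr)) {
    if (length(tr$true_profile_mm) != 360L ||
        any(!is.finite(tr$true_profile_mm)) || any(tr$true_profile_mm <= 0))
      msg <- c(msg, "true_profile_mm must be 360 positive finite values")
    hasBumps <- nrow(object@params@bumps) > 0L
    if (hasBumps != (length(tr$abnormal_degrees) > 0L))
      msg <- c(msg, "abnormal_degrees must be nonempty iff bumps are present")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Record of a square resize with zero padding
#'
#' @slot scale output pixels per input pixel.
#' @slot padRightPx,padBottomPx zero-padding added on the right/bottom.
#' @slot inputSize integer(2) (width, height) of the input.
#' @slot outputSize integer(2) (side, side).
#' @export
setClass("ResizeTransform", representation(
  scale = "numeric", padRightPx = "integer", padBottomPx = "integer",
  inputSize = "integer", outputSize = "integer"))

setValidity("ResizeTransform", function(object) {
  msg <- character(0)
  if (object@scale <= 0) msg <- c(msg, "scale must be positive")
  if (object@padRightPx < 0L || object@padBottomPx < 0L)
    msg <- c(msg, "padding must be nonnegative")
  if (object@padRightPx > 0L && object@padBottomPx > 0L)
    msg <- c(msg, "at most one of padRightPx, padBottomPx may be nonzero")
  side <- object@outputSize[1]
  if (abs(object@scale - side / max(object@inputSize)) > 1e-9)
    msg <- c(msg, "scale must equal side / max(input dimensions)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' A set of binary segmentation masks for one eye (plus the marker)
#'
#' @slot masks named list of logical matrices (any subset of sclera, cornea,
#'   light_reflex, marker).
#' @slot frame coordinate frame tag, "original" or "resized".
#' @export
setClass("SegmentationBundle",
         representation(masks = "list", frame = "character"))

setValidity("SegmentationBundle", function(object) {
  msg <- character(0)
  known <- c("sclera", "cornea", "light_reflex", "marker")
  if (!length(object@masks) || is.null(names(object@masks)) ||
      !all(names(object@masks) %in% known))
    msg <- c(msg, "mask names must be among sclera, cornea, light_reflex, marker")
  if (!all(vapply(object@masks, is.logical, logical(1))))
    msg <- c(msg, "masks must be logical matrices")
  if (!object@frame %in% c("original", "resized"))
    msg <- c(msg, "frame must be 'original' or 'resized'")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Millimetre calibration derived from the fiducial marker
#'
#' @slot markerDiameterPx equivalent-circle diameter of the segmented marker.
#' @slot markerDiameterMm physical marker diameter (9.0 mm forehead sticker).
#' @slot mmPerPx millimetres per pixel, = markerDiameterMm / markerDiameterPx.
#' @export
setClass("Calibration", representation(
  markerDiameterPx = "numeric", markerDiameterMm = "numeric",
  mmPerPx = "numeric"))

setValidity("Calibration", function(object) {
  msg <- character(0)
  if (object@markerDiameterPx <= 0 || object@markerDiameterMm <= 0)
    msg <- c(msg, "marker diameters must be positive")
  if (abs(object@mmPerPx -
          object@markerDiameterMm / object@markerDiameterPx) > 1e-12)
    msg <- c(msg, "mmPerPx must equal markerDiameterMm / markerDiameterPx")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' An ordered chain of crack-boundary vertices
#'
#' Vertices live on the pixel-corner lattice ((row, col), 0-based);
#' consecutive vertices are unit neighbours.  A closed chain repeats its
#' first vertex as its last.
#'
#' @slot vertices numeric matrix n x 2, columns (row, col).
#' @slot closed logical.
#' @export
setClass("BoundaryChain",
         representation(vertices = "matrix", closed = "logical"))

setValidity("BoundaryChain", function(object) {
  v <- object@vertices
  msg <- character(0)
  if (ncol(v) != 2L || nrow(v) < 2L)
    msg <- c(msg, "vertices must be an n x 2 matrix with n >= 2")
  d <- diff(v)
  if (nrow(v) >= 2L && any(abs(rowSums(abs(d)) - 1) > 1e-9))
    msg <- c(msg, "consecutive vertices must be unit lattice neighbours")
  if (object@closed && any(v[1, ] != v[nrow(v), ]))
    msg <- c(msg, "closed chains must end where they start")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Calibrated eyelid measurements for one eye
#'
#' @slot mrd1Mm,mrd2Mm margin-reflex distances, mm.
#' @slot upperLenMm,lowerLenMm corner-corrected eyelid margin lengths, mm.
#' @slot corneaPerimeterMm corner-corrected cornea outer boundary length, mm.
#' @slot reflexCenterPx numeric(2) (row, col) of the light-reflex centroid.
#' @slot canthiPx 2 x 2 matrix, rows medial/lateral, columns (row, col).
#' @slot mmPerPx scale the measurements were converted with.
#' @export
setClass("EyelidMeasurements", representation(
  mrd1Mm = "numeric", mrd2Mm = "numeric", upperLenMm = "numeric",
  lowerLenMm = "numeric", corneaPerimeterMm = "numeric",
  reflexCenterPx = "numeric", canthiPx = "matrix", mmPerPx = "numeric"))

#' Intercanthal reference frame for contour profiling
#'
#' @slot origin numeric(2) (row, col): foot of the perpendicular from the
#'   light reflex onto the intercanthal line (or the intercanthal midpoint,
#'   depending on the origin convention).
#' @slot tiltDeg angle of the intercanthal line against the image horizontal.
#' @slot lateralDir numeric(2) unit vector (row, col) toward the lateral
#'   canthus: the profile's 0-degree direction.
#' @slot upDir numeric(2) unit vector toward the upper lid: the 90-degree
#'   direction.
#' @export
setClass("ReferenceFrame", representation(
  origin = "numeric", tiltDeg = "numeric",
  lateralDir = "numeric", upDir = "numeric"))

#' A 360-degree radial contour profile
#'
#' @slot distancesMm numeric(360): distance (mm) from the reference origin to
#'   the eyelid margin at each whole degree (0 = toward the lateral canthus,
#'   90 = toward the upper lid).
#' @slot frame the \code{ReferenceFrame} the profile was cast in.
#' @slot subjectId identifier.
#' @export
setClass("ContourProfile", representation(
  distancesMm = "numeric", frame = "ReferenceFrame", subjectId = "character"))

setValidity("ContourProfile", function(object) {
  d <- object@distancesMm
  if (length(d) != 360L) return("distancesMm must have exactly 360 entries")
  if (any(!is.finite(d)) || any(d <= 0))
    return("distancesMm must be positive and finite")
  TRUE
})

#' Partition of the 360 contour degrees into k segments
#'
#' @slot k number of segments.
#' @slot intervalDeg 360 / k.
#' @slot segmentOfDegree integer(360): 1-based segment index of each degree.
#' @export
setClass("PartitionScheme", representation(
  k = "integer", intervalDeg = "numeric", segmentOfDegree = "integer"))

setValidity("PartitionScheme", function(object) {
  if (object@k < 2L || object@k > 360L) return("k must be in [2, 360]")
  if (length(object@segmentOfDegree) != 360L)
    return("segmentOfDegree must map all 360 degrees")
  sizes <- tabulate(object@segmentOfDegree, object@k)
  if (max(sizes) - min(sizes) > 1L)
    return("segment sizes may differ by at most one degree")
  TRUE
})

#' Normative per-segment acceptance intervals fitted on a normal cohort
#'
#' @slot scheme the \code{PartitionScheme} used.
#' @slot meanMm,sdMm per-segment sample mean and SD (n-1 denominator) of the
#'   cohort's segment values, mm.
#' @slot loMm,hiMm per-segment acceptance interval: mean +/- zCrit * SD for
#'   the Gaussian fit, empirical 2.5/97.5 percentiles for the percentile fit.
#' @slot zCrit two-sided normal critical value (1.959964 for the 95\% range).
#' @slot method "gaussian" or "percentile".
#' @slot nNormal size of the fitting cohort.
#' @export
setClass("NormativeModel", representation(
  scheme = "PartitionScheme", meanMm = "numeric", sdMm = "numeric",
  loMm = "numeric", hiMm = "numeric", zCrit = "numeric",
  method = "character", nNormal = "integer"))

setValidity("NormativeModel", function(object) {
  msg <- character(0)
  k <- object@scheme@k
  for (nm in c("meanMm", "sdMm", "loMm", "hiMm"))
    if (length(slot(object, nm)) != k)
      msg <- c(msg, paste(nm, "must have one entry per segment"))
  if (any(object@sdMm < 0)) msg <- c(msg, "sdMm must be nonnegative")
  if (any(object@loMm > object@hiMm))
    msg <- c(msg, "interval bounds must satisfy loMm <= hiMm")
  if (!object@method %in% c("gaussian", "percentile"))
    msg <- c(msg, "method must be 'gaussian' or 'percentile'")
  if (object@nNormal < 2L) msg <- c(msg, "nNormal must be at least 2")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Per-subject abnormality flags
#'
#' @slot subjectId identifier.
#' @slot k partition count of the scheme used.
#' @slot abnormalSegments integer vector of 1-based abnormal segment indices.
#' @slot isAbnormalSubject TRUE iff at least one segment is abnormal.
#' @export
setClass("AbnormalityReport", representation(
  subjectId = "character", k = "integer", abnormalSegments = "integer",
  isAbnormalSubject = "logical"))

setValidity("AbnormalityReport", function(object) {
  if (object@isAbnormalSubject != (length(object@abnormalSegments) > 0L))
    return("isAbnormalSubject must mirror abnormalSegments being nonempty")
  TRUE
})

#' Method-comparison agreement report
#'
#' @slot n number of pairs.
#' @slot icc ICC(2,1), two-way random effects, absolute agreement, single
#'   measure.
#' @slot iccBand qualitative band: poor (< 0.40), fair (0.40-0.60),
#'   good (0.60-0.75), excellent (0.75-1.00).
#' @slot meanDiff mean of a - b.
#' @slot loaLow,loaHigh 95\% limits of agreement (mean +/- 1.96 SD).
#' @slot ci95MeanDiff numeric(2), t-based 95\% CI of the mean difference.
#' @export
setClass("AgreementReport", representation(
  n = "integer", icc = "numeric", iccBand = "character",
  meanDiff = "numeric", loaLow = "numeric", loaHigh = "numeric",
  ci95MeanDiff = "numeric"))

setValidity("AgreementReport", function(object) {
  msg <- character(0)
  if (!(object@loaLow <= object@meanDiff && object@meanDiff <= object@loaHigh))
    msg <- c(msg, "limits of agreement must bracket the mean difference")
  if (!object@iccBand %in% c("poor", "fair", "good", "excellent"))
    msg <- c(msg, "invalid iccBand")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
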