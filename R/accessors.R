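# Accessors and show methods.

#' @rdname Scene-class
#' @param object,x a \code{Scene}.
#' @export
setGeneric("sceneMasks", function(x) standardGeneric("sceneMasks"))

#' @rdname Scene-class
#' @export
setMethod("sceneMasks", "Scene", function(x) x@masks)

#' @rdname Scene-class
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))

#' @rdname Scene-class
#' @export
setMethod("sceneTruth", "Scene", function(x) x@truth)

#' @rdname Scene-class
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))

#' @rdname Scene-class
#' @export
setMethod("sceneImage", "Scene", function(x) x@image)

#' @rdname SegmentationBundle-class
#' @param x a \code{SegmentationBundle}.
#' @export
setGeneric("bundleMasks", function(x) standardGeneric("bundleMasks"))

#' @rdname SegmentationBundle-class
#' @export
setMethod("bundleMasks", "SegmentationBundle", function(x) x@masks)

#' @rdname Calibration-class
#' @param x a \code{Calibration}.
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))

#' @rdname Calibration-class
#' @export
setMethod("mmPerPx", "Calibration", function(x) x@mmPerPx)

#' @rdname ContourProfile-class
#' @param x a \code{ContourProfile}.
#' @export
setGeneric("profileDistances", function(x) standardGeneric("profileDistances"))

#' @rdname ContourProfile-class
#' @export
setMethod("profileDistances", "ContourProfile", function(x) x@distancesMm)

#' @rdname EyelidMeasurements-class
#' @param x an \code{EyelidMeasurements}.
#' @param row.names,optional,... passed for generic compatibility, unused.
#' @export
setMethod("as.data.frame", "EyelidMeasurements",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(mrd1_mm = x@mrd1Mm, mrd2_mm = x@mrd2Mm,
               upper_len_mm = x@upperLenMm, lower_len_mm = x@lowerLenMm,
               cornea_perimeter_mm = x@corneaPerimeterMm,
               mm_per_px = x@mmPerPx)
  })

#' @rdname AgreementReport-class
#' @param x an \code{AgreementReport}.
#' @param row.names,optional,... passed for generic compatibility, unused.
#' @export
setMethod("as.data.frame", "AgreementReport",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(n = x@n, icc = x@icc, icc_band = x@iccBand,
               mean_diff = x@meanDiff, loa_low = x@loaLow,
               loa_high = x@loaHigh,
               ci95_low = x@ci95MeanDiff[1], ci95_high = x@ci95MeanDiff[2])
  })

setMethod("show", "SceneParams", function(object) {
  cat("SceneParams:", object@imageWidthPx, "x", object@imageHeightPx,
      "px @", object@mmPerPxTrue, "mm/px\n")
  cat("  MRD1", object@mrd1Mm, "mm, MRD2", object@mrd2Mm,
      "mm, fissure width", object@fissureWidthMm, "mm, tilt",
      object@canthalTiltDeg, "deg\n")
  cat("  cornea r", object@corneaRadiusMm, "mm, reflex r",
      object@reflexRadiusMm, "mm, marker", object@markerDiameterMm, "mm\n")
  nb <- nrow(object@bumps)
  if (nb) cat("  bumps:", nb, "\n")
})

setMethod("show", "Scene", function(object) {
  d <- dim(object@masks[[1]])
  cat("Scene", d[2], "x", d[1], "px;",
      if (length(object@image)) "rendered" else "masks only", "\n")
  cat("  true MRD1", round(object@truth$true_mrd1_mm, 3),
      "mm, MRD2", round(object@truth$true_mrd2_mm, 3), "mm;",
      length(object@truth$abnormal_degrees), "abnormal degrees\n")
})

setMethod("show", "Calibration", function(object) {
  cat("Calibration: marker", round(object@markerDiameterPx, 2), "px =",
      object@markerDiameterMm, "mm ->", signif(object@mmPerPx, 6), "mm/px\n")
})

setMethod("show", "EyelidMeasurements", function(object) {
  cat("EyelidMeasurements (mm): MRD1", round(object@mrd1Mm, 3),
      " MRD2", round(object@mrd2Mm, 3),
      "\n  upper lid", round(object@upperLenMm, 2),
      " lower lid", round(object@lowerLenMm, 2),
      " cornea boundary", round(object@corneaPerimeterMm, 2), "\n")
})

setMethod("show", "ContourProfile", function(object) {
  d <- object@distancesMm
  cat("ContourProfile [", object@subjectId, "]: 360 samples, ",
      round(min(d), 2), "-", round(max(d), 2), " mm\n", sep = "")
})

setMethod("show", "PartitionScheme", function(object) {
  cat("PartitionScheme: k =", object@k, "(", formatIntervalDeg(object@intervalDeg),
      "degree intervals )\n")
})

setMethod("show", "NormativeModel", function(object) {
  cat("NormativeModel: k =", object@scheme@k, ", fitted on",
      object@nNormal, "normals, z =", object@zCrit, "\n")
})

setMethod("show", "AbnormalityReport", function(object) {
  cat("AbnormalityReport [", object@subjectId, "]: ",
      if (object@isAbnormalSubject) "ABNORMAL" else "normal",
      " (", length(object@abnormalSegments), "/", object@k,
      " segments)\n", sep = "")
})

setMethod("show", "AgreementReport", function(object) {
  cat("AgreementReport: n =", object@n, "\n")
  cat("  ICC(2,1) =", round(object@icc, 4), "(", object@iccBand, ")\n")
  cat("  mean diff =", round(object@meanDiff, 4),
      " LOA [", round(object@loaLow, 4), ",", round(object@loaHigh, 4), "]\n")
})
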