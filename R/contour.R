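# 360-degree radial contour profiling and partition-based abnormality
# detection.
#
# The eyelid contour is profiled about the intercanthal reference frame: the
# intercanthal line joins the medial and lateral canthi; an orthogonal line
# through the light reflex meets it at the reference origin; the frame is
# rotated so the intercanthal line is horizontal.  Rays cast at each whole
# degree (0 = toward the lateral canthus, 90 = toward the upper lid) measure
# the distance to the eyelid margin; the 360 samples are grouped into k equal
# partitions and each subject's segment values are compared against
# per-segment normative intervals (mean +/- z * SD) fitted on a normal
# cohort.  A subject with at least one abnormal segment is flagged abnormal.

#' Build the intercanthal reference frame
#'
#' The frame's tilt is the angle of the canthus-to-canthus segment against
#' the image horizontal; the origin is, by default, the foot of the
#' perpendicular from the light-reflex center onto the intercanthal line
#' (equivalently, in the rotated frame, the point of the line directly above
#' or below the rotated reflex).  The alternative convention uses the
#' intercanthal midpoint and ignores the reflex.
#'
#' @param canthi list with \code{medial} and \code{lateral} (row, col)
#'   points (lattice coordinates; pixel coordinates are accepted and used
#'   as-is).
#' @param center (row, col) light-reflex center.
#' @param origin origin convention: \code{"reflex_foot"} (default) or
#'   \code{"intercanthal_midpoint"}.
#' @return a \code{\link{ReferenceFrame-class}} object.
#' @export
buildFrame <- function(canthi, center,
                       origin = c("reflex_foot", "intercanthal_midpoint")) {
  origin <- match.arg(origin)
  med <- as.numeric(canthi$medial); lat <- as.numeric(canthi$lateral)
  d <- lat - med
  .stopIf(sqrt(sum(d^2)) < 1e-9, "canthi coincide; reference frame undefined")
  u0 <- d / sqrt(sum(d^2))
  o <- if (origin == "reflex_foot") {
    .stopIf(any(!is.finite(center)), "reflex center must be finite")
    med + sum((as.numeric(center) - med) * u0) * u0
  } else {
    (med + lat) / 2
  }
  w <- c(-u0[2], u0[1])
  if (w[1] > 0) w <- -w # 90 degrees points toward the upper lid
  tilt <- atan2(-d[1], abs(d[2])) * 180 / pi # elevation of the lateral canthus
  new("ReferenceFrame", origin = o, tiltDeg = tilt, lateralDir = u0, upDir = w)
}

# minimum positive ray-polyline intersection parameter for each ray
# directions: matrix n x 2 (row, col); segments from polyline vertices v
.rayPolylineDistance <- function(origin, directions, v) {
  p1r <- v[-nrow(v), 1]; p1c <- v[-nrow(v), 2]
  p2r <- v[-1, 1]; p2c <- v[-1, 2]
  er <- p2r - p1r; ec <- p2c - p1c
  out <- numeric(nrow(directions))
  for (i in seq_len(nrow(directions))) {
    ur <- directions[i, 1]; uc <- directions[i, 2]
    den <- ur * ec - uc * er
    t <- (ec * (p1r - origin[1]) - er * (p1c - origin[2])) / den
    # position along the segment, from whichever component is nonzero
    # (crack segments are axis-aligned unit edges)
    sr <- origin[1] + t * ur - p1r
    sc <- origin[2] + t * uc - p1c
    s <- ifelse(abs(ec) >= abs(er), sc / ec, sr / er)
    hit <- abs(den) > 1e-12 & is.finite(t) & t > 1e-9 &
      is.finite(s) & s >= -1e-9 & s <= 1 + 1e-9
    out[i] <- if (any(hit)) min(t[hit]) else NA_real_
  }
  out
}

#' Cast the 360-degree radial contour profile
#'
#' For each whole degree d, a ray is cast from the frame origin at angle d in
#' the rotated frame (0 = toward the lateral canthus, 90 = toward the upper
#' lid) and the distance to its nearest intersection with the combined
#' upper + lower margin polyline is recorded in millimetres.
#'
#' @param upper,lower open \code{BoundaryChain}s from
#'   \code{\link{splitMargins}}.
#' @param frame a \code{\link{buildFrame}} result; its origin must lie inside
#'   the closed fissure boundary.
#' @param cal a \code{\link{calibrate}} result.
#' @param subjectId identifier stored on the profile.
#' @return a \code{\link{ContourProfile-class}} object.
#' @export
radialProfile <- function(upper, lower, frame, cal, subjectId = "subject") {
  stopifnot(is(upper, "BoundaryChain"), is(lower, "BoundaryChain"),
            is(frame, "ReferenceFrame"), is(cal, "Calibration"))
  v <- rbind(upper@vertices, lower@vertices)
  deg <- 0:359
  th <- deg * pi / 180
  dirs <- cbind(frame@lateralDir[1] * cos(th) + frame@upDir[1] * sin(th),
                frame@lateralDir[2] * cos(th) + frame@upDir[2] * sin(th))
  t <- .rayPolylineDistance(frame@origin, dirs, v)
  .stopIf(any(is.na(t)),
          "some rays do not intersect the margin; is the origin inside the fissure?")
  new("ContourProfile", distancesMm = t * cal@mmPerPx, frame = frame,
      subjectId = subjectId)
}

#' Contour profile straight from a segmentation bundle
#'
#' Convenience wrapper: fissure construction, canthus detection, margin
#' splitting, frame building and ray casting in one call.
#'
#' @inheritParams measureEye
#' @inheritParams buildFrame
#' @param subjectId identifier stored on the profile.
#' @return a \code{ContourProfile}.
#' @export
contourProfile <- function(bundle, cal, eyeSide = "left",
                           origin = "reflex_foot", subjectId = "subject") {
  stopifnot(is(bundle, "SegmentationBundle"), is(cal, "Calibration"))
  sclera <- largestComponent(.asMask(bundle@masks$sclera))
  cornea <- largestComponent(.asMask(bundle@masks$cornea))
  reflex <- .asMask(bundle@masks$light_reflex)
  .stopIf(!any(reflex), "light reflex not detected (empty mask)")
  f <- EBImage::fillHull((sclera | cornea) * 1L)
  fissure <- matrix(as.integer(round(f)), nrow(sclera)) > 0L
  canthi <- findCanthi(sclera, eyeSide = eyeSide)
  margins <- splitMargins(fissure, canthi)
  center <- reflexCenter(largestComponent(reflex))
  frame <- buildFrame(list(medial = margins$canthiVertices["medial", ],
                           lateral = margins$canthiVertices["lateral", ]),
                      center, origin = origin)
  radialProfile(margins$upper, margins$lower, frame, cal,
                subjectId = subjectId)
}

#' Partition the 360 contour degrees into k segments
#'
#' Segment i covers degrees [i * 360/k, (i+1) * 360/k).  The base case k = 4
#' is the four quadrants cut by the intercanthal line and its orthogonal
#' through the reflex; each larger k subdivides the circle equally, so for
#' the standard set (4, 8, 16, 24, 32, 64, 128, 256) segment boundaries at 0
#' and 90 degrees coincide with the two drawn lines.
#'
#' @param k number of partitions, between 2 and 360.
#' @return a \code{\link{PartitionScheme-class}} object.
#' @export
makeScheme <- function(k) {
  .stopIf(!is.finite(k) || k < 2 || k > 360, "k must be in [2, 360]")
  k <- as.integer(k)
  seg <- as.integer(floor((0:359) * k / 360)) + 1L
  new("PartitionScheme", k = k, intervalDeg = 360 / k, segmentOfDegree = seg)
}

#' Printed form of a partition's degree interval
#'
#' One decimal place, halves rounded away from zero, matching the
#' conventional reporting (e.g. 360/32 = 11.25 prints as 11.3).
#'
#' @param intervalDeg numeric degree interval.
#' @return character.
#' @export
formatIntervalDeg <- function(intervalDeg) {
  sprintf("%.1f", roundHalfAway(intervalDeg, 1L))
}

#' Aggregate a profile into per-segment values
#'
#' The segment value is the arithmetic mean of its member degrees' distances.
#'
#' @param profile a \code{ContourProfile}.
#' @param scheme a \code{\link{makeScheme}} result.
#' @return numeric(k) of segment values in mm.
#' @export
segmentValues <- function(profile, scheme) {
  stopifnot(is(profile, "ContourProfile"), is(scheme, "PartitionScheme"))
  as.numeric(tapply(profile@distancesMm, scheme@segmentOfDegree, mean))
}

#' Fit per-segment normative intervals on a normal cohort
#'
#' Per-segment sample mean and SD (n - 1 denominator) of the cohort's segment
#' values.  With the default Gaussian reading of the "95\% range" the
#' acceptance interval for a segment is mean +/- zCrit * SD; the percentile
#' method instead uses the empirical central interval at the same coverage
#' (2.5 and 97.5 percentiles for zCrit = 1.96).
#'
#' @param profiles list of \code{ContourProfile}s from the normal cohort
#'   (at least 2).
#' @param scheme a \code{PartitionScheme}.
#' @param zCrit two-sided normal critical value; the default 1.959964
#'   corresponds to the central 95\% range of a normal distribution.
#' @param method "gaussian" (default) or "percentile".
#' @return a \code{\link{NormativeModel-class}} object.
#' @export
fitNormative <- function(profiles, scheme, zCrit = stats::qnorm(0.975),
                         method = c("gaussian", "percentile")) {
  method <- match.arg(method)
  .stopIf(length(profiles) < 2L,
          "need at least 2 normal profiles (SD undefined otherwise)")
  vals <- vapply(profiles, segmentValues, numeric(scheme@k), scheme = scheme)
  vals <- matrix(vals, nrow = scheme@k)
  mu <- rowMeans(vals)
  sd <- apply(vals, 1, stats::sd)
  if (method == "gaussian") {
    lo <- mu - zCrit * sd
    hi <- mu + zCrit * sd
  } else {
    alpha <- 2 * (1 - stats::pnorm(zCrit))
    lo <- apply(vals, 1, stats::quantile, probs = alpha / 2, names = FALSE)
    hi <- apply(vals, 1, stats::quantile, probs = 1 - alpha / 2, names = FALSE)
  }
  new("NormativeModel", scheme = scheme, meanMm = mu, sdMm = sd,
      loMm = lo, hiMm = hi, zCrit = zCrit, method = method,
      nNormal = length(profiles))
}

#' Flag abnormal contour segments against a normative model
#'
#' A segment is abnormal when its value falls outside
#' [mean - z * SD, mean + z * SD]; for a degenerate segment with SD = 0 any
#' value different from the mean is abnormal.  A subject with at least one
#' abnormal segment is classified abnormal.
#'
#' @param profile a \code{ContourProfile}.
#' @param model a \code{\link{fitNormative}} result.
#' @return an \code{\link{AbnormalityReport-class}} object.
#' @export
flagAbnormal <- function(profile, model) {
  stopifnot(is(profile, "ContourProfile"), is(model, "NormativeModel"))
  vals <- segmentValues(profile, model@scheme)
  segs <- which(vals < model@loMm | vals > model@hiMm)
  new("AbnormalityReport", subjectId = profile@subjectId,
      k = model@scheme@k, abnormalSegments = as.integer(segs),
      isAbnormalSubject = length(segs) > 0L)
}

#' Partition-count verification sweep
#'
#' For each partition count k, fits the normative model on the labeled
#' normals, flags every subject, and reports sensitivity (flagged abnormals /
#' all abnormals) and specificity (unflagged normals / all normals).
#'
#' @param profiles list of \code{ContourProfile}s.
#' @param isAbnormal logical vector of true labels, one per profile.
#' @param ks integer vector of partition counts; the standard sweep is
#'   c(4, 8, 16, 24, 32, 64, 128, 256).
#' @param zCrit normative critical value, see \code{\link{fitNormative}}.
#' @param method normative fit method, see \code{\link{fitNormative}}.
#' @return data.frame with columns k, interval_deg, sensitivity, specificity.
#' @export
verificationSweep <- function(profiles, isAbnormal,
                              ks = c(4L, 8L, 16L, 24L, 32L, 64L, 128L, 256L),
                              zCrit = stats::qnorm(0.975),
                              method = "gaussian") {
  .stopIf(length(profiles) != length(isAbnormal),
          "profiles and isAbnormal must have equal length")
  .stopIf(sum(!isAbnormal) < 2L, "need at least 2 normal subjects")
  .stopIf(sum(isAbnormal) < 1L, "need at least 1 abnormal subject")
  normals <- profiles[!isAbnormal]
  res <- lapply(ks, function(k) {
    scheme <- makeScheme(k)
    model <- fitNormative(normals, scheme, zCrit = zCrit, method = method)
    flags <- vapply(profiles, function(p)
      flagAbnormal(p, model)@isAbnormalSubject, logical(1))
    data.frame(k = as.integer(k), interval_deg = roundHalfAway(360 / k, 1L),
               sensitivity = sum(flags & isAbnormal) / sum(isAbnormal),
               specificity = sum(!flags & !isAbnormal) / sum(!isAbnormal))
  })
  do.call(rbind, res)
}

#' Plot a verification sweep
#'
#' Sensitivity against the number of partitions, one point per k.
#'
#' @param sweep a \code{\link{verificationSweep}} result.
#' @param file optional PNG path; when given the plot is written there.
#' @return the input, invisibly.
#' @export
plotVerificationSweep <- function(sweep, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(sweep$k, sweep$sensitivity, type = "b", log = "x",
                 xlab = "number of partitions",
                 ylab = "sensitivity (identified abnormal ratio)",
                 ylim = c(0, 1), pch = 16)
  graphics::abline(h = 0.8, lty = 3)
  invisible(sweep)
}
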