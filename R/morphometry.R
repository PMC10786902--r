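# Mask-to-millimetre morphometry: marker calibration, canthus detection,
# eyelid margin extraction, margin-reflex distances and boundary lengths.
#
# Measurement is performed in original-image coordinates, so the marker
# calibration and the eye measurements share one scale.  "Vertical" is the
# image column direction: the acquisition protocol keeps the head upright,
# and no head-pose correction is attempted.

#' Equivalent-circle diameter of the segmented marker
#'
#' Diameter of the circle with the same area as the largest connected
#' component of the marker mask: \code{2 * sqrt(area / pi)}.  Chosen over a
#' Feret diameter for robustness to single-pixel boundary noise.
#'
#' @param markerMask logical matrix.
#' @return diameter in pixels.
#' @export
estimateMarkerDiameter <- function(markerMask) {
  markerMask <- .asMask(markerMask, "marker mask")
  .stopIf(!any(markerMask), "marker not found (empty mask)")
  area <- sum(largestComponent(markerMask, warnMultiple = TRUE))
  2 * sqrt(area / pi)
}

#' Millimetre-per-pixel calibration from the fiducial marker
#'
#' @param markerDiameterPx measured marker diameter in pixels.
#' @param markerDiameterMm physical marker diameter; the acquisition protocol
#'   uses a 9.0 mm forehead sticker.
#' @return a \code{\link{Calibration-class}} object.
#' @examples
#' calibrate(90, 9.0) # 0.1 mm per pixel
#' @export
calibrate <- function(markerDiameterPx, markerDiameterMm = 9.0) {
  .stopIf(!is.finite(markerDiameterPx) || markerDiameterPx <= 0,
          "markerDiameterPx must be positive")
  .stopIf(!is.finite(markerDiameterMm) || markerDiameterMm <= 0,
          "markerDiameterMm must be positive")
  new("Calibration", markerDiameterPx = markerDiameterPx,
      markerDiameterMm = markerDiameterMm,
      mmPerPx = markerDiameterMm / markerDiameterPx)
}

#' Locate the canthi as the horizontal endpoints of the sclera
#'
#' The medial and lateral canthi are taken as the leftmost and rightmost
#' foreground pixels of the (sclera or fissure) mask; when an extreme column
#' holds several foreground pixels, the vertically median one is used.
#' Medial/lateral labels come from \code{eyeSide}: for an unmirrored
#' photograph of the subject's left eye the lateral (temporal) canthus is the
#' image-left endpoint.
#'
#' @param mask logical matrix (sclera, or the filled fissure).
#' @param eyeSide "left" or "right" (subject's side, unmirrored photograph).
#' @return list with \code{medial} and \code{lateral}, each a (row, col)
#'   0-based pixel coordinate.
#' @export
findCanthi <- function(mask, eyeSide = c("left", "right")) {
  eyeSide <- match.arg(eyeSide)
  mask <- .asMask(mask)
  .stopIf(!any(mask), "cannot locate canthi: empty mask")
  colsWith <- which(colSums(mask) > 0)
  pickInCol <- function(cl) {
    rows <- which(mask[, cl])
    r <- rows[ceiling(length(rows) / 2)] # vertically median pixel, ties low
    c(r - 1L, cl - 1L)
  }
  leftPt <- pickInCol(min(colsWith))
  rightPt <- pickInCol(max(colsWith))
  if (eyeSide == "left") list(medial = rightPt, lateral = leftPt)
  else list(medial = leftPt, lateral = rightPt)
}

#' Centroid of the light-reflex mask
#'
#' @param reflexMask logical matrix.
#' @return (row, col) sub-pixel point (pixel centers at integer + 0.5).
#' @export
reflexCenter <- function(reflexMask) {
  reflexMask <- .asMask(reflexMask, "light reflex mask")
  .stopIf(!any(reflexMask), "light reflex not detected (empty mask)")
  idx <- which(reflexMask, arr.ind = TRUE)
  c(mean(idx[, 1]) - 0.5, mean(idx[, 2]) - 0.5)
}

# snap a pixel-coordinate point to a nearby chain vertex (<= maxDist px).
# Canthi are snapped to the column-extreme vertex among the nearby ones
# (preferCol "min"/"max"), i.e. the tip of the canthal wedge, so the cut
# point is an extreme point of both resulting margin chains.
.snapToChain <- function(vertices, pointPx, maxDist = 2, preferCol = "none") {
  center <- pointPx + 0.5 # pixel center in lattice coordinates
  d2 <- (vertices[, 1] - center[1])^2 + (vertices[, 2] - center[2])^2
  near <- which(d2 <= maxDist^2)
  .stopIf(length(near) == 0L,
          "canthus is farther than ", maxDist, " px from the fissure boundary")
  ext <- near
  if (preferCol != "none") {
    cols <- vertices[near, 2]
    ext <- if (preferCol == "min") near[cols == min(cols)]
           else near[cols == max(cols)]
  }
  # deterministic tie-break: distance, then row, then column
  ord <- order(d2[ext], vertices[ext, 1], vertices[ext, 2])
  ext[ord[1]]
}

#' Cut the fissure boundary into upper and lower eyelid margins
#'
#' Traces the crack boundary of the filled fissure mask, snaps each canthus
#' to its nearest boundary vertex (at most 2 px away) and cuts the closed
#' chain there.  The sub-chain containing the topmost boundary vertex is the
#' upper margin; both open chains share exactly the two canthus vertices.
#'
#' @param fissureMask filled union of the sclera and cornea masks.
#' @param canthi list with \code{medial} and \code{lateral} (row, col) pixel
#'   coordinates, as returned by \code{\link{findCanthi}}.
#' @return list with \code{upper} and \code{lower} open
#'   \code{BoundaryChain}s, plus \code{canthiVertices} (2 x 2 matrix of the
#'   snapped lattice vertices, rows medial/lateral).
#' @export
splitMargins <- function(fissureMask, canthi) {
  fissureMask <- .asMask(fissureMask, "fissure mask")
  .stopIf(sum(rowSums(fissureMask) > 0) < 2L,
          "degenerate fissure mask: needs at least 2 pixel rows")
  chain <- traceBoundary(fissureMask)
  v <- chain@vertices[-nrow(chain@vertices), , drop = FALSE] # drop repeat
  medSide <- if (canthi$medial[2] <= canthi$lateral[2]) "min" else "max"
  iMed <- .snapToChain(v, canthi$medial, preferCol = medSide)
  iLat <- .snapToChain(v, canthi$lateral,
                       preferCol = if (medSide == "min") "max" else "min")
  .stopIf(iMed == iLat, "canthi snap to the same boundary vertex")
  i <- min(iMed, iLat); j <- max(iMed, iLat)
  chainA <- v[i:j, , drop = FALSE]
  chainB <- rbind(v[j:nrow(v), , drop = FALSE], v[seq_len(i), , drop = FALSE])
  topA <- min(chainA[, 1]); topB <- min(chainB[, 1])
  if (topA < topB || (topA == topB && mean(chainA[, 1]) < mean(chainB[, 1]))) {
    upper <- chainA; lower <- chainB
  } else {
    upper <- chainB; lower <- chainA
  }
  list(upper = boundaryChain(upper), lower = boundaryChain(lower),
       canthiVertices = rbind(medial = v[iMed, ], lateral = v[iLat, ]))
}

#' Margin-reflex distances from the eyelid margins
#'
#' MRD1 is the vertical distance from the light-reflex center up to the upper
#' eyelid margin, MRD2 down to the lower margin, both along the image column
#' through the reflex center, with intersections interpolated linearly along
#' the chain segments.  A reflex covered by the upper lid (negative MRD1
#' beyond one pixel) is out of measurement range and raises an error.
#'
#' @param upper,lower open \code{BoundaryChain}s from
#'   \code{\link{splitMargins}}.
#' @param center (row, col) reflex center from \code{\link{reflexCenter}}.
#' @param cal a \code{\link{calibrate}} result.
#' @return named numeric: \code{mrd1_mm}, \code{mrd2_mm}.
#' @export
computeMRDs <- function(upper, lower, center, cal) {
  stopifnot(is(upper, "BoundaryChain"), is(lower, "BoundaryChain"),
            is(cal, "Calibration"))
  rowUp <- .chainColumnCrossing(upper@vertices, center)
  rowLo <- .chainColumnCrossing(lower@vertices, center)
  .stopIf(is.na(rowUp) || is.na(rowLo),
          "reflex center column does not intersect both eyelid margins")
  mrd1 <- (center[1] - rowUp) * cal@mmPerPx
  mrd2 <- (rowLo - center[1]) * cal@mmPerPx
  .stopIf(mrd1 < -1 * cal@mmPerPx,
          "negative MRD1: light reflex covered by the upper eyelid is out of measurement range")
  c(mrd1_mm = mrd1, mrd2_mm = mrd2)
}

# row of the chain's crossing of the vertical line through center's column,
# nearest to the center row; NA when the chain never spans that column
.chainColumnCrossing <- function(v, center) {
  x0 <- center[2]
  c1 <- v[-nrow(v), 2]; c2 <- v[-1, 2]
  r1 <- v[-nrow(v), 1]; r2 <- v[-1, 1]
  lo <- pmin(c1, c2); hi <- pmax(c1, c2)
  hit <- which(x0 >= lo & x0 < hi) # horizontal segments spanning the column
  rows <- r1[hit] # horizontal crack segments have constant row
  if (!length(rows)) {
    # vertical-only contact (column exactly on a vertical segment)
    onCol <- which(c1 == x0 & c2 == x0)
    if (!length(onCol)) return(NA_real_)
    rows <- (r1[onCol] + r2[onCol]) / 2
  }
  rows[which.min(abs(rows - center[1]))]
}

#' Measure one eye from a segmentation bundle
#'
#' Orchestrates the full measurement: corneal outer-boundary length by
#' corner-corrected perimeter, palpebral fissure as the hole-filled union of
#' sclera and cornea, canthus detection from the sclera endpoints, margin
#' splitting, corner-corrected margin lengths, light-reflex centroid and
#' MRD1/MRD2, all converted with the marker calibration.
#'
#' @param bundle a complete \code{SegmentationBundle} in original coordinates
#'   (classes sclera, cornea, light_reflex; marker optional here).
#' @param cal a \code{\link{calibrate}} result.
#' @param eyeSide "left" or "right", for medial/lateral canthus labeling.
#' @return an \code{\link{EyelidMeasurements-class}} object.
#' @export
measureEye <- function(bundle, cal, eyeSide = "left") {
  stopifnot(is(bundle, "SegmentationBundle"), is(cal, "Calibration"))
  need <- c("sclera", "cornea", "light_reflex")
  miss <- setdiff(need, names(bundle@masks))
  .stopIf(length(miss) > 0,
          "segmentation bundle is missing: ", paste(miss, collapse = ", "))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  sclera <- stage("cleanup", largestComponent(.asMask(bundle@masks$sclera)))
  cornea <- stage("cleanup", largestComponent(.asMask(bundle@masks$cornea)))
  reflex <- .asMask(bundle@masks$light_reflex)
  .stopIf(!any(reflex), "[light reflex] light reflex not detected (empty mask)")
  reflex <- largestComponent(reflex)

  corneaPerimMm <- stage("cornea boundary",
                         quadrantPerimeter(cornea) * cal@mmPerPx)
  fissure <- stage("fissure", {
    f <- EBImage::fillHull((sclera | cornea) * 1L)
    matrix(as.integer(round(f)), nrow(sclera)) > 0L
  })
  canthi <- stage("canthi", findCanthi(sclera, eyeSide = eyeSide))
  margins <- stage("margins", splitMargins(fissure, canthi))
  upperLen <- stage("upper margin", marginLength(margins$upper, cal))
  lowerLen <- stage("lower margin", marginLength(margins$lower, cal))
  center <- stage("light reflex", reflexCenter(reflex))
  mrds <- stage("MRD", computeMRDs(margins$upper, margins$lower, center, cal))

  new("EyelidMeasurements",
      mrd1Mm = unname(mrds["mrd1_mm"]), mrd2Mm = unname(mrds["mrd2_mm"]),
      upperLenMm = upperLen, lowerLenMm = lowerLen,
      corneaPerimeterMm = corneaPerimMm, reflexCenterPx = center,
      canthiPx = margins$canthiVertices, mmPerPx = cal@mmPerPx)
}
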