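# Synthetic eyelid-scene generator.
#
# Stands in for clinical face-crop photographs: a palpebral fissure bounded
# by two parabolic eyelid curves meeting at two canthi, a corneal disc with a
# central light-reflex dot, and a forehead calibration marker of known
# physical diameter.  Masks are exact rasterizations of the analytic shapes
# (a pixel is foreground iff its center lies inside the analytic region), and
# every scene carries a ground-truth record computed from the analytic curves
# by fine numeric quadrature -- never from the rasters -- so the rasters can
# be measured against an independent truth.
#
# Contour abnormalities are planted as raised-cosine radial deformations
# ("bumps") of the fissure boundary in polar coordinates about the reference
# origin: localized, smooth, and addressable by degree.

# ---- geometry helpers -------------------------------------------------------

.parabolaThrough <- function(p1, p2, p3) {
  # fit row = a col^2 + b col + c through three (row, col) points
  X <- cbind(c(p1[2], p2[2], p3[2])^2, c(p1[2], p2[2], p3[2]), 1)
  as.numeric(solve(X, c(p1[1], p2[1], p3[1])))
}

.rotMat <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# scene geometry in pixel units, before the optional rigid rotation
.sceneGeometry <- function(p) {
  s <- p@mmPerPxTrue
  o <- p@eyeCenter
  halfw <- p@fissureWidthMm / (2 * s)
  tilt <- p@canthalTiltDeg * pi / 180
  cLat <- c(o[1] - halfw * tan(tilt), o[2] - halfw)
  cMed <- c(o[1] + halfw * tan(tilt), o[2] + halfw)
  upper <- .parabolaThrough(cLat, cMed, c(o[1] - p@mrd1Mm / s, o[2]))
  lower <- .parabolaThrough(cLat, cMed, c(o[1] + p@mrd2Mm / s, o[2]))
  u0 <- (cLat - o) / sqrt(sum((cLat - o)^2))
  w <- c(-u0[2], u0[1])
  if (w[1] > 0) w <- -w            # 90 degrees points toward the upper lid
  list(s = s, o = o, cLat = cLat, cMed = cMed,
       upper = upper, lower = lower, u0 = u0, w = w,
       rot = .rotMat(p@rotationDeg), rotDeg = p@rotationDeg)
}

# radial distance (px) from the origin to the undeformed margin at angles
# theta (radians, in the canonical frame: 0 = lateral, pi/2 = up)
.rho0 <- function(theta, g) {
  ur <- g$u0[1] * cos(theta) + g$w[1] * sin(theta)
  uc <- g$u0[2] * cos(theta) + g$w[2] * sin(theta)
  up <- sin(theta) >= 0
  a <- ifelse(up, g$upper[1], g$lower[1])
  b <- ifelse(up, g$upper[2], g$lower[2])
  cc <- ifelse(up, g$upper[3], g$lower[3])
  oc <- g$o[2]; or <- g$o[1]
  A <- a * uc^2
  B <- 2 * a * oc * uc + b * uc - ur
  C <- a * oc^2 + b * oc + cc - or
  disc <- B^2 - 4 * A * C
  disc[disc < 0] <- NA_real_
  sq <- sqrt(disc)
  quad <- abs(A) > 1e-12
  t1 <- ifelse(quad, (-B + sq) / (2 * A), -C / B)
  t2 <- ifelse(quad, (-B - sq) / (2 * A), -C / B)
  t1[t1 <= 1e-9] <- Inf
  t2[t2 <= 1e-9] <- Inf
  out <- pmin(t1, t2)
  .stopIf(any(!is.finite(out)),
          "internal: a contour ray has no intersection with the eyelid curve")
  out
}

# bump deformation (mm) at angles theta (radians)
.bumpMm <- function(theta, bumps) {
  if (is.null(bumps) || nrow(bumps) == 0L) return(rep(0, length(theta)))
  deg <- (theta * 180 / pi) %% 360
  out <- numeric(length(theta))
  for (i in seq_len(nrow(bumps))) {
    d <- abs((deg - bumps$center_deg[i] + 180) %% 360 - 180)
    inside <- d < bumps$width_deg[i] / 2
    out[inside] <- out[inside] + bumps$amplitude_mm[i] * 0.5 *
      (1 + cos(2 * pi * d[inside] / bumps$width_deg[i]))
  }
  out
}

.rho <- function(theta, g, bumps) .rho0(theta, g) + .bumpMm(theta, bumps) / g$s

# ---- constructors -----------------------------------------------------------

#' Construct synthetic scene parameters
#'
#' Defaults emulate the acquisition protocol the pipeline targets: a
#' 1200 x 797 px RGB face crop at 0.1 mm/px, a 9.0 mm forehead marker, and a
#' normal adult fissure (MRD1 3.0 mm, MRD2 6.0 mm, 28 mm wide).  The corneal
#' disc (radius 2.0 mm) is deliberately small enough to sit fully inside the
#' default fissure so its whole boundary is visible and its true perimeter is
#' an exact circle circumference.
#'
#' @param imageWidthPx,imageHeightPx frame size in px.
#' @param mmPerPxTrue true scale in mm per px.
#' @param eyeCenter,markerCenter (row, col) positions in px (0-based).
#' @param mrd1Mm,mrd2Mm margin-reflex distances in mm.
#' @param fissureWidthMm horizontal canthus-to-canthus extent in mm.
#' @param canthalTiltDeg lateral canthus elevation in degrees.
#' @param corneaRadiusMm,reflexRadiusMm disc radii in mm.
#' @param markerDiameterMm physical marker diameter in mm.
#' @param bumps data.frame(center_deg, width_deg, amplitude_mm) of contour
#'   deformations; empty for a normal scene.
#' @param noiseSd sd of Gaussian noise added to the rendered image.
#' @param rotationDeg rigid rotation of the eye geometry about its center.
#' @param seed RNG seed (render noise).
#' @return a validated \code{SceneParams} object.
#' @export
sceneParams <- function(imageWidthPx = 1200L, imageHeightPx = 797L,
                        mmPerPxTrue = 0.1, eyeCenter = c(400, 300),
                        mrd1Mm = 3.0, mrd2Mm = 6.0, fissureWidthMm = 28,
                        canthalTiltDeg = 0, corneaRadiusMm = 2.0,
                        reflexRadiusMm = 0.5, markerCenter = c(90, 600),
                        markerDiameterMm = 9.0,
                        bumps = data.frame(center_deg = numeric(0),
                                           width_deg = numeric(0),
                                           amplitude_mm = numeric(0)),
                        noiseSd = 0, rotationDeg = 0, seed = 1L) {
  new("SceneParams",
      imageWidthPx = as.integer(imageWidthPx),
      imageHeightPx = as.integer(imageHeightPx),
      mmPerPxTrue = mmPerPxTrue, eyeCenter = as.numeric(eyeCenter),
      mrd1Mm = mrd1Mm, mrd2Mm = mrd2Mm, fissureWidthMm = fissureWidthMm,
      canthalTiltDeg = canthalTiltDeg, corneaRadiusMm = corneaRadiusMm,
      reflexRadiusMm = reflexRadiusMm, markerCenter = as.numeric(markerCenter),
      markerDiameterMm = markerDiameterMm, bumps = bumps, noiseSd = noiseSd,
      rotationDeg = rotationDeg, seed = as.integer(seed))
}

# structure colors used by the renderer (and relied on by the color-rule
# segmentation backend)
.sceneColors <- list(
  skin = c(0.80, 0.62, 0.52), sclera = c(0.93, 0.93, 0.90),
  cornea = c(0.33, 0.20, 0.12), light_reflex = c(1.00, 1.00, 1.00),
  marker = c(0.10, 0.25, 0.75))

# ---- scene generation -------------------------------------------------------

#' Generate a synthetic eyelid scene with pixel-exact ground truth
#'
#' Rasterizes the analytic eye geometry described by \code{params} into four
#' binary masks (sclera, cornea, light reflex, marker), optionally renders a
#' flat-color RGB image with Gaussian noise, and records ground truth (true
#' MRDs, analytic eyelid arc lengths, the 360-degree radial contour profile,
#' abnormal degrees and canthus positions) computed from the analytic curves.
#'
#' @param params a \code{\link{sceneParams}} object.
#' @param renderImage render the RGB image (set FALSE when only the masks are
#'   needed; the oracle segmentation backend never looks at the image).
#' @return a \code{\link{Scene-class}} object.
#' @export
generateScene <- function(params, renderImage = TRUE) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  p <- params
  g <- .sceneGeometry(p)
  s <- g$s
  .stopIf(p@mrd1Mm <= p@reflexRadiusMm,
          "mrd1Mm: light reflex would not sit inside the palpebral fissure")
  H <- p@imageHeightPx; W <- p@imageWidthPx

  thetaFine <- seq(0, 2 * pi, length.out = 14401L)[-14401L]
  rhoFine <- .rho(thetaFine, g, p@bumps)
  .stopIf(any(rhoFine <= 0),
          "bumps: amplitude_mm collapses the fissure (margin radius <= 0)")
  .stopIf(any(rhoFine <= p@reflexRadiusMm / s),
          "bumps: deformation pushes the eyelid margin inside the light reflex")

  # --- fissure mask: polar membership test on pixel centers ------------------
  rmax <- max(rhoFine) + 2
  rr <- max(0, floor(g$o[1] - rmax)):min(H - 1, ceiling(g$o[1] + rmax))
  cc <- max(0, floor(g$o[2] - rmax)):min(W - 1, ceiling(g$o[2] + rmax))
  .stopIf(length(rr) < 2L || length(cc) < 2L,
          "eyeCenter: eye region falls outside the image frame")
  pr <- rep(rr + 0.5, times = length(cc))
  pc <- rep(cc + 0.5, each = length(rr))
  # inverse-rotate pixel centers into the canonical (unrotated) frame
  dv <- cbind(pr - g$o[1], pc - g$o[2]) %*% t(.rotMat(-g$rotDeg))
  rad <- sqrt(rowSums(dv^2))
  th <- atan2(dv[, 1] * g$w[1] + dv[, 2] * g$w[2],
              dv[, 1] * g$u0[1] + dv[, 2] * g$u0[2]) %% (2 * pi)
  inside <- rad < .rho(th, g, p@bumps) & rad > 0
  fissureBox <- matrix(inside, nrow = length(rr))
  fissure <- matrix(FALSE, H, W)
  fissure[rr + 1L, cc + 1L] <- fissureBox

  # --- discs ------------------------------------------------------------------
  disc <- function(center, radiusPx) {
    m <- matrix(FALSE, H, W)
    r0 <- max(0, floor(center[1] - radiusPx - 1))
    r1 <- min(H - 1, ceiling(center[1] + radiusPx + 1))
    c0 <- max(0, floor(center[2] - radiusPx - 1))
    c1 <- min(W - 1, ceiling(center[2] + radiusPx + 1))
    rws <- r0:r1; cls <- c0:c1
    d2 <- outer((rws + 0.5 - center[1])^2, (cls + 0.5 - center[2])^2, `+`)
    m[rws + 1L, cls + 1L] <- d2 < radiusPx^2
    m
  }
  corneaDisc <- disc(g$o, p@corneaRadiusMm / s)
  reflexDisc <- disc(g$o, p@reflexRadiusMm / s)
  marker <- disc(p@markerCenter, p@markerDiameterMm / (2 * s))
  cornea <- corneaDisc & fissure
  lightReflex <- reflexDisc & fissure
  sclera <- fissure & !corneaDisc

  # --- ground truth from the analytic curves ----------------------------------
  degs <- (0:359) * pi / 180
  profile <- .rho(degs, g, p@bumps) * s
  # margin points in final (rotated) image coordinates
  u0r <- as.numeric(g$rot %*% g$u0)
  wr <- as.numeric(g$rot %*% g$w)
  P <- cbind(g$o[1] + rhoFine * (u0r[1] * cos(thetaFine) + wr[1] * sin(thetaFine)),
             g$o[2] + rhoFine * (u0r[2] * cos(thetaFine) + wr[2] * sin(thetaFine)))
  nHalf <- (length(thetaFine)) / 2   # 7200: index of theta just below pi
  iUpper <- 1:(nHalf + 1L)           # theta in [0, pi]
  iLower <- c((nHalf + 1L):length(thetaFine), 1L) # theta in [pi, 2pi]
  arc <- function(idx) sum(sqrt(rowSums(diff(P[idx, , drop = FALSE])^2))) * s
  trueUpper <- arc(iUpper)
  trueLower <- arc(iLower)
  # true MRDs: vertical line through the reflex center against the margin
  mrds <- .verticalCrossings(P, g$o)
  ab <- integer(0)
  if (nrow(p@bumps)) {
    bump <- .bumpMm(degs, p@bumps)
    ab <- which(abs(bump) > 0) - 1L
  }
  canthi <- rbind(medial = g$o + as.numeric(g$rot %*% (g$cMed - g$o)),
                  lateral = g$o + as.numeric(g$rot %*% (g$cLat - g$o)))
  truth <- list(
    true_mrd1_mm = mrds["up"] * s, true_mrd2_mm = mrds["down"] * s,
    true_upper_len_mm = trueUpper, true_lower_len_mm = trueLower,
    true_profile_mm = as.numeric(profile), abnormal_degrees = ab,
    canthi_px = canthi, mm_per_px_true = s,
    reflex_center_px = g$o + 0) # reflex centered at the eye center
  names(truth$true_mrd1_mm) <- NULL
  names(truth$true_mrd2_mm) <- NULL

  img <- array(0, c(0, 0, 3))
  if (renderImage) {
    col <- .sceneColors
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      m <- matrix(col$skin[ch], H, W)
      m[sclera] <- col$sclera[ch]
      m[cornea] <- col$cornea[ch]
      m[lightReflex] <- col$light_reflex[ch]
      m[marker] <- col$marker[ch]
      img[, , ch] <- m
    }
    if (p@noiseSd > 0) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(p@seed)
      img <- img + array(stats::rnorm(length(img), 0, p@noiseSd), dim(img))
      img[img < 0] <- 0; img[img > 1] <- 1
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
  }

  new("Scene", image = img,
      masks = list(sclera = sclera, cornea = cornea,
                   light_reflex = lightReflex, marker = marker),
      truth = truth, params = p)
}

# rows of the upper/lower margin crossings of the vertical line through o,
# returned as distances (px) up/down from o
.verticalCrossings <- function(P, o) {
  dc <- P[, 2] - o[2]
  Pn <- rbind(P, P[1, ])
  cross <- which(dc * c(dc[-1], dc[1]) <= 0 & (dc != 0 | c(dc[-1], dc[1]) != 0))
  .stopIf(length(cross) < 2L, "internal: vertical line misses the margin")
  rows <- vapply(cross, function(i) {
    p1 <- Pn[i, ]; p2 <- Pn[i + 1, ]
    if (p2[2] == p1[2]) return(p1[1])
    t <- (o[2] - p1[2]) / (p2[2] - p1[2])
    p1[1] + t * (p2[1] - p1[1])
  }, numeric(1))
  up <- rows[rows <= o[1]]
  down <- rows[rows > o[1]]
  .stopIf(!length(up) || !length(down),
          "internal: reflex center not between the margins")
  c(up = o[1] - max(up), down = min(down) - o[1])
}

# ---- cohorts ----------------------------------------------------------------

.defaultVariation <- function() {
  list(mrd1 = c(mean = 3.1, sd = 0.8), mrd2 = c(mean = 5.8, sd = 1.1),
       width = c(mean = 28, sd = 1.5), tilt = c(mean = 4, sd = 2))
}

.defaultBumpSpec <- function() {
  list(nBumps = 1L, widthDeg = 10, amplitudeRange = c(2.5, 3.5))
}

# jittered per-subject parameters; hard floors keep the light reflex visible
# and the corneal disc fully inside the fissure
.drawSubjectParams <- function(base, variation, seed) {
  v <- utils::modifyList(.defaultVariation(), variation)
  set.seed(seed)
  draw <- function(spec, lo) max(lo, stats::rnorm(1, spec[["mean"]], spec[["sd"]]))
  mrd1 <- draw(v$mrd1, base@corneaRadiusMm + 0.4)
  mrd2 <- draw(v$mrd2, base@corneaRadiusMm + 0.4)
  width <- draw(v$width, 20)
  tilt <- stats::rnorm(1, v$tilt[["mean"]], v$tilt[["sd"]])
  initialize(base, mrd1Mm = mrd1, mrd2Mm = mrd2, fissureWidthMm = width,
             canthalTiltDeg = tilt, seed = as.integer(seed))
}

.drawBumps <- function(spec, seed) {
  b <- utils::modifyList(.defaultBumpSpec(), spec)
  set.seed(seed + 1L)
  # bump centers kept clear of the canthi (degrees 0 and 180) so deformations
  # do not displace the canthus reference points
  centers <- stats::runif(b$nBumps, 0, 1)
  centers <- ifelse(centers < 0.5,
                    20 + centers * 2 * 140,      # [20, 160): upper lid
                    200 + (centers - 0.5) * 2 * 140) # [200, 340): lower lid
  data.frame(center_deg = centers,
             width_deg = rep(b$widthDeg, b$nBumps),
             amplitude_mm = stats::runif(b$nBumps, b$amplitudeRange[1],
                                         b$amplitudeRange[2]))
}

#' Generate a reproducible cohort of synthetic scenes
#'
#' Draws per-subject fissure parameters (MRD1/MRD2, fissure width, canthal
#' tilt) from the variation spec, plants raised-cosine contour bumps in the
#' abnormal subjects, and derives one child seed per scene from the master
#' seed, so the cohort is fully reproducible.
#'
#' @param nNormal number of bump-free scenes (at least 2: the normative SD is
#'   undefined below that).
#' @param nAbnormal number of scenes with at least one bump.
#' @param variation named list overriding the per-subject jitter
#'   (means/SDs for \code{mrd1}, \code{mrd2}, \code{width}, \code{tilt}).
#' @param bumpSpec named list overriding bump generation: \code{nBumps},
#'   \code{widthDeg}, \code{amplitudeRange}.
#' @param seed master seed.
#' @param base template \code{SceneParams} for everything not jittered.
#' @param renderImage render RGB images (FALSE by default: cohort work uses
#'   the masks).
#' @return list of \code{Scene} objects, normals first; names are subject ids.
#' @export
generateCohort <- function(nNormal, nAbnormal = 0L, variation = list(),
                           bumpSpec = list(), seed = 1L,
                           base = sceneParams(), renderImage = FALSE) {
  .stopIf(nNormal < 2L, "nNormal must be at least 2 (normative SD undefined)")
  n <- nNormal + nAbnormal
  seeds <- deriveSeeds(seed, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- .drawSubjectParams(base, variation, seeds[i])
    if (i > nNormal) p@bumps <- .drawBumps(bumpSpec, seeds[i])
    out[[i]] <- generateScene(p, renderImage = renderImage)
  }
  names(out) <- sprintf("S%03d", seq_len(n))
  out
}

# ---- scene I/O --------------------------------------------------------------

.paramsToList <- function(p) {
  list(image_width_px = p@imageWidthPx, image_height_px = p@imageHeightPx,
       mm_per_px_true = p@mmPerPxTrue, eye_center = p@eyeCenter,
       mrd1_mm = p@mrd1Mm, mrd2_mm = p@mrd2Mm,
       fissure_width_mm = p@fissureWidthMm,
       canthal_tilt_deg = p@canthalTiltDeg,
       cornea_radius_mm = p@corneaRadiusMm,
       reflex_radius_mm = p@reflexRadiusMm,
       marker_center = p@markerCenter,
       marker_diameter_mm = p@markerDiameterMm,
       bumps = p@bumps, noise_sd = p@noiseSd,
       rotation_deg = p@rotationDeg, seed = p@seed)
}

.paramsFromList <- function(x) {
  bumps <- as.data.frame(x$bumps)
  if (!nrow(bumps)) bumps <- data.frame(center_deg = numeric(0),
                                        width_deg = numeric(0),
                                        amplitude_mm = numeric(0))
  sceneParams(imageWidthPx = x$image_width_px,
              imageHeightPx = x$image_height_px,
              mmPerPxTrue = x$mm_per_px_true, eyeCenter = x$eye_center,
              mrd1Mm = x$mrd1_mm, mrd2Mm = x$mrd2_mm,
              fissureWidthMm = x$fissure_width_mm,
              canthalTiltDeg = x$canthal_tilt_deg,
              corneaRadiusMm = x$cornea_radius_mm,
              reflexRadiusMm = x$reflex_radius_mm,
              markerCenter = x$marker_center,
              markerDiameterMm = x$marker_diameter_mm,
              bumps = bumps, noiseSd = x$noise_sd,
              rotationDeg = x$rotation_deg, seed = x$seed)
}

#' Write a scene to a directory / read it back
#'
#' The image is written as \code{image.png}, each mask as a single-channel
#' 0/255 PNG (\code{mask_<name>.png}) and the ground truth plus parameters as
#' \code{truth.json}; a \code{manifest.json} lists the files with MD5
#' checksums.  The mask and truth round-trip is lossless.
#'
#' @param scene a \code{Scene}.
#' @param directory output directory (created if missing).
#' @return path of the written manifest, invisibly.
#' @export
writeScene <- function(scene, directory) {
  stopifnot(is(scene, "Scene"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (length(scene@image)) {
    png::writePNG(scene@image, file.path(directory, "image.png"))
    files <- c(files, "image.png")
  }
  for (nm in names(scene@masks)) {
    f <- paste0("mask_", nm, ".png")
    png::writePNG(scene@masks[[nm]] * 1, file.path(directory, f))
    files <- c(files, f)
  }
  truth <- scene@truth
  truth$canthi_px <- list(medial = as.numeric(truth$canthi_px["medial", ]),
                          lateral = as.numeric(truth$canthi_px["lateral", ]))
  jsonlite::write_json(list(params = .paramsToList(scene@params), truth = truth),
                       file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, "truth.json")
  manifest <- list(files = files,
                   md5 = as.list(tools::md5sum(file.path(directory, files))))
  names(manifest$md5) <- files
  mpath <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
  invisible(mpath)
}

#' @rdname writeScene
#' @param directory directory previously written by \code{writeScene}.
#' @export
readScene <- function(directory) {
  tj <- file.path(directory, "truth.json")
  .stopIf(!file.exists(tj), "cannot read scene: missing file ", tj)
  x <- jsonlite::read_json(tj, simplifyVector = TRUE)
  params <- .paramsFromList(x$params)
  truth <- x$truth
  truth$canthi_px <- rbind(medial = as.numeric(truth$canthi_px$medial),
                           lateral = as.numeric(truth$canthi_px$lateral))
  truth$abnormal_degrees <- as.integer(truth$abnormal_degrees)
  masks <- list()
  for (nm in c("sclera", "cornea", "light_reflex", "marker")) {
    f <- file.path(directory, paste0("mask_", nm, ".png"))
    .stopIf(!file.exists(f), "cannot read scene: missing file ", f)
    masks[[nm]] <- png::readPNG(f) > 0.5
  }
  imgFile <- file.path(directory, "image.png")
  img <- if (file.exists(imgFile)) {
    a <- png::readPNG(imgFile)
    if (length(dim(a)) == 2L) array(a, c(dim(a), 3)) else a[, , 1:3, drop = FALSE]
  } else array(0, c(0, 0, 3))
  new("Scene", image = img, masks = masks, truth = truth, params = params)
}
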