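# End-to-end orchestration: scene directories -> measurements, profiles,
# normative fit and abnormality flags, with a run manifest.

#' Measure a scene end to end
#'
#' Runs segmentation (via the given backend), marker calibration, eyelid
#' measurement and contour profiling for one scene.
#'
#' @param scene a \code{Scene}.
#' @param backend a segmentation backend (default: the ground-truth oracle).
#' @param eyeSide "left" or "right".
#' @param origin contour origin convention, see \code{\link{buildFrame}}.
#' @param subjectId identifier.
#' @return list with \code{measurements} (\code{EyelidMeasurements}),
#'   \code{profile} (\code{ContourProfile}) and \code{calibration}.
#' @export
measureScene <- function(scene, backend = oracleBackend(), eyeSide = "left",
                         origin = "reflex_foot", subjectId = "subject") {
  stopifnot(is(scene, "Scene"))
  bundle <- segmentTargets(backend, scene)
  dPx <- estimateMarkerDiameter(bundle@masks$marker)
  cal <- calibrate(dPx, scene@params@markerDiameterMm)
  meas <- measureEye(bundle, cal, eyeSide = eyeSide)
  prof <- contourProfile(bundle, cal, eyeSide = eyeSide, origin = origin,
                         subjectId = subjectId)
  list(measurements = meas, profile = prof, calibration = cal)
}

#' Stream a cohort of synthetic scenes into contour profiles
#'
#' Generates the same scenes as \code{\link{generateCohort}} (identical
#' per-scene seed derivation) but measures each scene as it is produced and
#' keeps only the profile, measurements and truth summary, so large cohorts
#' stay within desk-scale memory.
#'
#' @inheritParams generateCohort
#' @param backend segmentation backend used for measurement.
#' @param origin contour origin convention.
#' @return list with \code{profiles} (list of \code{ContourProfile}),
#'   \code{isAbnormal} (logical), \code{measurements} (data.frame) and
#'   \code{truth} (data.frame of true values).
#' @export
cohortProfiles <- function(nNormal, nAbnormal = 0L, variation = list(),
                           bumpSpec = list(), seed = 1L,
                           base = sceneParams(), backend = oracleBackend(),
                           origin = "reflex_foot") {
  .stopIf(nNormal < 2L, "nNormal must be at least 2 (normative SD undefined)")
  n <- nNormal + nAbnormal
  seeds <- deriveSeeds(seed, n)
  profiles <- vector("list", n)
  meas <- vector("list", n)
  truths <- vector("list", n)
  ids <- sprintf("S%03d", seq_len(n))
  renderNeeded <- !identical(backend$name, "oracle")
  for (i in seq_len(n)) {
    p <- .drawSubjectParams(base, variation, seeds[i])
    if (i > nNormal) p@bumps <- .drawBumps(bumpSpec, seeds[i])
    scene <- generateScene(p, renderImage = renderNeeded)
    res <- measureScene(scene, backend = backend, origin = origin,
                        subjectId = ids[i])
    profiles[[i]] <- res$profile
    meas[[i]] <- cbind(subject_id = ids[i],
                       as.data.frame(res$measurements))
    truths[[i]] <- data.frame(
      subject_id = ids[i],
      true_mrd1_mm = scene@truth$true_mrd1_mm,
      true_mrd2_mm = scene@truth$true_mrd2_mm,
      true_upper_len_mm = scene@truth$true_upper_len_mm,
      true_lower_len_mm = scene@truth$true_lower_len_mm,
      true_cornea_perimeter_mm = 2 * pi * p@corneaRadiusMm,
      mm_per_px_true = p@mmPerPxTrue,
      bump_center_deg = if (nrow(p@bumps)) p@bumps$center_deg[1] else NA_real_,
      bump_width_deg = if (nrow(p@bumps)) p@bumps$width_deg[1] else NA_real_,
      bump_amplitude_mm = if (nrow(p@bumps)) p@bumps$amplitude_mm[1] else NA_real_)
  }
  names(profiles) <- ids
  list(profiles = profiles, isAbnormal = seq_len(n) > nNormal,
       measurements = do.call(rbind, meas), truth = do.call(rbind, truths))
}

#' Run the full pipeline over a directory of scenes
#'
#' Each subdirectory of \code{inputDir} holding a scene written by
#' \code{\link{writeScene}} is read, segmented with the configured backend,
#' measured and profiled.  Per-scene failures are logged and skipped; the run
#' continues over the remaining subjects.  Results, profiles, the resolved
#' configuration and MD5 checksums of every artifact are written under
#' \code{outDir}.
#'
#' @param config named list: \code{inputDir}, \code{outDir}, and optionally
#'   \code{backend} ("oracle", "color" or "external"), \code{eyeSide},
#'   \code{origin}, \code{zCrit}, \code{ks}, \code{seed},
#'   \code{fitNormative} (logical: fit on scenes without planted bumps and
#'   flag everyone).
#' @return the run manifest (list), invisibly; written as
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config) {
  cfg <- utils::modifyList(list(
    backend = "oracle", eyeSide = "left", origin = "reflex_foot",
    zCrit = stats::qnorm(0.975), ks = c(4L, 8L, 16L, 24L, 32L, 64L, 128L, 256L),
    seed = 1L, fitNormative = FALSE), config)
  .stopIf(is.null(cfg$inputDir) || is.null(cfg$outDir),
          "config must name inputDir and outDir")
  dirs <- list.dirs(cfg$inputDir, recursive = FALSE)
  .stopIf(length(dirs) == 0L, "no scene directories under ", cfg$inputDir)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

  rows <- list(); profs <- list(); labels <- logical(0)
  failures <- list()
  for (d in dirs) {
    id <- basename(d)
    res <- tryCatch({
      scene <- readScene(d)
      backend <- switch(cfg$backend,
                        oracle = oracleBackend(),
                        color = colorBackend(),
                        external = externalBackend(d),
                        stop("unknown backend: ", cfg$backend))
      c(measureScene(scene, backend = backend, eyeSide = cfg$eyeSide,
                     origin = cfg$origin, subjectId = id),
        list(hasBumps = nrow(scene@params@bumps) > 0L))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      message("subject ", id, " failed: ", conditionMessage(res))
      next
    }
    rows[[id]] <- cbind(subject_id = id, eye = cfg$eyeSide,
                        as.data.frame(res$measurements))
    profs[[id]] <- res$profile
    labels <- c(labels, res$hasBumps)
  }
  .stopIf(length(rows) == 0L, "all subjects failed")

  resultsCsv <- file.path(cfg$outDir, "results.csv")
  utils::write.csv(do.call(rbind, rows), resultsCsv, row.names = FALSE)
  profMat <- vapply(profs, profileDistances, numeric(360))
  profCsv <- file.path(cfg$outDir, "profiles.csv")
  utils::write.csv(data.frame(degree = 0:359, profMat, check.names = FALSE),
                   profCsv, row.names = FALSE)
  artifacts <- c(resultsCsv, profCsv)

  if (isTRUE(cfg$fitNormative) && sum(!labels) >= 2L && any(labels)) {
    sweep <- verificationSweep(profs, labels, ks = cfg$ks, zCrit = cfg$zCrit)
    sweepCsv <- file.path(cfg$outDir, "verification.csv")
    utils::write.csv(sweep, sweepCsv, row.names = FALSE)
    plotVerificationSweep(sweep, file.path(cfg$outDir, "verification.png"))
    artifacts <- c(artifacts, sweepCsv,
                   file.path(cfg$outDir, "verification.png"))
  }

  manifest <- list(config = cfg[order(names(cfg))],
                   n_subjects = length(rows),
                   failures = failures,
                   artifacts = as.list(stats::setNames(
                     tools::md5sum(artifacts), basename(artifacts))))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
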