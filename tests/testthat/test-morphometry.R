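test_that("marker diameter is the equivalent-circle diameter", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(estimateMarkerDiameter(m), 2 / sqrt(pi), tolerance = 1e-12)

  disk <- rasterDisk(45)
  d <- estimateMarkerDiameter(disk)
  expect_gt(d, 89.1)
  expect_lt(d, 90.9)

  expect_error(estimateMarkerDiameter(matrix(FALSE, 3, 3)), "marker not found")
})

test_that("calibration is the marker proportionality equation", {
  expect_equal(mmPerPx(calibrate(90, 9.0)), 0.1)
  expect_equal(mmPerPx(calibrate(9, 9.0)), 1.0)
  expect_equal(mmPerPx(calibrate(180, 9.0)), mmPerPx(calibrate(90, 9.0)) / 2)
  expect_error(calibrate(-1, 9), "positive")
  expect_error(calibrate(90, 0), "positive")
})

test_that("canthi are the horizontal endpoints with the median tie rule", {
  bar <- matrix(FALSE, 12, 10); bar[6, ] <- TRUE # row 5, cols 0..9 (0-based)
  ca <- findCanthi(bar, eyeSide = "left")
  expect_identical(ca$lateral, c(5L, 0L))
  expect_identical(ca$medial, c(5L, 9L))
  caR <- findCanthi(bar, eyeSide = "right")
  expect_identical(caR$medial, c(5L, 0L))

  tri <- matrix(FALSE, 10, 6)
  tri[5:7, 1] <- TRUE # extreme column holds rows {4,5,6}: median row 5
  tri[5, 2:5] <- TRUE
  expect_identical(findCanthi(tri)$lateral, c(5L, 0L))
  expect_error(findCanthi(matrix(FALSE, 3, 3)), "empty")
})

test_that("reflex center is the foreground centroid with pixel-center convention", {
  m <- matrix(FALSE, 6, 6); m[3, 4] <- TRUE # pixel (2, 3)
  expect_equal(reflexCenter(m), c(2.5, 3.5))
  m2 <- matrix(FALSE, 6, 6); m2[3, 3:4] <- TRUE
  expect_equal(reflexCenter(m2), c(2.5, 3.0))
  disk <- rasterDisk(10, 40) # symmetric about (20, 20)
  expect_equal(reflexCenter(disk), c(20, 20), tolerance = 1e-9)
  expect_error(reflexCenter(matrix(FALSE, 2, 2)), "light reflex not detected")
})

test_that("margins split symmetrically on a rectangle", {
  m <- matrix(FALSE, 21, 41); m[6:15, 6:35] <- TRUE
  ca <- list(medial = c(10L, 35L), lateral = c(10L, 5L)) # edge midpoints
  mg <- splitMargins(m, ca)
  cal <- calibrate(1, 1)
  expect_equal(marginLength(mg$upper, cal), marginLength(mg$lower, cal))
  expect_lt(min(mg$upper@vertices[, 1]), min(mg$lower@vertices[, 1]))
  # both chains share exactly the two canthus vertices
  shared <- intersect(paste(mg$upper@vertices[, 1], mg$upper@vertices[, 2]),
                      paste(mg$lower@vertices[, 1], mg$lower@vertices[, 2]))
  expect_length(shared, 2L)

  flat <- matrix(FALSE, 5, 10); flat[3, 2:9] <- TRUE
  expect_error(splitMargins(flat, list(medial = c(2L, 8L),
                                       lateral = c(2L, 1L))),
               "degenerate")
  expect_error(splitMargins(m, list(medial = c(1L, 20L), lateral = ca$lateral)),
               "farther than")
})

test_that("MRDs interpolate the margins at the reflex column", {
  m <- matrix(FALSE, 21, 41); m[6:15, 6:35] <- TRUE
  mg <- splitMargins(m, list(medial = c(10L, 35L), lateral = c(10L, 5L)))
  cal <- calibrate(1, 1)
  # center on the upper margin: MRD1 = 0
  top <- min(mg$upper@vertices[, 1])
  mrds0 <- computeMRDs(mg$upper, mg$lower, c(top, 20.5), cal)
  expect_equal(unname(mrds0["mrd1_mm"]), 0)
  # shifting the center down by k px moves MRD1 up and MRD2 down by k * scale
  for (k in c(1, 3.5)) {
    a <- computeMRDs(mg$upper, mg$lower, c(top + 2, 20.5), cal)
    b <- computeMRDs(mg$upper, mg$lower, c(top + 2 + k, 20.5), cal)
    expect_equal(unname(b["mrd1_mm"] - a["mrd1_mm"]), k)
    expect_equal(unname(a["mrd2_mm"] - b["mrd2_mm"]), k)
  }
  # reflex outside the chains' column span
  expect_error(computeMRDs(mg$upper, mg$lower, c(10, 50), cal),
               "does not intersect")
  # reflex covered by the upper lid is out of measurement range
  expect_error(computeMRDs(mg$upper, mg$lower, c(top - 3, 20.5), cal),
               "negative MRD1")
})

test_that("measureEye recovers the synthetic truth end to end", {
  sc <- generateScene(smallParams(mrd1Mm = 3.0, mrd2Mm = 6.0), renderImage = FALSE)
  res <- measureScene(sc)
  m <- res$measurements
  scale <- mmPerPx(res$calibration)
  expect_lt(abs(m@mrd1Mm - 3.0), 0.15)
  expect_lt(abs(m@mrd2Mm - 6.0), 0.15)
  expect_lt(abs(m@upperLenMm / sc@truth$true_upper_len_mm - 1), 0.03)
  expect_lt(abs(m@lowerLenMm / sc@truth$true_lower_len_mm - 1), 0.03)
  # canthi within 2 px of the analytic truth
  expect_lt(max(abs(m@canthiPx - sc@truth$canthi_px)), 2)

  # anatomically sized cornea: boundary within 2% of its circumference
  deep <- generateScene(sceneParams(mrd1Mm = 6.5, mrd2Mm = 7.5,
                                    corneaRadiusMm = 5.5),
                        renderImage = FALSE)
  resDeep <- measureScene(deep)
  expect_lt(abs(resDeep$measurements@corneaPerimeterMm / (2 * pi * 5.5) - 1),
            0.02)

  # a missing reflex mask fails naming the stage
  bundle <- segmentTargets(oracleBackend(), sc)
  bundle@masks$light_reflex[] <- FALSE
  expect_error(suppressWarnings(measureEye(bundle, res$calibration)),
               "light reflex")
})

test_that("millimetre measurements are invariant to the acquisition scale", {
  for (s in c(0.08, 0.125)) {
    sc <- generateScene(sceneParams(mmPerPxTrue = s), renderImage = FALSE)
    res <- measureScene(sc)
    expect_lt(abs(res$measurements@mrd1Mm - 3.0), 2 * s)
    expect_lt(abs(res$measurements@mrd2Mm - 6.0), 2 * s)
    expect_lt(abs(res$measurements@upperLenMm /
                  sc@truth$true_upper_len_mm - 1), 0.03)
  }
})
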