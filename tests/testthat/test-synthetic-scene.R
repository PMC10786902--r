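test_that("ground truth echoes the analytic inputs", {
  sc <- generateScene(smallParams(mrd1Mm = 3.0, mrd2Mm = 6.0),
                      renderImage = FALSE)
  expect_equal(sc@truth$true_mrd1_mm, 3.0, tolerance = 1e-8)
  expect_equal(sc@truth$true_mrd2_mm, 6.0, tolerance = 1e-8)
  expect_length(sc@truth$true_profile_mm, 360)
  expect_true(all(sc@truth$true_profile_mm > 0))
  expect_length(sc@truth$abnormal_degrees, 0)
})

test_that("profile truth at 0 and 180 degrees equals the canthus distances", {
  sc <- generateScene(smallParams(canthalTiltDeg = 3), renderImage = FALSE)
  o <- sc@truth$reflex_center_px
  dLat <- sqrt(sum((sc@truth$canthi_px["lateral", ] - o)^2)) * 0.1
  dMed <- sqrt(sum((sc@truth$canthi_px["medial", ] - o)^2)) * 0.1
  expect_equal(sc@truth$true_profile_mm[1], dLat, tolerance = 1e-6)
  expect_equal(sc@truth$true_profile_mm[181], dMed, tolerance = 1e-6)
})

test_that("a bump raises the profile by its amplitude at its center", {
  base <- generateScene(smallParams(), renderImage = FALSE)
  bumped <- generateScene(smallParams(
    bumps = data.frame(center_deg = 90, width_deg = 20, amplitude_mm = 2)),
    renderImage = FALSE)
  d <- bumped@truth$true_profile_mm - base@truth$true_profile_mm
  expect_equal(d[91], 2, tolerance = 1e-8)
  expect_setequal(bumped@truth$abnormal_degrees, 81:99)
  expect_true(all(abs(d[setdiff(0:359, 80:100) + 1]) < 1e-12))
})

test_that("rasterized discs have the analytic area (radius >= 20 px)", {
  for (rMm in c(2.0, 4.5)) {
    sc <- generateScene(smallParams(mrd1Mm = rMm + 0.5, mrd2Mm = rMm + 1,
                                    corneaRadiusMm = rMm),
                        renderImage = FALSE)
    rPx <- rMm / 0.1
    ratio <- sum(sc@masks$cornea) / (pi * rPx^2)
    expect_gt(ratio, 0.98)
    expect_lt(ratio, 1.02)
  }
  sc <- generateScene(smallParams(), renderImage = FALSE)
  ratio <- sum(sc@masks$marker) / (pi * 45^2)
  expect_gt(ratio, 0.98)
  expect_lt(ratio, 1.02)
})

test_that("scene generation is deterministic and masks are consistent", {
  p <- smallParams(noiseSd = 0.02, seed = 7L)
  a <- generateScene(p)
  b <- generateScene(p)
  expect_identical(a@masks, b@masks)
  expect_identical(a@image, b@image)
  m <- a@masks
  expect_false(any(m$light_reflex & !m$cornea))
  fissure <- m$sclera | m$cornea
  expect_false(any(m$cornea & !fissure))
  expect_true(all(vapply(m, function(x) identical(dim(x), dim(m$sclera)),
                         logical(1))))
})

test_that("invalid parameters fail naming the offending field", {
  expect_error(smallParams(reflexRadiusMm = 3, corneaRadiusMm = 2),
               "reflexRadiusMm")
  expect_error(smallParams(mrd2Mm = -1), "mrd2Mm")
  expect_error(smallParams(mrd1Mm = -7, mrd2Mm = 6), "fissure")
  expect_error(smallParams(markerCenter = c(260, 200)), "marker")
  expect_error(generateScene(smallParams(mrd1Mm = 0.4, reflexRadiusMm = 0.5)),
               "reflex")
})

test_that("cohorts are reproducible and labeled as requested", {
  a <- generateCohort(4, 0, seed = 7, base = smallParams())
  expect_length(a, 4)
  expect_true(all(vapply(a, function(s)
    length(s@truth$abnormal_degrees) == 0, logical(1))))

  b1 <- generateCohort(3, 2, seed = 7, base = smallParams())
  b2 <- generateCohort(3, 2, seed = 7, base = smallParams())
  expect_identical(lapply(b1, function(s) s@truth),
                   lapply(b2, function(s) s@truth))
  expect_true(all(vapply(b1[4:5], function(s)
    length(s@truth$abnormal_degrees) > 0, logical(1))))

  zeroVar <- list(mrd1 = c(mean = 3.1, sd = 0), mrd2 = c(mean = 5.8, sd = 0),
                  width = c(mean = 28, sd = 0), tilt = c(mean = 4, sd = 0))
  c1 <- generateCohort(2, 1, variation = zeroVar,
                       bumpSpec = list(amplitudeRange = c(3, 3)),
                       seed = 1, base = smallParams())
  expect_identical(c1[[1]]@masks, c1[[2]]@masks)
  expect_identical(c1[[1]]@truth, c1[[2]]@truth)
  expect_error(generateCohort(1, 0, base = smallParams()), "at least 2")
})

test_that("scene round-trips losslessly through a directory", {
  sc <- generateScene(smallParams(
    bumps = data.frame(center_deg = 120, width_deg = 12, amplitude_mm = 2.5)))
  d <- tempfile("scene")
  manifest <- writeScene(sc, d)
  expect_true(file.exists(manifest))
  back <- readScene(d)
  expect_identical(back@masks, sc@masks)
  for (f in c("true_mrd1_mm", "true_mrd2_mm", "true_upper_len_mm",
              "true_lower_len_mm")) {
    expect_equal(back@truth[[f]], sc@truth[[f]], tolerance = 1e-9)
  }
  expect_equal(back@truth$true_profile_mm, sc@truth$true_profile_mm,
               tolerance = 1e-9)
  expect_identical(back@truth$abnormal_degrees, sc@truth$abnormal_degrees)
  unlink(d, recursive = TRUE)
  expect_error(readScene(tempfile("nothere")), "missing file")
})
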