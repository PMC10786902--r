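test_that("the reference frame puts its origin at the reflex foot", {
  # horizontal intercanthal line through rows 0; reflex at (3, 5):
  # foot of the perpendicular is (0, 5)
  fr <- buildFrame(list(medial = c(0, 0), lateral = c(0, 10)), c(3, 5))
  expect_equal(fr@origin, c(0, 5))
  expect_equal(fr@tiltDeg, 0)

  frMid <- buildFrame(list(medial = c(0, 0), lateral = c(0, 10)), c(3, 5),
                      origin = "intercanthal_midpoint")
  expect_equal(frMid@origin, c(0, 5))
  frMid2 <- buildFrame(list(medial = c(0, 0), lateral = c(0, 10)), c(3, 2),
                       origin = "intercanthal_midpoint")
  expect_equal(frMid2@origin, c(0, 5)) # midpoint ignores the reflex

  # tilted canthi have equal height along the frame's up direction
  med <- c(12, 40); lat <- c(8, 10)
  frT <- buildFrame(list(medial = med, lateral = lat), c(15, 25))
  hMed <- sum((med - frT@origin) * frT@upDir)
  hLat <- sum((lat - frT@origin) * frT@upDir)
  expect_lt(abs(hMed - hLat), 1e-6)
  expect_equal(frT@tiltDeg, atan2(12 - 8, 30) * 180 / pi)

  expect_error(buildFrame(list(medial = c(1, 1), lateral = c(1, 1)), c(0, 0)),
               "coincide")
})

test_that("a circular fissure profiles at its radius in every direction", {
  disk <- rasterDisk(50, 128) # radius 50 px, center (64, 64)
  ca <- findCanthi(disk)
  mg <- splitMargins(disk, ca)
  fr <- buildFrame(list(medial = mg$canthiVertices["medial", ],
                        lateral = mg$canthiVertices["lateral", ]),
                   c(64, 64))
  prof <- radialProfile(mg$upper, mg$lower, fr, calibrate(1, 0.1))
  d <- profileDistances(prof)
  expect_length(d, 360)
  # 2 px: median-row canthus snap shifts the origin by <= 1 px, boundary
  # rasterization contributes <= ~0.7 px more
  expect_true(all(abs(d - 5.0) < 0.2))
})

test_that("profile degrees 0 and 180 measure the canthus distances", {
  sc <- generateScene(smallParams(canthalTiltDeg = 4), renderImage = FALSE)
  res <- measureScene(sc)
  d <- profileDistances(res$profile)
  # single-raster quantization tolerance: at the canthi the rays graze the
  # margin, so the radial error is the boundary displacement divided by the
  # sine of the incidence angle
  tol <- profileTolMm(sc@truth$true_profile_mm, 0.1, 280, q = 1)
  expect_lt(abs(d[1] - sc@truth$true_profile_mm[1]), tol[1])
  expect_lt(abs(d[181] - sc@truth$true_profile_mm[181]), tol[181])
})

test_that("a planted bump appears in the measured profile at its degree", {
  base <- measureScene(generateScene(smallParams(), renderImage = FALSE))
  bumped <- measureScene(generateScene(
    smallParams(bumps = data.frame(center_deg = 90, width_deg = 10,
                                   amplitude_mm = 2)),
    renderImage = FALSE))
  delta <- profileDistances(bumped$profile)[91] -
    profileDistances(base$profile)[91]
  expect_gt(delta, 1.7)
  expect_lt(delta, 2.3)
})

test_that("partition schemes follow the printed-interval conventions", {
  s24 <- makeScheme(24)
  expect_equal(s24@intervalDeg, 15.0)
  expect_identical(formatIntervalDeg(s24@intervalDeg), "15.0")
  expect_identical(formatIntervalDeg(makeScheme(32)@intervalDeg), "11.3")
  expect_identical(formatIntervalDeg(makeScheme(64)@intervalDeg), "5.6")
  expect_identical(formatIntervalDeg(makeScheme(128)@intervalDeg), "2.8")
  expect_identical(formatIntervalDeg(makeScheme(256)@intervalDeg), "1.4")

  s4 <- makeScheme(4)
  expect_identical(unique(s4@segmentOfDegree[1:90]), 1L)   # [0, 90)
  expect_identical(unique(s4@segmentOfDegree[91:180]), 2L) # [90, 180)
  expect_error(makeScheme(1), "k must be")
  expect_error(makeScheme(720), "k must be")
})

test_that("segment values are the per-segment means of the profile", {
  const <- syntheticProfile(rep(5, 360))
  for (k in c(4, 24, 256))
    expect_true(all(segmentValues(const, makeScheme(k)) == 5))

  p <- syntheticProfile(seq(0.1, 36, by = 0.1))
  expect_equal(segmentValues(p, makeScheme(360)), profileDistances(p))

  step <- syntheticProfile(c(rep(1, 90), rep(2, 270)))
  expect_equal(segmentValues(step, makeScheme(4)), c(1, 2, 2, 2))
})

test_that("the normative fit is the per-segment sample mean and SD", {
  p1 <- syntheticProfile(rep(5, 360))
  model0 <- fitNormative(list(p1, p1), makeScheme(24))
  expect_true(all(model0@sdMm == 0))
  expect_true(all(model0@meanMm == 5))
  expect_error(fitNormative(list(p1), makeScheme(24)), "at least 2")

  set.seed(19)
  sigma <- 0.4
  profs <- lapply(1:100, function(i)
    syntheticProfile(5 + rep(rnorm(24, 0, sigma), each = 15)))
  model <- fitNormative(profs, makeScheme(24))
  expect_true(all(abs(model@sdMm / sigma - 1) < 0.25))
  vals <- vapply(profs, segmentValues, numeric(24), scheme = makeScheme(24))
  expect_equal(model@meanMm, rowMeans(vals))
})

test_that("abnormal segments are flagged outside mean +/- z * SD", {
  set.seed(23)
  profs <- lapply(1:50, function(i) syntheticProfile(rnorm(360, 5, 0.2)))
  scheme <- makeScheme(24)
  model <- fitNormative(profs, scheme)

  atMean <- syntheticProfile(rep(model@meanMm, each = 15))
  expect_false(flagAbnormal(atMean, model)@isAbnormalSubject)

  shifted <- rep(model@meanMm, each = 15)
  shifted[106:120] <- shifted[106:120] + 10 * model@sdMm[8] # segment 8
  rep8 <- flagAbnormal(syntheticProfile(shifted), model)
  expect_identical(rep8@abnormalSegments, 8L)
  expect_true(rep8@isAbnormalSubject)

  # z -> infinity flags nothing on the fitting cohort
  loose <- fitNormative(profs, scheme, zCrit = 1e9)
  expect_false(any(vapply(profs, function(p)
    flagAbnormal(p, loose)@isAbnormalSubject, logical(1))))

  # SD = 0 segments flag any deviation from the mean
  strict <- fitNormative(list(syntheticProfile(rep(5, 360)),
                              syntheticProfile(rep(5, 360))), scheme)
  off <- syntheticProfile(c(rep(5.001, 15), rep(5, 345)))
  expect_identical(flagAbnormal(off, strict)@abnormalSegments, 1L)

  # percentile intervals span the empirical central 95% range
  pm <- fitNormative(profs, scheme, method = "percentile")
  vals <- vapply(profs, segmentValues, numeric(24), scheme = scheme)
  expect_equal(pm@loMm, apply(vals, 1, quantile, probs = 0.025, names = FALSE))
  expect_equal(pm@hiMm, apply(vals, 1, quantile, probs = 0.975, names = FALSE))
  expect_true(flagAbnormal(syntheticProfile(shifted), pm)@isAbnormalSubject)
})

test_that("refining a partition keeps a displaced full segment abnormal", {
  set.seed(31)
  profs <- lapply(1:60, function(i) syntheticProfile(rnorm(360, 5, 0.2)))
  bad <- rnorm(360, 5, 0.2)
  bad[91:180] <- bad[91:180] + 3 # segment 2 of k=4, fully displaced
  badProf <- syntheticProfile(bad)
  for (k in c(4, 8, 16)) { # 4 | 8 | 16
    model <- fitNormative(profs, makeScheme(k))
    expect_true(flagAbnormal(badProf, model)@isAbnormalSubject)
  }
})

test_that("the verification sweep reports sensitivity and specificity", {
  set.seed(37)
  profs <- lapply(1:20, function(i) syntheticProfile(rnorm(360, 5, 0.1)))
  bad <- rnorm(360, 5, 0.1); bad[100:109] <- bad[100:109] + 5
  profs <- c(profs, list(syntheticProfile(bad)))
  labels <- c(rep(FALSE, 20), TRUE)
  sw <- verificationSweep(profs, labels, ks = c(4, 24, 256))
  expect_identical(sw$k, c(4L, 24L, 256L))
  expect_true(all(sw$sensitivity == 1.0)) # huge bump flagged at every k
  expect_true(all(sw$sensitivity >= 0 & sw$sensitivity <= 1))
  expect_true(all(sw$specificity >= 0 & sw$specificity <= 1))
  expect_error(verificationSweep(profs, rep(FALSE, 21)), "abnormal")
  expect_error(verificationSweep(profs[21], TRUE), "normal")
})
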