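test_that("ICC(2,1) matches an independent reference implementation", {
  # absolute-agreement single-measure ICC computed for this fixture with
  # pingouin.intraclass_corr (ICC type A,1): 0.9374468085106386
  a <- c(9.0, 9.5, 7.2, 8.1, 10.3, 6.6, 9.9, 8.8)
  b <- c(9.4, 9.2, 7.9, 8.3, 10.9, 7.1, 10.4, 8.6)
  res <- iccAgreement(a, b)
  expect_equal(res$icc, 0.9374468085106386, tolerance = 1e-12)
  expect_identical(res$band, "excellent")
  # symmetric in the two raters
  expect_equal(iccAgreement(b, a)$icc, res$icc)
})

test_that("ICC reaches 1 on identical ratings and ~0 on independent noise", {
  a <- c(1, 5, 3, 9, 7, 2)
  expect_equal(iccAgreement(a, a)$icc, 1.0)
  expect_identical(iccAgreement(a, a)$band, "excellent")

  set.seed(5)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(abs(iccAgreement(x, y)$icc), 0.1)

  expect_error(iccAgreement(c(1, 2), c(1, 2)), "at least 3")
  expect_error(iccAgreement(rep(2, 5), rep(2, 5)), "zero total variance")
})

test_that("absolute agreement is sensitive to a systematic offset", {
  set.seed(8)
  a <- rnorm(200, 10, 2)
  noise <- rnorm(200, 0, 0.2)
  baseline <- iccAgreement(a, a + noise)$icc
  offset <- iccAgreement(a + 1.0, a + noise)$icc
  expect_lt(offset, baseline)
  # the consistency variant ignores the offset entirely
  expect_equal(iccAgreement(a + 1.0, a + noise, type = "consistency")$icc,
               iccAgreement(a, a + noise, type = "consistency")$icc)
  # consistency ICC for the pingouin fixture: ICC(C,1) = 0.9582427142235755
  x <- c(9.0, 9.5, 7.2, 8.1, 10.3, 6.6, 9.9, 8.8)
  y <- c(9.4, 9.2, 7.9, 8.3, 10.9, 7.1, 10.4, 8.6)
  expect_equal(iccAgreement(x, y, type = "consistency")$icc,
               0.9582427142235755, tolerance = 1e-12)
})

test_that("qualitative bands follow the conventional cutpoints", {
  band <- lidmetrics:::.iccBand
  expect_identical(band(0.39), "poor")
  expect_identical(band(0.40), "fair")
  expect_identical(band(0.599), "fair")
  expect_identical(band(0.60), "good")
  expect_identical(band(0.749), "good")
  expect_identical(band(0.75), "excellent")
  expect_identical(band(1.00), "excellent")
})

test_that("Bland-Altman recovers a planted constant offset exactly", {
  a <- c(3.1, 4.2, 5.0, 6.3, 2.8)
  ba <- blandAltman(a, a - 0.2)
  expect_equal(ba$mean_diff, 0.2)
  expect_equal(ba$loa_low, 0.2)
  expect_equal(ba$loa_high, 0.2)

  # swapping the methods negates the difference and mirrors the limits
  b <- a + rnorm(5)
  f <- blandAltman(a, b); g <- blandAltman(b, a)
  expect_equal(g$mean_diff, -f$mean_diff)
  expect_equal(g$loa_low, -f$loa_high)
  expect_equal(g$loa_high, -f$loa_low)
  expect_error(blandAltman(a, b[1:3]), "equal length")
})

test_that("a simulated constant bias lands inside the mean-difference CI", {
  set.seed(12)
  b <- rnorm(300, 5, 1.5)
  a <- b + rnorm(300, 0.214, 0.3) # offset structure of a typical MRD bias
  ba <- blandAltman(a, b)
  expect_gt(0.214, ba$ci95_mean_diff[1])
  expect_lt(0.214, ba$ci95_mean_diff[2])
})

test_that("the limits of agreement cover ~95% of Gaussian differences", {
  set.seed(21)
  b <- rnorm(5000, 10, 1)
  a <- b + rnorm(5000, 0.5, 0.8)
  ba <- blandAltman(a, b)
  d <- a - b
  coverage <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gt(coverage, 0.93)
  expect_lt(coverage, 0.97)
})

test_that("agreementReport combines ICC and Bland-Altman consistently", {
  set.seed(33)
  b <- rnorm(50, 30, 5)
  a <- b + rnorm(50, 1.4, 1.0)
  rep <- agreementReport(a, b)
  expect_s4_class(rep, "AgreementReport")
  df <- as.data.frame(rep)
  expect_equal(df$mean_diff, mean(a - b))
  expect_true(df$loa_low <= df$mean_diff && df$mean_diff <= df$loa_high)
  pc <- pairedCompare(a, b)
  expect_true(pc$p_paired_t < 0.05) # the planted bias is detectable
  expect_true(is.numeric(pc$p_wilcoxon))
})
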