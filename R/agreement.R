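# Method-comparison statistics: intraclass correlation and Bland-Altman
# limits of agreement, used to validate automated measurements against a
# reference rater.

# single-measure ICC from the two-way mean squares: ICC(2,1) (absolute
# agreement) or ICC(3,1) (consistency)
.iccSingle <- function(a, b, type = "agreement") {
  x <- cbind(a, b)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  rowM <- rowMeans(x); colM <- colMeans(x)
  ssTotal <- sum((x - grand)^2)
  ssRows <- k * sum((rowM - grand)^2)
  ssCols <- n * sum((colM - grand)^2)
  ssErr <- ssTotal - ssRows - ssCols
  msr <- ssRows / (n - 1)
  msc <- ssCols / (k - 1)
  mse <- ssErr / ((n - 1) * (k - 1))
  den <- if (type == "agreement")
    msr + (k - 1) * mse + k * (msc - mse) / n
  else msr + (k - 1) * mse
  .stopIf(abs(den) < 1e-300, "zero total variance: ICC undefined")
  (msr - mse) / den
}

.iccBand <- function(icc) {
  if (icc < 0.40) "poor"
  else if (icc < 0.60) "fair"
  else if (icc < 0.75) "good"
  else "excellent"
}

#' Intraclass correlation between two measurement methods
#'
#' ICC(2,1): two-way random effects, absolute agreement, single measure --
#' the variant appropriate when two measurement systems are compared for
#' interchangeability.  The qualitative band follows the conventional
#' cutpoints: below 0.40 poor, 0.40-0.60 fair, 0.60-0.75 good, 0.75-1.00
#' excellent.
#'
#' @param a,b paired numeric vectors of equal length (>= 3), finite.
#' @param type "agreement" for ICC(2,1) (default), "consistency" for
#'   ICC(3,1), which ignores systematic offsets between the methods.
#' @return list with \code{icc} and \code{band}.
#' @export
iccAgreement <- function(a, b, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  .stopIf(length(a) != length(b), "a and b must have equal length")
  .stopIf(length(a) < 3L, "need at least 3 pairs")
  .stopIf(any(!is.finite(a)) || any(!is.finite(b)),
          "inputs must be finite")
  .stopIf(stats::var(c(a, b)) == 0, "zero total variance: ICC undefined")
  icc <- .iccSingle(a, b, type = type)
  list(icc = icc, band = .iccBand(icc))
}

#' Bland-Altman mean difference and 95\% limits of agreement
#'
#' Differences d = a - b: mean difference, limits of agreement
#' mean +/- 1.96 * SD(d) (n - 1 denominator), and a t-based 95\% confidence
#' interval for the mean difference.
#'
#' @param a,b paired numeric vectors of equal length (>= 3).
#' @return list with \code{mean_diff}, \code{loa_low}, \code{loa_high},
#'   \code{ci95_mean_diff} (length-2), \code{sd_diff}, \code{n}.
#' @export
blandAltman <- function(a, b) {
  .stopIf(length(a) != length(b), "a and b must have equal length")
  .stopIf(length(a) < 3L, "need at least 3 pairs")
  d <- a - b
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  se <- sdd / sqrt(n)
  tcrit <- stats::qt(0.975, n - 1)
  list(mean_diff = md,
       loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
       ci95_mean_diff = c(md - tcrit * se, md + tcrit * se),
       sd_diff = sdd, n = n)
}

#' Full agreement report for two measurement methods
#'
#' Combines \code{\link{iccAgreement}} and \code{\link{blandAltman}}.
#'
#' @inheritParams iccAgreement
#' @return an \code{\link{AgreementReport-class}} object.
#' @export
agreementReport <- function(a, b) {
  icc <- iccAgreement(a, b)
  ba <- blandAltman(a, b)
  new("AgreementReport", n = length(a), icc = icc$icc, iccBand = icc$band,
      meanDiff = ba$mean_diff, loaLow = ba$loa_low, loaHigh = ba$loa_high,
      ci95MeanDiff = ba$ci95_mean_diff)
}

#' Bland-Altman plot
#'
#' Differences against pairwise means, with the mean difference and the 95\%
#' limits of agreement drawn as horizontal lines.
#'
#' @inheritParams iccAgreement
#' @param file optional PNG path.
#' @param main plot title.
#' @return the \code{\link{blandAltman}} result, invisibly.
#' @export
plotBlandAltman <- function(a, b, file = NULL, main = "Bland-Altman") {
  ba <- blandAltman(a, b)
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::plot((a + b) / 2, a - b, pch = 16,
                 xlab = "mean of methods", ylab = "difference (a - b)",
                 main = main)
  graphics::abline(h = ba$mean_diff, lty = 1)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(ba)
}

#' Paired comparison of two methods by both conventional tests
#'
#' Returns the Wilcoxon rank-sum test and the paired t-test for the same
#' pair of measurement vectors; which of the two is appropriate depends on
#' the distribution of the differences, so both are reported.
#'
#' @inheritParams iccAgreement
#' @return list with \code{wilcoxon} and \code{paired_t} (both htest objects)
#'   and their p-values.
#' @export
pairedCompare <- function(a, b) {
  .stopIf(length(a) != length(b), "a and b must have equal length")
  w <- stats::wilcox.test(a, b, exact = FALSE)
  t <- stats::t.test(a, b, paired = TRUE)
  list(wilcoxon = w, paired_t = t,
       p_wilcoxon = w$p.value, p_paired_t = t$p.value)
}
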