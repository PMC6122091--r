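two_band_spectrum <- function(sigma = 0.3) {
  st <- StickSpectrum(1239.841984 / c(275, 210), c(-15, -25))
  convolveSticks(st, BroadeningConfig(sigma = sigma))
}

test_that("planted negative bands at 210 and 275 nm are both recovered", {
  sp <- two_band_spectrum()
  peaks <- findPeaks(sp)
  neg <- peaks[peaks$sign == "negative", ]
  expect_equal(nrow(neg), 2)
  expect_lte(abs(neg$position_nm[1] - 210), 1)
  expect_lte(abs(neg$position_nm[2] - 275), 1)
  expect_true(all(neg$amplitude < 0))
})

test_that("a constant spectrum has no peaks and short spectra error", {
  sp <- CDSpectrum(seq(200, 300, 5), rep(-2, 21))
  expect_equal(nrow(findPeaks(sp)), 0)
  expect_error(findPeaks(CDSpectrum(c(200, 210), c(-1, -2))), "short")
})

test_that("a single negative Gaussian band yields one peak at its minimum", {
  grid <- seq(200, 300, 0.5)
  vals <- -12 * exp(-((grid - 250) / 15)^2)
  peaks <- findPeaks(CDSpectrum(grid, vals))
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$position_nm, 250)
  expect_equal(peaks$amplitude, min(vals))
  expect_equal(peaks$sign, "negative")
})

test_that("peak detection commutes with negation (positions kept, signs flipped)", {
  sp <- two_band_spectrum()
  p1 <- findPeaks(sp)
  p2 <- findPeaks(CDSpectrum(wavelengths(sp), -deltaEpsilon(sp)))
  expect_equal(p1$position_nm, p2$position_nm)
  expect_equal(p1$prominence, p2$prominence)
  expect_true(all(p1$sign != p2$sign))
})

test_that("low-prominence grid noise is suppressed", {
  grid <- seq(200, 300, 1)
  vals <- -10 * exp(-((grid - 250) / 20)^2) + 0.2 * sin(grid * 3)
  peaks <- findPeaks(CDSpectrum(grid, vals), minProminence = 1)
  expect_equal(nrow(peaks[peaks$sign == "negative", ]), 1)
})

test_that("the canonical comparison gives shifts {-20, -10} and a passing 20 nm verdict", {
  rep_ <- matchPeaks(c(-200, -270), c(-220, -280))
  expect_equal(sort(rep_@pairs$shift_nm), c(-20, -10))
  expect_equal(rep_@maxAbsShift, 20)
  expect_true(rep_@verdict)
})

test_that("over-blue-shifted peaks fail the 20 nm verdict", {
  rep_ <- matchPeaks(c(-190, -260), c(-220, -280))
  expect_equal(sort(rep_@pairs$shift_nm), c(-30, -20))
  expect_false(rep_@verdict)
})

test_that("identical peak sets match with all-zero shifts", {
  rep_ <- matchPeaks(c(-205, -277), c(-205, -277))
  expect_equal(rep_@pairs$shift_nm, c(0, 0))
  expect_equal(rep_@maxAbsShift, 0)
  expect_true(rep_@verdict)
})

test_that("matching is symmetric up to the sign of the shifts", {
  a <- c(-198, -262); b <- c(-221, -283)
  r1 <- matchPeaks(a, b)
  r2 <- matchPeaks(b, a)
  expect_equal(sort(r1@pairs$shift_nm), sort(-r2@pairs$shift_nm))
  expect_equal(r1@maxAbsShift, r2@maxAbsShift)
})

test_that("unbalanced peak sets leave the surplus unmatched", {
  rep_ <- matchPeaks(c(-200, -240, -270), c(-220, -280))
  expect_equal(nrow(rep_@pairs), 2)
  expect_equal(nrow(rep_@unmatchedCalc), 1)
})

test_that("empty post-filter collections name the offending side", {
  expect_error(matchPeaks(c(200), c(-220, -280)), "calculated")
  expect_error(matchPeaks(c(-200), c(220)), "experimental")
})

test_that("the positive-feature diagnostic is 0 on all-negative spectra", {
  sp <- two_band_spectrum()
  expect_identical(positiveFeature(sp), 0)
})

test_that("a planted +50 shoulder at 230 nm is measured at ~50", {
  # R chosen so the isolated 230 nm band peaks at +50; the neighbouring
  # negative bands shave a little off under the 0.3 eV convolution
  e230 <- 1239.841984 / 230
  r50 <- 50 / (4 * as.numeric(cdPrefactor()) * 1e-40 * e230 *
                 gaussianLineshape(e230, e230, 0.3))
  st <- StickSpectrum(1239.841984 / c(275, 230, 210), c(-15, r50, -25))
  sp <- convolveSticks(st, BroadeningConfig(sigma = 0.3))
  expect_equal(positiveFeature(sp, c(220, 240)), 50, tolerance = 0.1)
  expect_equal(positiveFeature(sp, c(220, 240)),
               max(deltaEpsilon(sp)[wavelengths(sp) >= 220 &
                                      wavelengths(sp) <= 240]))
})

test_that("positive-feature bounds propagate and disjoint windows error", {
  grid <- seq(200, 300, 1)
  vals <- pmin(5, 10 - abs(grid - 250) / 2) - 6  # <= +4 everywhere
  sp <- CDSpectrum(grid, vals)
  expect_lte(positiveFeature(sp, c(240, 260)), 5)
  expect_error(positiveFeature(sp, c(400, 420)), "range|disjoint")
})

test_that("positive feature is monotone under adding a positive constant", {
  sp <- two_band_spectrum()
  up <- CDSpectrum(wavelengths(sp), deltaEpsilon(sp) + 3)
  expect_gte(positiveFeature(up), positiveFeature(sp))
})

test_that("comparison reports serialize to key-value text and CSV", {
  rep_ <- matchPeaks(c(-200, -270), c(-220, -280))
  rep_ <- addPositiveFeature(rep_, two_band_spectrum())
  txt <- withr::local_tempfile(fileext = ".txt")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeComparisonReport(rep_, txt)
  writeMatchedPairsCsv(rep_, csv)
  kv <- readLines(txt)
  expect_true(any(grepl("max_abs_shift_nm: 20", kv)))
  expect_true(any(grepl("all_peaks_within_tolerance: TRUE", kv)))
  expect_true(any(grepl("positive_feature_max: 0", kv)))
  back <- utils::read.csv(csv)
  expect_equal(sort(back$shift_nm), c(-20, -10))
})
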