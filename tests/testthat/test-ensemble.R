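flat_spectrum <- function(value, grid = seq(200, 300, by = 5), label = NA)
  CDSpectrum(grid, rep(value, length(grid)), label = label)

test_that("resampling onto the source grid is the identity", {
  sp <- CDSpectrum(c(200, 210, 220), c(-1, -3, -2))
  expect_equal(deltaEpsilon(resampleSpectrum(sp, c(200, 210, 220))),
               c(-1, -3, -2))
})

test_that("resampling at a midpoint returns the arithmetic mean of neighbours", {
  sp <- CDSpectrum(c(200, 210), c(-4, -6))
  expect_equal(deltaEpsilon(resampleSpectrum(sp, 205)), -5)
})

test_that("resampling outside the source span is a range error", {
  sp <- CDSpectrum(c(200, 210), c(-4, -6))
  expect_error(resampleSpectrum(sp, c(195, 205)), "range")
  expect_error(resampleSpectrum(sp, 215), "range")
})

test_that("identical members give a zero-width band equal to each member", {
  sp <- flat_spectrum(-7)
  ens <- averageSpectra(rep(list(sp), 10))
  expect_equal(ensembleMean(ens), deltaEpsilon(sp))
  expect_equal(ciLower(ens), ensembleMean(ens))
  expect_equal(ciUpper(ens), ensembleMean(ens))
  expect_equal(nMembers(ens), 10)
})

test_that("two-member t band matches the closed-form df=1 quantile", {
  ens <- averageSpectra(list(flat_spectrum(1), flat_spectrum(-1)))
  # s = sqrt(2) for {+1, -1}; half-width = qt(0.975, 1) * s / sqrt(2)
  half <- t_quantile_df1(0.975) * sqrt(2) / sqrt(2)
  expect_equal(ensembleMean(ens), rep(0, 21))
  expect_equal(ciUpper(ens) - ensembleMean(ens), rep(half, 21),
               tolerance = 1e-12)
  expect_equal(ensembleMean(ens) - ciLower(ens), rep(half, 21),
               tolerance = 1e-12)
})

test_that("averaging is permutation-invariant over members", {
  set.seed(5)
  members <- lapply(1:6, function(i)
    CDSpectrum(seq(200, 300, 5), rnorm(21, -5, 2)))
  e1 <- averageSpectra(members)
  e2 <- averageSpectra(rev(members))
  expect_equal(ensembleMean(e1), ensembleMean(e2))
  expect_equal(ciLower(e1), ciLower(e2))
  expect_equal(ciUpper(e1), ciUpper(e2))
})

test_that("adding a member equal to the current mean never widens the band", {
  set.seed(11)
  members <- lapply(1:5, function(i)
    CDSpectrum(seq(200, 300, 5), rnorm(21, -5, 2)))
  e1 <- averageSpectra(members)
  e2 <- averageSpectra(c(members,
                         list(CDSpectrum(wavelengths(e1), ensembleMean(e1)))))
  w1 <- ciUpper(e1) - ciLower(e1)
  w2 <- ciUpper(e2) - ciLower(e2)
  expect_true(all(w2 <= w1 + 1e-12))
})

test_that("mirrored spurious features cancel in the ensemble mean", {
  grid <- seq(200, 300, 1)
  base <- -10 * exp(-((grid - 250) / 20)^2)
  spur <- 6 * exp(-((grid - 280) / 5)^2)
  members <- list(CDSpectrum(grid, base + spur),
                  CDSpectrum(grid, base - spur))
  ens <- averageSpectra(members)
  expect_equal(ensembleMean(ens), base, tolerance = 1e-12)
})

test_that("members on different grids are averaged on the span intersection", {
  a <- CDSpectrum(seq(200, 300, 2), rep(-4, 51))
  b <- CDSpectrum(seq(210, 320, 5), rep(-8, 23))
  ens <- averageSpectra(list(a, b))
  expect_gte(min(wavelengths(ens)), 210)
  expect_lte(max(wavelengths(ens)), 300)
  expect_equal(unique(ensembleMean(ens)), -6)
})

test_that("a single member degenerates to the mean with a warning", {
  expect_warning(ens <- averageSpectra(list(flat_spectrum(-3))),
                 "single-member")
  expect_equal(ciLower(ens), ensembleMean(ens))
})

test_that("an empty member list is an error", {
  expect_error(averageSpectra(list()), "empty")
})

test_that("the bootstrap band is seeded, brackets the mean, and is reproducible", {
  set.seed(23)
  members <- lapply(1:10, function(i)
    CDSpectrum(seq(200, 300, 10), rnorm(11, -5, 2)))
  e1 <- averageSpectra(members, method = "bootstrap", seed = 7)
  e2 <- averageSpectra(members, method = "bootstrap", seed = 7)
  expect_equal(ciLower(e1), ciLower(e2))
  expect_true(all(ciLower(e1) <= ensembleMean(e1) + 1e-12))
  expect_true(all(ciUpper(e1) >= ensembleMean(e1) - 1e-12))
  # both recipes agree on the mean
  et <- averageSpectra(members, method = "t")
  expect_equal(ensembleMean(e1), ensembleMean(et))
})

test_that("ensemble CSVs round-trip mean, band and members", {
  set.seed(31)
  members <- lapply(1:4, function(i)
    CDSpectrum(seq(200, 300, 5), rnorm(21, -5, 2), label = paste0("m", i)))
  ens <- averageSpectra(members)
  path <- withr::local_tempfile(fileext = ".csv")
  writeEnsembleCsv(ens, path)
  back <- readEnsembleCsv(path)
  expect_equal(ensembleMean(back), ensembleMean(ens), tolerance = 1e-12)
  expect_equal(ciLower(back), ciLower(ens), tolerance = 1e-12)
  expect_equal(nMembers(back), 4)
  expect_equal(deltaEpsilon(members(back)[[2]]),
               deltaEpsilon(members[[2]]), tolerance = 1e-12)
})
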