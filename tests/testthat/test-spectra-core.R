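test_that("lineshape peaks at 1/(sqrt(2*pi)*sigma), is symmetric, rejects bad sigma", {
  peak <- gaussianLineshape(4.5, 4.5, 0.3)
  expect_equal(peak, 1 / (sqrt(2 * pi) * 0.3), tolerance = 1e-12)
  expect_equal(gaussianLineshape(4.5 + 0.3, 4.5, 0.3), peak * exp(-1 / 2),
               tolerance = 1e-12)
  expect_equal(gaussianLineshape(4.5 - 0.3, 4.5, 0.3),
               gaussianLineshape(4.5 + 0.3, 4.5, 0.3))
  expect_error(gaussianLineshape(4.5, 4.5, 0), "sigma")
  expect_error(gaussianLineshape(4.5, 4.5, -0.1), "sigma")
})

test_that("lineshape integrates to unity over +/- 8 sigma", {
  for (sigma in c(0.1, 0.2, 0.3)) {
    E <- seq(5 - 8 * sigma, 5 + 8 * sigma, by = 1e-3)
    expect_equal(trapezoid(E, gaussianLineshape(E, 5, sigma)), 1,
                 tolerance = 1e-6)
  }
})

test_that("prefactor is computed from constants and matches the standard cgs conversion", {
  a <- cdPrefactor()
  expect_gt(as.numeric(a), 0)
  # the familiar conversion: Delta-eps = En * Rn[cgs] * sigma_n(E) / 2.296e-39
  expect_equal(1 / (4 * as.numeric(a)), 2.296e-39, tolerance = 0.02)
  expect_match(attr(a, "derivation"), "8\\*pi\\^3")
  # functional dependence: a is proportional to 1/h
  consts <- physicalConstants()
  consts$planck <- 2 * consts$planck
  expect_equal(as.numeric(cdPrefactor(consts)), as.numeric(a) / 2,
               tolerance = 1e-14)
})

test_that("single-state convolution reproduces the 2.296e-39 literature magnitude", {
  stick <- StickSpectrum(5.0, 1)  # R = 1 (x 1e-40 cgs)
  cfg <- BroadeningConfig(sigma = 0.3, gridMin = 240, gridMax = 255,
                          gridStep = 0.1)
  sp <- convolveSticks(stick, cfg)
  E <- 1239.841984 / wavelengths(sp)
  ref <- 5.0 * 1e-40 * gaussianLineshape(E, 5.0, 0.3) / 2.296e-39
  expect_equal(deltaEpsilon(sp), ref, tolerance = 0.02)
})

test_that("empty stick spectrum convolves to the zero spectrum", {
  sp <- convolveSticks(StickSpectrum())
  expect_true(all(deltaEpsilon(sp) == 0))
  expect_equal(length(wavelengths(sp)), length(seq(170, 400, by = 0.5)))
})

test_that("convolution is linear in the rotatory strengths", {
  st <- three_state_stick()
  k <- -3.5
  scaled <- StickSpectrum(energies(st), k * rotatoryStrengths(st))
  v1 <- deltaEpsilon(convolveSticks(st))
  v2 <- deltaEpsilon(convolveSticks(scaled))
  expect_equal(v2, k * v1, tolerance = 1e-14)
})

test_that("negating all rotatory strengths negates the spectrum pointwise", {
  st <- three_state_stick()
  neg <- StickSpectrum(energies(st), -rotatoryStrengths(st))
  expect_equal(deltaEpsilon(convolveSticks(neg)),
               -deltaEpsilon(convolveSticks(st)), tolerance = 0)
})

test_that("three-state convolution equals the brute-force oracle to 1e-10 relative", {
  st <- three_state_stick()
  cfg <- BroadeningConfig(sigma = 0.3)
  sp <- convolveSticks(st, cfg)
  ref <- oracle_convolve(energies(st), rotatoryStrengths(st), 0.3,
                         wavelengths(sp))
  expect_equal(deltaEpsilon(sp), ref, tolerance = 1e-10)
})

test_that("vectorized convolution equals the naive loop on random sticks (both weightings)", {
  set.seed(421)
  for (case in 1:100) {
    st <- random_stick(sample(1:6, 1))
    sigma <- stats::runif(1, 0.1, 0.4)
    weighting <- sample(c("per_state_energy", "incident_energy"), 1)
    cfg <- BroadeningConfig(sigma = sigma, gridMin = 200, gridMax = 320,
                            gridStep = 2, energyWeighting = weighting)
    sp <- convolveSticks(st, cfg)
    ref <- oracle_convolve(energies(st), rotatoryStrengths(st), sigma,
                           wavelengths(sp), weighting)
    expect_equal(deltaEpsilon(sp), ref, tolerance = 1e-10)
  }
})

test_that("convolution is additive over unions of states", {
  set.seed(99)
  a <- random_stick(3); b <- random_stick(4)
  ab <- StickSpectrum(c(energies(a), energies(b)),
                      c(rotatoryStrengths(a), rotatoryStrengths(b)))
  cfg <- BroadeningConfig(sigma = 0.25, gridMin = 190, gridMax = 330,
                          gridStep = 1)
  vsum <- deltaEpsilon(convolveSticks(a, cfg)) +
    deltaEpsilon(convolveSticks(b, cfg))
  expect_equal(deltaEpsilon(convolveSticks(ab, cfg)), vsum,
               tolerance = 1e-12)
})

test_that("the spectrum decays to negligible values far from every state", {
  sigma <- 0.1
  st <- StickSpectrum(6.2, -20)  # ~200 nm
  cfg <- BroadeningConfig(sigma = sigma, gridMin = 180, gridMax = 400,
                          gridStep = 0.5)
  sp <- convolveSticks(st, cfg)
  E <- 1239.841984 / wavelengths(sp)
  far <- abs(E - 6.2) >= 8 * sigma
  expect_true(any(far))
  expect_lt(max(abs(deltaEpsilon(sp)[far])),
            1e-6 * max(abs(deltaEpsilon(sp))))
})

test_that("invalid states are rejected with indexed errors", {
  expect_error(StickSpectrum(c(4.5, -1), c(1, 2)), "state\\(s\\) 2")
  expect_error(StickSpectrum(c(4.5, 5.0), c(1, NaN)), "state\\(s\\) 2")
})

test_that("stick spectra normalize to ascending energy with unique indices", {
  st <- StickSpectrum(c(6.0, 4.5, 5.2), c(-10, 8, -15))
  expect_equal(energies(st), c(4.5, 5.2, 6.0))
  expect_equal(rotatoryStrengths(st), c(8, -15, -10))
  expect_equal(states(st)$index, c(2L, 3L, 1L))
  expect_equal(wavelengths(st), 1239.841984 / c(4.5, 5.2, 6.0))
})
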