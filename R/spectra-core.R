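#' @include methods.R
NULL

#' CODATA-2018 physical constants for the CD conversion
#'
#' Returns the constants entering the rotatory-strength-to-Delta-epsilon
#' prefactor.  The prefactor itself is always computed from these values by
#' [cdPrefactor()], never hard-coded, so the unit reconciliation lives in a
#' single audited place.
#'
#' @return a list with `avogadro` (mol^-1), `planck` (J s), `lightspeed`
#'   (cm s^-1) and `hc_eV_nm` (eV nm).
#' @export
physicalConstants <- function() {
  list(avogadro = 6.02214076e23,   # mol^-1 (exact, SI 2019)
       planck = 6.62607015e-34,    # J s (exact)
       lightspeed = 2.99792458e10, # cm s^-1
       hc_eV_nm = HC_EV_NM)
}

#' Prefactor a of the rotatory-strength-to-CD conversion
#'
#' Computes the constant a in Delta-epsilon = 4a * sum_n Rn * En * sigma_n(E)
#' from first principles:
#'
#'   a = 8 pi^3 N_A / (3 ln(10) 10^3 h c)
#'
#' with h in erg s (cgs) and c in cm s^-1, so that with Rn in units of
#' 1e-40 cgs (erg esu cm / Gauss), En in eV and sigma_n(E) a Gaussian
#' normalized on the same energy axis, Delta-epsilon comes out in
#' M^-1 cm^-1.  Equivalently 4a*1e-40 = 1e-40 / 2.2965e-39, the familiar
#' conversion constant of chiroptical post-processing (the energy-axis unit
#' cancels in the product En * sigma_n(E)).
#'
#' The derivation string and the constant values used are attached as
#' attributes so the unit choice is auditable.
#'
#' @param constants a list as returned by [physicalConstants()]; injectable
#'   for testing.
#' @return the numeric prefactor a (for Rn expressed in cgs units, i.e. the
#'   caller multiplies Rn by 1e-40), with attributes `derivation` and
#'   `constants`.
#' @export
cdPrefactor <- function(constants = physicalConstants()) {
  h_erg_s <- constants$planck * 1e7  # J s -> erg s
  a <- 8 * pi^3 * constants$avogadro /
    (3 * log(10) * 1e3 * h_erg_s * constants$lightspeed)
  attr(a, "derivation") <-
    "a = 8*pi^3*N_A / (3*ln(10)*10^3*h*c); h in erg s, c in cm s^-1; Delta-eps(E) [M^-1 cm^-1] = 4a * sum_n Rn[cgs] * En * sigma_n(E), energy axis unit cancels in En*sigma_n(E)"
  attr(a, "constants") <- constants
  a
}

#' Normalized Gaussian lineshape in energy
#'
#' sigma_n(E) = exp(-(E - En)^2 / (2 sigma^2)) / (sqrt(2 pi) sigma),
#' a unit-area Gaussian in energy; sigma is the exponential half-width.
#'
#' @param E incident photon energy (eV); vectorized.
#' @param En excitation energy of the state (eV).
#' @param sigma exponential half-width (eV), > 0.
#' @return spectral density in eV^-1.
#' @examples
#' gaussianLineshape(4.5, 4.5, 0.3)  # peak value 1/(sqrt(2*pi)*0.3)
#' @export
gaussianLineshape <- function(E, En, sigma) {
  if (length(sigma) != 1 || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a single positive number (eV)")
  exp(-(E - En)^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
}

#' Convolve a stick spectrum into a broadened CD spectrum
#'
#' Evaluates Delta-epsilon(E) = 4a * sum_n Rn * w_n * sigma_n(E) on an
#' energy grid corresponding to the requested wavelength window, where
#' sigma_n is the normalized Gaussian of [gaussianLineshape()] and the
#' energy weight w_n is the state's own excitation energy En (default) or
#' the incident energy E, per the configuration.  All arithmetic is done in
#' energy space (the half-width sigma is specified in eV); the output grid
#' is reported in nm.
#'
#' Linearity holds exactly: scaling every Rn by k scales the output by k,
#' and the convolution of a union of states is the sum of the convolutions.
#' An empty stick spectrum yields the zero spectrum.
#'
#' @param stick a [StickSpectrum-class].
#' @param config a [BroadeningConfig-class]; default sigma 0.3 eV on a
#'   170-400 nm grid at 0.5 nm.
#' @param constants constants list for the prefactor (see [cdPrefactor()]).
#' @return a [CDSpectrum-class] on the nm grid, Delta-epsilon in M^-1 cm^-1.
#' @examples
#' stick <- StickSpectrum(c(4.5, 5.2, 6.0), c(8, -15, -10))
#' sp <- convolveSticks(stick, BroadeningConfig(sigma = 0.3))
#' range(deltaEpsilon(sp))
#' @export
convolveSticks <- function(stick, config = BroadeningConfig(),
                           constants = physicalConstants()) {
  stopifnot(is(stick, "StickSpectrum"), is(config, "BroadeningConfig"))
  validObject(stick)
  validObject(config)
  grid_nm <- seq(config@gridMin, config@gridMax, by = config@gridStep)
  E <- HC_EV_NM / grid_nm  # decreasing in lambda; evaluated pointwise
  st <- stick@states
  if (nrow(st) == 0L) {
    vals <- numeric(length(grid_nm))
  } else {
    if (any(st$energy_eV <= 0)) {
      bad <- st$index[st$energy_eV <= 0]
      stop("non-positive excitation energy at state(s) ",
           paste(bad, collapse = ", "))
    }
    if (any(!is.finite(st$rotatory_strength))) {
      bad <- st$index[!is.finite(st$rotatory_strength)]
      stop("non-finite rotatory strength at state(s) ",
           paste(bad, collapse = ", "))
    }
    a <- cdPrefactor(constants)
    ## lineshape matrix: rows = grid points, cols = states
    G <- outer(E, st$energy_eV,
               function(e, en) gaussianLineshape(e, en, config@sigma))
    w <- switch(config@energyWeighting,
                per_state_energy = sweep(G, 2, st$energy_eV, `*`),
                incident_energy = G * E)
    vals <- as.numeric(4 * a * 1e-40 *
                         (w %*% st$rotatory_strength))
  }
  CDSpectrum(grid = grid_nm, values = vals, axis = "wavelength_nm",
             label = stick@label,
             metadata = c(stick@metadata,
                          list(sigma_eV = config@sigma,
                               energy_weighting = config@energyWeighting)))
}
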