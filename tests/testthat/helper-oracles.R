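# Independent oracles, written as naive loops before the vectorized paths
# they check and kept deliberately free of package internals.

# Brute-force per-point stick-to-spectrum conversion: for each grid
# wavelength, sum 4a * Rn * En * gaussian over states, with the prefactor
# derived inline from CODATA constants in cgs.
oracle_convolve <- function(energies, rstrengths, sigma, grid_nm,
                            weighting = "per_state_energy") {
  avogadro <- 6.02214076e23
  h_erg_s <- 6.62607015e-27
  c_cm_s <- 2.99792458e10
  a <- 8 * pi^3 * avogadro / (3 * log(10) * 1e3 * h_erg_s * c_cm_s)
  out <- numeric(length(grid_nm))
  for (i in seq_along(grid_nm)) {
    E <- 1239.841984 / grid_nm[i]
    acc <- 0
    for (n in seq_along(energies)) {
      g <- exp(-(E - energies[n])^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
      w <- if (weighting == "per_state_energy") energies[n] else E
      acc <- acc + rstrengths[n] * 1e-40 * w * g
    }
    out[i] <- 4 * a * acc
  }
  out
}

# Trapezoid quadrature for lineshape normalization checks.
trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Closed-form Student-t quantile for 1 degree of freedom (Cauchy):
# qt(p, 1) = tan(pi * (p - 1/2)).
t_quantile_df1 <- function(p) tan(pi * (p - 0.5))

random_stick <- function(n_states, emin = 3.8, emax = 6.5, rmax = 30) {
  StickSpectrum(stats::runif(n_states, emin, emax),
                stats::runif(n_states, -rmax, rmax))
}
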