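#' @include spectra-core.R
NULL

#' Construct a synthetic-ensemble recipe
#'
#' The default recipe emulates a ten-snapshot ensemble of a silver-mediated
#' guanine duplex: two dominant negative electronic bands centered near
#' 5.90 eV (~210 nm) and 4.51 eV (~275 nm), three states per band, with
#' modest thermal jitter of state energies (s.d. 0.05 eV) and rotatory
#' strengths (fractional s.d. 0.10) from snapshot to snapshot.  Band mean
#' rotatory strengths (-25 and -15 in 1e-40 cgs) put the broadened
#' Delta-epsilon in the tens of M^-1 cm^-1, the magnitude of measured
#' guanine-duplex ECD.
#'
#' @param nSnapshots snapshots in the ensemble (default 10).
#' @param bands data.frame with `center_eV`, `mean_R`, `n_states` per band.
#' @param energyJitterEv Gaussian s.d. of per-state energies (eV).
#' @param rJitterFrac fractional Gaussian s.d. of rotatory strengths.
#' @param seed integer root seed.
#' @return an [EnsembleRecipe-class].
#' @export
ensembleRecipe <- function(nSnapshots = 10,
                           bands = data.frame(center_eV = c(5.90, 4.51),
                                              mean_R = c(-25, -15),
                                              n_states = c(3L, 3L)),
                           energyJitterEv = 0.05, rJitterFrac = 0.10,
                           seed = 1) {
  new("EnsembleRecipe", nSnapshots = nSnapshots, bands = bands,
      energyJitterEv = energyJitterEv, rJitterFrac = rJitterFrac,
      seed = seed)
}

#' Generate a synthetic stick-spectrum ensemble
#'
#' For each snapshot, every band contributes `n_states` states with
#' energies drawn from Normal(center_eV, energyJitterEv) and rotatory
#' strengths from Normal(mean_R, |mean_R| * rJitterFrac).  One root seed
#' drives everything: per-snapshot substream seeds are drawn up front from
#' the root stream, so ensembles are bit-identical across calls with the
#' same recipe.  Zero jitter yields identical snapshots.
#'
#' @param recipe an [EnsembleRecipe-class].
#' @return list of `nSnapshots` [StickSpectrum-class] objects labelled
#'   `snapshot_01`, `snapshot_02`, ...
#' @examples
#' sticks <- generateEnsemble(ensembleRecipe(seed = 42))
#' length(sticks)
#' @export
generateEnsemble <- function(recipe = ensembleRecipe()) {
  stopifnot(is(recipe, "EnsembleRecipe"))
  validObject(recipe)
  n <- as.integer(recipe@nSnapshots)
  set.seed(as.integer(recipe@seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    set.seed(sub_seeds[i])
    e <- c(); r <- c()
    for (b in seq_len(nrow(recipe@bands))) {
      nb <- recipe@bands$n_states[b]
      eb <- stats::rnorm(nb, recipe@bands$center_eV[b],
                         recipe@energyJitterEv)
      rb <- stats::rnorm(nb, recipe@bands$mean_R[b],
                         abs(recipe@bands$mean_R[b]) * recipe@rJitterFrac)
      e <- c(e, eb); r <- c(r, rb)
    }
    StickSpectrum(e, r, label = sprintf("snapshot_%02d", i),
                  metadata = list(seed = sub_seeds[i], recipe_seed = recipe@seed))
  })
}

#' Generate a pseudo-experimental spectrum
#'
#' Convolves a reference stick spectrum on a 1 nm grid and adds seeded
#' Gaussian noise, producing a stand-in for a measured spectrum with known
#' ground truth.  Zero noise returns exactly the convolved reference.
#'
#' @param stick reference [StickSpectrum-class].
#' @param sigma broadening half-width in eV.
#' @param noiseSd Gaussian noise s.d. in M^-1 cm^-1.
#' @param seed integer seed.
#' @param gridMin,gridMax wavelength window in nm.
#' @return a [CDSpectrum-class] tagged `kind = "pseudo_experimental"`.
#' @export
generatePseudoExperiment <- function(stick, sigma = 0.3, noiseSd = 0,
                                     seed = 1, gridMin = 170, gridMax = 400) {
  sp <- convolveSticks(stick, BroadeningConfig(sigma = sigma,
                                               gridMin = gridMin,
                                               gridMax = gridMax,
                                               gridStep = 1))
  set.seed(as.integer(seed))
  vals <- sp@values + stats::rnorm(length(sp@values), 0, noiseSd)
  CDSpectrum(sp@grid, vals, axis = "wavelength_nm",
             label = "pseudo-experiment",
             metadata = list(kind = "pseudo_experimental", sigma_eV = sigma,
                             noise_sd = noiseSd, seed = seed))
}
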