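#' @include AllGenerics.R
NULL

#' Construct a stick spectrum from excited-state data
#'
#' Normalizes the states: sorts by ascending excitation energy (indices
#' travel with their states) and validates positivity, finiteness and index
#' uniqueness.  States with tiny rotatory strengths are kept; filtering is a
#' caller decision.
#'
#' @param energies excitation energies in eV (> 0).
#' @param rotatoryStrengths length-gauge rotatory strengths in 1e-40 cgs.
#' @param oscillatorStrengths optional dimensionless oscillator strengths.
#' @param indices optional 1-based state indices (default `seq_along`).
#' @param label snapshot/source identifier.
#' @param metadata free-form provenance list.
#' @return a [StickSpectrum-class].
#' @examples
#' StickSpectrum(c(4.5, 5.2, 6.0), c(8, -15, -10), label = "snapshot-1")
#' @export
StickSpectrum <- function(energies = numeric(), rotatoryStrengths = numeric(),
                          oscillatorStrengths = NULL, indices = NULL,
                          label = NA_character_, metadata = list()) {
  n <- length(energies)
  if (length(rotatoryStrengths) != n)
    stop("energies and rotatoryStrengths must have equal length")
  if (n > 0 && any(!is.finite(energies) | energies <= 0)) {
    bad <- which(!is.finite(energies) | energies <= 0)
    stop("non-positive or non-finite excitation energy at state(s) ",
         paste(bad, collapse = ", "))
  }
  if (n > 0 && any(!is.finite(rotatoryStrengths))) {
    bad <- which(!is.finite(rotatoryStrengths))
    stop("non-finite rotatory strength at state(s) ",
         paste(bad, collapse = ", "))
  }
  if (is.null(indices)) indices <- seq_len(n)
  if (is.null(oscillatorStrengths)) oscillatorStrengths <- rep(NA_real_, n)
  o <- order(energies)
  st <- data.frame(index = as.integer(indices)[o],
                   energy_eV = as.numeric(energies)[o],
                   rotatory_strength = as.numeric(rotatoryStrengths)[o],
                   oscillator_strength = as.numeric(oscillatorStrengths)[o])
  rownames(st) <- NULL
  new("StickSpectrum", states = st, label = as.character(label)[1],
      metadata = metadata)
}

#' Construct a CD spectrum
#'
#' @param grid strictly increasing axis values.
#' @param values Delta-epsilon in M^-1 cm^-1.
#' @param axis `"wavelength_nm"` (default) or `"energy_eV"`.
#' @param label,metadata identification and provenance.
#' @return a [CDSpectrum-class].
#' @export
CDSpectrum <- function(grid, values, axis = "wavelength_nm",
                       label = NA_character_, metadata = list()) {
  new("CDSpectrum", grid = as.numeric(grid), values = as.numeric(values),
      axis = axis, label = as.character(label)[1], metadata = metadata)
}

#' Construct a broadening configuration
#'
#' @param sigma Gaussian exponential half-width in eV.  0.3 eV is typical
#'   for metal-mediated tetramers; 0.2 eV for plain B-DNA/guanine tetramers.
#' @param gridMin,gridMax,gridStep output wavelength window and step in nm.
#' @param energyWeighting `"per_state_energy"` or `"incident_energy"`.
#' @return a [BroadeningConfig-class].
#' @export
BroadeningConfig <- function(sigma = 0.3, gridMin = 170, gridMax = 400,
                             gridStep = 0.5,
                             energyWeighting = "per_state_energy") {
  new("BroadeningConfig", sigma = sigma, gridMin = gridMin, gridMax = gridMax,
      gridStep = gridStep, energyWeighting = energyWeighting)
}

#' Construct range-separation parameters
#'
#' @param alpha,beta,mu see [RangeSepParams-class].
#' @return a [RangeSepParams-class].
#' @export
RangeSepParams <- function(alpha, beta, mu) {
  new("RangeSepParams", alpha = as.numeric(alpha), beta = as.numeric(beta),
      mu = as.numeric(mu))
}

#' Construct a molecular structure from an atom table
#'
#' @param atoms data.frame with columns element, name, resname, resid,
#'   chain, x, y, z (Angstrom).
#' @param metadata provenance list.
#' @return a [MolecularStructure-class].
#' @export
MolecularStructure <- function(atoms, metadata = list()) {
  atoms$element <- as.character(atoms$element)
  atoms$name <- as.character(atoms$name)
  atoms$resname <- as.character(atoms$resname)
  atoms$resid <- as.integer(atoms$resid)
  atoms$chain <- as.character(atoms$chain)
  rownames(atoms) <- NULL
  new("MolecularStructure", atoms = atoms, metadata = metadata)
}

## ---- accessor methods -------------------------------------------------

#' @rdname accessors
setMethod("states", "StickSpectrum", function(x) x@states)
#' @rdname accessors
setMethod("nStates", "StickSpectrum", function(x) nrow(x@states))
#' @rdname accessors
setMethod("energies", "StickSpectrum", function(x) x@states$energy_eV)
#' @rdname accessors
setMethod("rotatoryStrengths", "StickSpectrum",
          function(x) x@states$rotatory_strength)
#' @rdname accessors
setMethod("wavelengths", "StickSpectrum",
          function(x) HC_EV_NM / x@states$energy_eV)
#' @rdname accessors
setMethod("specLabel", "StickSpectrum", function(x) x@label)
#' @rdname accessors
setMethod("specMetadata", "StickSpectrum", function(x) x@metadata)

#' @rdname accessors
setMethod("wavelengths", "CDSpectrum", function(x) {
  if (x@axis == "wavelength_nm") x@grid else HC_EV_NM / x@grid
})
#' @rdname accessors
setMethod("deltaEpsilon", "CDSpectrum", function(x) x@values)
#' @rdname accessors
setMethod("axisUnit", "CDSpectrum", function(x) x@axis)
#' @rdname accessors
setMethod("specLabel", "CDSpectrum", function(x) x@label)
#' @rdname accessors
setMethod("specMetadata", "CDSpectrum", function(x) x@metadata)

#' @rdname accessors
setMethod("wavelengths", "EnsembleSpectrum", function(x) x@grid)
#' @rdname accessors
setMethod("ensembleMean", "EnsembleSpectrum", function(x) x@mean)
#' @rdname accessors
setMethod("ciLower", "EnsembleSpectrum", function(x) x@ciLower)
#' @rdname accessors
setMethod("ciUpper", "EnsembleSpectrum", function(x) x@ciUpper)
#' @rdname accessors
setMethod("members", "EnsembleSpectrum", function(x) x@members)
#' @rdname accessors
setMethod("confidenceLevel", "EnsembleSpectrum", function(x) x@confidenceLevel)
#' @rdname accessors
setMethod("nMembers", "EnsembleSpectrum", function(x) length(x@members))

#' @rdname accessors
setMethod("atoms", "MolecularStructure", function(x) x@atoms)

#' @rdname accessors
setMethod("rsAlpha", "RangeSepParams", function(x) x@alpha)
#' @rdname accessors
setMethod("rsBeta", "RangeSepParams", function(x) x@beta)
#' @rdname accessors
setMethod("rsMu", "RangeSepParams", function(x) x@mu)

## ---- show methods -----------------------------------------------------

setMethod("show", "StickSpectrum", function(object) {
  cat("StickSpectrum with", nrow(object@states), "state(s)")
  if (!is.na(object@label)) cat(" [", object@label, "]", sep = "")
  cat("\n")
  if (nrow(object@states) > 0) {
    e <- object@states$energy_eV
    cat(sprintf("  energies: %.3f .. %.3f eV (%.1f .. %.1f nm)\n",
                min(e), max(e), HC_EV_NM / max(e), HC_EV_NM / min(e)))
    r <- object@states$rotatory_strength
    cat(sprintf("  R(length): %.2f .. %.2f (1e-40 cgs)\n", min(r), max(r)))
  }
  invisible(NULL)
})

setMethod("show", "CDSpectrum", function(object) {
  cat("CDSpectrum on", length(object@grid), "points,", object@axis)
  if (!is.na(object@label)) cat(" [", object@label, "]", sep = "")
  cat("\n")
  if (length(object@grid) > 0)
    cat(sprintf("  grid %.1f .. %.1f; Delta-epsilon %.3g .. %.3g M-1cm-1\n",
                min(object@grid), max(object@grid),
                min(object@values), max(object@values)))
  invisible(NULL)
})

setMethod("show", "EnsembleSpectrum", function(object) {
  cat(sprintf(
    "EnsembleSpectrum: %d member(s), %.0f%% %s band, %d grid points\n",
    length(object@members), 100 * object@confidenceLevel, object@ciMethod,
    length(object@grid)))
  invisible(NULL)
})

setMethod("show", "RangeSepParams", function(object) {
  cat(sprintf("RangeSepParams(alpha = %.4f, beta = %.4f, mu = %.4f bohr^-1)\n",
              object@alpha, object@beta, object@mu))
  invisible(NULL)
})

setMethod("show", "MolecularStructure", function(object) {
  at <- object@atoms
  cat("MolecularStructure:", nrow(at), "atom(s),",
      length(unique(paste(at$chain, at$resid))), "residue(s)\n")
  invisible(NULL)
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport (", object@signFilter, " peaks)\n", sep = "")
  if (nrow(object@pairs) > 0) {
    for (i in seq_len(nrow(object@pairs)))
      cat(sprintf("  calc %.1f nm <-> exp %.1f nm  shift %+.1f nm\n",
                  object@pairs$calc_nm[i], object@pairs$exp_nm[i],
                  object@pairs$shift_nm[i]))
  }
  cat(sprintf("  max |shift| = %.1f nm; verdict at %.0f nm tolerance: %s\n",
              object@maxAbsShift, object@toleranceNm, object@verdict))
  if (!is.na(object@positiveFeature))
    cat(sprintf("  positive feature in %.0f-%.0f nm: %.2f M-1cm-1\n",
                object@positiveWindow[1], object@positiveWindow[2],
                object@positiveFeature))
  invisible(NULL)
})
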