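#' @import methods
NULL

## Conversion constant between photon energy (eV) and vacuum wavelength (nm):
## lambda[nm] = HC_EV_NM / E[eV].  CODATA value of h*c in eV*nm.
HC_EV_NM <- 1239.841984

.empty_states <- function() {
  data.frame(index = integer(), energy_eV = numeric(),
             rotatory_strength = numeric(), oscillator_strength = numeric())
}

#' StickSpectrum: excited states before broadening
#'
#' An ordered collection of excited states, each carrying a 1-based state
#' index, an excitation energy in eV and a length-gauge rotatory strength in
#' units of 1e-40 cgs (erg esu cm / Gauss).  States are kept sorted by
#' ascending energy; state indices must be unique.  Wavelengths are always
#' derived from the energies (lambda = hc/E) and never stored.
#'
#' @slot states data.frame with columns `index`, `energy_eV`,
#'   `rotatory_strength`, `oscillator_strength` (NA when unknown).
#' @slot label character(1) snapshot or source identifier.
#' @slot metadata free-form provenance list (functional, basis, source file).
#'
#' @seealso [StickSpectrum()], [convolveSticks()]
#' @exportClass StickSpectrum
setClass("StickSpectrum",
  representation(states = "data.frame", label = "character",
                 metadata = "list"),
  prototype(states = .empty_states(), label = NA_character_,
            metadata = list()))

setValidity("StickSpectrum", function(object) {
  st <- object@states
  need <- c("index", "energy_eV", "rotatory_strength", "oscillator_strength")
  if (!all(need %in% names(st)))
    return(paste("states must have columns:", paste(need, collapse = ", ")))
  if (nrow(st) == 0L) return(TRUE)
  if (anyDuplicated(st$index)) return("state indices must be unique")
  if (any(!is.finite(st$energy_eV)) || any(st$energy_eV <= 0))
    return("all excitation energies must be finite and > 0 eV")
  if (any(!is.finite(st$rotatory_strength)))
    return("rotatory strengths must be finite (no NaN/NA)")
  if (is.unsorted(st$energy_eV))
    return("states must be sorted by ascending energy")
  TRUE
})

#' Spectrum of molar circular dichroism on a wavelength or energy grid
#'
#' The unit-carrying central object: Delta-epsilon values (M^-1 cm^-1)
#' aligned with a strictly increasing grid.  The grid axis is tagged
#' explicitly as `"wavelength_nm"` or `"energy_eV"`.
#'
#' @slot grid strictly increasing numeric axis.
#' @slot values Delta-epsilon in M^-1 cm^-1, same length as `grid`.
#' @slot axis `"wavelength_nm"` or `"energy_eV"`.
#' @slot label character(1) identifier.
#' @slot metadata free-form list.
#'
#' @exportClass CDSpectrum
setClass("CDSpectrum",
  representation(grid = "numeric", values = "numeric", axis = "character",
                 label = "character", metadata = "list"),
  prototype(grid = numeric(), values = numeric(), axis = "wavelength_nm",
            label = NA_character_, metadata = list()))

setValidity("CDSpectrum", function(object) {
  if (length(object@grid) != length(object@values))
    return("grid and values must have equal length")
  if (length(object@grid) > 1 && any(diff(object@grid) <= 0))
    return("grid must be strictly increasing")
  if (any(!is.finite(object@values)))
    return("spectrum values must be finite")
  if (!object@axis %in% c("wavelength_nm", "energy_eV"))
    return("axis must be 'wavelength_nm' or 'energy_eV'")
  TRUE
})

#' Broadening configuration for the stick-to-spectrum convolution
#'
#' @slot sigma Gaussian exponential half-width in eV (> 0).
#' @slot gridMin,gridMax spectral window in nm.
#' @slot gridStep grid spacing in nm.
#' @slot energyWeighting `"per_state_energy"` (weight each state by its own
#'   excitation energy En, the default) or `"incident_energy"` (weight by the
#'   incident photon energy E); both conventions occur in chiroptical
#'   post-processing.
#'
#' @exportClass BroadeningConfig
setClass("BroadeningConfig",
  representation(sigma = "numeric", gridMin = "numeric", gridMax = "numeric",
                 gridStep = "numeric", energyWeighting = "character"),
  prototype(sigma = 0.3, gridMin = 170, gridMax = 400, gridStep = 0.5,
            energyWeighting = "per_state_energy"))

setValidity("BroadeningConfig", function(object) {
  if (length(object@sigma) != 1 || !is.finite(object@sigma) ||
      object@sigma <= 0)
    return("sigma must be a single positive number (eV)")
  if (object@gridMin >= object@gridMax)
    return("gridMin must be < gridMax")
  if (object@gridStep <= 0) return("gridStep must be > 0")
  if (!object@energyWeighting %in% c("per_state_energy", "incident_energy"))
    return("energyWeighting must be 'per_state_energy' or 'incident_energy'")
  TRUE
})

#' Snapshot-ensemble average spectrum with confidence band
#'
#' Pointwise mean over member spectra on a shared wavelength grid, with the
#' lower/upper bounds of a pointwise confidence interval of the mean.
#'
#' @slot grid shared wavelength grid (nm).
#' @slot mean pointwise ensemble mean (M^-1 cm^-1).
#' @slot ciLower,ciUpper pointwise confidence bounds.
#' @slot members list of the member [CDSpectrum-class] objects (resampled to
#'   `grid`).
#' @slot confidenceLevel fraction, e.g. 0.95.
#' @slot ciMethod `"t"` (Student-t interval) or `"bootstrap"` (percentile).
#'
#' @exportClass EnsembleSpectrum
setClass("EnsembleSpectrum",
  representation(grid = "numeric", mean = "numeric", ciLower = "numeric",
                 ciUpper = "numeric", members = "list",
                 confidenceLevel = "numeric", ciMethod = "character"),
  prototype(grid = numeric(), mean = numeric(), ciLower = numeric(),
            ciUpper = numeric(), members = list(), confidenceLevel = 0.95,
            ciMethod = "t"))

setValidity("EnsembleSpectrum", function(object) {
  n <- length(object@grid)
  if (length(object@mean) != n || length(object@ciLower) != n ||
      length(object@ciUpper) != n)
    return("grid, mean, ciLower and ciUpper must have equal length")
  if (length(object@members) < 1)
    return("an ensemble needs at least one member")
  tol <- 1e-9 * (1 + max(abs(object@mean), 0))
  if (any(object@ciLower > object@mean + tol) ||
      any(object@ciUpper < object@mean - tol))
    return("confidence band must bracket the mean pointwise")
  if (object@confidenceLevel <= 0 || object@confidenceLevel >= 1)
    return("confidenceLevel must be in (0, 1)")
  TRUE
})

#' Coulomb-attenuation (range-separation) parameters
#'
#' The (alpha, beta, mu) triple of a Coulomb-attenuated hybrid functional:
#' the Hartree-Fock exchange fraction varies with interelectronic distance
#' r12 as alpha + beta*erf(mu*r12), so HF exchange has weight alpha at
#' r12 = 0 and alpha + beta at r12 = Inf.
#'
#' @slot alpha short-range HF-exchange weight, dimensionless in \[0, 1\].
#' @slot beta long-range increment; alpha + beta must lie in \[0, 1\].
#' @slot mu attenuation parameter in bohr^-1 (>= 0).
#'
#' @seealso [camB3LYP()], [b3lyp()], [hfWeight()], [parameterPath()]
#' @exportClass RangeSepParams
setClass("RangeSepParams",
  representation(alpha = "numeric", beta = "numeric", mu = "numeric"),
  prototype(alpha = 0.19, beta = 0.46, mu = 0.33))

setValidity("RangeSepParams", function(object) {
  a <- object@alpha; b <- object@beta; m <- object@mu
  if (length(a) != 1 || length(b) != 1 || length(m) != 1)
    return("alpha, beta and mu must be scalars")
  if (!is.finite(a) || a < 0 || a > 1) return("alpha must be in [0, 1]")
  if (!is.finite(b) || a + b < 0 || a + b > 1)
    return("alpha + beta must be in [0, 1]")
  if (!is.finite(m) || m < 0) return("mu must be >= 0")
  TRUE
})

#' Molecular structure as a flat atom table
#'
#' Atoms with element symbol, PDB-convention atom name, residue name and
#' number, chain id and Cartesian coordinates in Angstrom.  The triple
#' (chain, residue number, atom name) must be unique.
#'
#' @slot atoms data.frame with columns `element`, `name`, `resname`,
#'   `resid`, `chain`, `x`, `y`, `z`.
#' @slot metadata provenance list.
#'
#' @exportClass MolecularStructure
setClass("MolecularStructure",
  representation(atoms = "data.frame", metadata = "list"),
  prototype(atoms = data.frame(element = character(), name = character(),
                               resname = character(), resid = integer(),
                               chain = character(), x = numeric(),
                               y = numeric(), z = numeric()),
            metadata = list()))

setValidity("MolecularStructure", function(object) {
  at <- object@atoms
  need <- c("element", "name", "resname", "resid", "chain", "x", "y", "z")
  if (!all(need %in% names(at)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(at) == 0L) return(TRUE)
  if (any(!is.finite(at$x)) || any(!is.finite(at$y)) || any(!is.finite(at$z)))
    return("coordinates must be finite")
  key <- paste(at$chain, at$resid, at$name, sep = "|")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    return(paste0("duplicate (chain, residue, atom name) triple: ", d))
  }
  TRUE
})

#' Recipe for synthetic snapshot ensembles
#'
#' Describes a stick-spectrum ensemble as a set of electronic bands whose
#' state energies and rotatory strengths jitter from snapshot to snapshot
#' around a common electronic structure, emulating thermally fluctuating
#' molecular-dynamics snapshots.
#'
#' @slot nSnapshots number of snapshots (default 10).
#' @slot bands data.frame with columns `center_eV` (band center excitation
#'   energy), `mean_R` (mean rotatory strength, 1e-40 cgs) and `n_states`
#'   (states per band).
#' @slot energyJitterEv per-snapshot Gaussian s.d. of state energies (eV).
#' @slot rJitterFrac fractional Gaussian s.d. of rotatory strengths.
#' @slot seed integer root seed; snapshots reproduce bit-identically.
#'
#' @seealso [ensembleRecipe()], [generateEnsemble()]
#' @exportClass EnsembleRecipe
setClass("EnsembleRecipe",
  representation(nSnapshots = "numeric", bands = "data.frame",
                 energyJitterEv = "numeric", rJitterFrac = "numeric",
                 seed = "numeric"),
  prototype(nSnapshots = 10,
            bands = data.frame(center_eV = c(5.90, 4.51),
                               mean_R = c(-25, -15),
                               n_states = c(3L, 3L)),
            energyJitterEv = 0.05, rJitterFrac = 0.10, seed = 1))

setValidity("EnsembleRecipe", function(object) {
  if (object@nSnapshots < 1) return("nSnapshots must be >= 1")
  need <- c("center_eV", "mean_R", "n_states")
  if (!all(need %in% names(object@bands)))
    return(paste("bands must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@bands) < 1) return("at least one band is required")
  if (any(object@bands$center_eV <= 0))
    return("band centers must be positive energies (eV)")
  if (any(object@bands$n_states < 1))
    return("each band needs at least one state")
  if (object@energyJitterEv < 0 || object@rJitterFrac < 0)
    return("jitter standard deviations must be >= 0")
  TRUE
})

#' Calculated-vs-experimental peak comparison report
#'
#' @slot pairs data.frame of matched peaks: `calc_nm`, `exp_nm`, `shift_nm`
#'   (calc - exp), `calc_amplitude`, `exp_amplitude`.
#' @slot unmatchedCalc,unmatchedExp data.frames of unmatched peaks.
#' @slot maxAbsShift largest absolute matched shift (nm).
#' @slot toleranceNm verdict tolerance (nm).
#' @slot verdict TRUE iff all matched absolute shifts <= toleranceNm.
#' @slot signFilter which peak sign was compared.
#' @slot positiveFeature maximum positive Delta-epsilon found in
#'   `positiveWindow` on the calculated spectrum (NA when not evaluated).
#' @slot positiveWindow the nm window used for `positiveFeature`.
#'
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  representation(pairs = "data.frame", unmatchedCalc = "data.frame",
                 unmatchedExp = "data.frame", maxAbsShift = "numeric",
                 toleranceNm = "numeric", verdict = "logical",
                 signFilter = "character", positiveFeature = "numeric",
                 positiveWindow = "numeric"),
  prototype(pairs = data.frame(), unmatchedCalc = data.frame(),
            unmatchedExp = data.frame(), maxAbsShift = NA_real_,
            toleranceNm = 20, verdict = NA, signFilter = "negative",
            positiveFeature = NA_real_, positiveWindow = c(220, 240)))

#' End-to-end run configuration
#'
#' A flat, typed configuration for [runPipeline()].  Exactly one input mode
#' must be active: quantum-chemistry logs, stick tables, or a synthetic
#' ensemble recipe.  Unit-bearing fields carry the unit in their name.
#'
#' @slot inputMode `"qc_logs"`, `"stick_tables"` or `"synthetic"`.
#' @slot qcLogPaths,stickTablePaths input file paths for the file modes.
#' @slot recipe an [EnsembleRecipe-class] for the synthetic mode (or NULL).
#' @slot sigmaEv Gaussian half-width for broadening (eV).
#' @slot gridMinNm,gridMaxNm,gridStepNm output wavelength grid.
#' @slot energyWeighting see [BroadeningConfig-class].
#' @slot confidenceLevel,ciMethod ensemble band options.
#' @slot minProminence peak-detection prominence floor (M^-1 cm^-1).
#' @slot shiftToleranceNm verdict tolerance for peak shifts (nm).
#' @slot positiveWindowNm window for the positive-shoulder diagnostic (nm).
#' @slot experimentalCsv optional experimental spectrum CSV path (NA = none).
#' @slot outDir output directory.
#' @slot seed integer seed used for every stochastic stage.
#'
#' @exportClass RunConfig
setClass("RunConfig",
  representation(inputMode = "character", qcLogPaths = "character",
                 stickTablePaths = "character", recipe = "ANY",
                 sigmaEv = "numeric", gridMinNm = "numeric",
                 gridMaxNm = "numeric", gridStepNm = "numeric",
                 energyWeighting = "character", confidenceLevel = "numeric",
                 ciMethod = "character", minProminence = "numeric",
                 shiftToleranceNm = "numeric", positiveWindowNm = "numeric",
                 experimentalCsv = "character", outDir = "character",
                 seed = "numeric"),
  prototype(inputMode = "synthetic", qcLogPaths = character(),
            stickTablePaths = character(), recipe = NULL, sigmaEv = 0.3,
            gridMinNm = 170, gridMaxNm = 400, gridStepNm = 0.5,
            energyWeighting = "per_state_energy", confidenceLevel = 0.95,
            ciMethod = "t", minProminence = 1, shiftToleranceNm = 20,
            positiveWindowNm = c(220, 240), experimentalCsv = NA_character_,
            outDir = ".", seed = 1))

setValidity("RunConfig", function(object) {
  if (!object@inputMode %in% c("qc_logs", "stick_tables", "synthetic"))
    return("inputMode must be 'qc_logs', 'stick_tables' or 'synthetic'")
  active <- c(qc_logs = length(object@qcLogPaths) > 0,
              stick_tables = length(object@stickTablePaths) > 0,
              synthetic = !is.null(object@recipe))
  if (sum(active) != 1)
    return(paste0("exactly one input mode must be populated; found: ",
                  paste(names(active)[active], collapse = ", ")))
  if (!active[[object@inputMode]])
    return(paste0("inputMode is '", object@inputMode,
                  "' but its inputs are empty"))
  if (object@sigmaEv <= 0) return("sigmaEv must be > 0")
  if (length(object@positiveWindowNm) != 2 ||
      object@positiveWindowNm[1] >= object@positiveWindowNm[2])
    return("positiveWindowNm must be an increasing pair of wavelengths")
  TRUE
})
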