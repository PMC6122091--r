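#' @include AllClasses.R
NULL

#' Accessors for spectra, stick spectra and ensembles
#'
#' Slot access goes through these accessors, never through `@`.
#' `wavelengths()` on a [StickSpectrum-class] derives lambda = hc/E from the
#' stored energies (hc = 1239.841984 eV nm); on a [CDSpectrum-class] it
#' returns (or converts to) the wavelength grid.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("deltaEpsilon", function(x) standardGeneric("deltaEpsilon"))
#' @rdname accessors
#' @export
setGeneric("axisUnit", function(x) standardGeneric("axisUnit"))
#' @rdname accessors
#' @export
setGeneric("specLabel", function(x) standardGeneric("specLabel"))
#' @rdname accessors
#' @export
setGeneric("specMetadata", function(x) standardGeneric("specMetadata"))
#' @rdname accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))
#' @rdname accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))
#' @rdname accessors
#' @export
setGeneric("rotatoryStrengths", function(x)
  standardGeneric("rotatoryStrengths"))
#' @rdname accessors
#' @export
setGeneric("ensembleMean", function(x) standardGeneric("ensembleMean"))
#' @rdname accessors
#' @export
setGeneric("ciLower", function(x) standardGeneric("ciLower"))
#' @rdname accessors
#' @export
setGeneric("ciUpper", function(x) standardGeneric("ciUpper"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("confidenceLevel", function(x) standardGeneric("confidenceLevel"))
#' @rdname accessors
#' @export
setGeneric("nMembers", function(x) standardGeneric("nMembers"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("rsAlpha", function(x) standardGeneric("rsAlpha"))
#' @rdname accessors
#' @export
setGeneric("rsBeta", function(x) standardGeneric("rsBeta"))
#' @rdname accessors
#' @export
setGeneric("rsMu", function(x) standardGeneric("rsMu"))
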