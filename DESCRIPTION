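Package: ecdtools
Title: Ensemble Electronic Circular Dichroism Spectra from Excited-State
    Calculations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts excited-state stick spectra (excitation energies and
    length-gauge rotatory strengths) from time-dependent density functional
    theory calculations into Gaussian-broadened molar circular dichroism
    spectra, averages them over molecular-dynamics snapshot ensembles with
    pointwise confidence bands, and diagnoses spectral features such as
    negative-peak positions and spurious positive shoulders against
    experimental spectra. Also generates Coulomb-attenuation parameter
    interpolation paths between range-separated and global hybrid
    exchange-correlation functionals, and prepares backbone-truncated
    quantum-chemistry models of nucleic acids by excising the
    sugar-phosphate backbone and capping glycosidic nitrogens with
    hydrogens. A synthetic-data module emulates snapshot ensembles so the
    whole pipeline runs without external quantum-chemistry output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ecdtools-package.R'
    'methods.R'
    'spectra-core.R'
    'qc-io.R'
    'ensemble.R'
    'features.R'
    'structure-prep.R'
    'synthetic.R'
    'rangesep.R'
    'pipeline.R'
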