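Package: dtims
Title: Drift-Tube Ion Mobility Analysis of Protein Oligomer Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising transient protein oligomers by native
    drift-tube ion mobility mass spectrometry. Converts multi-voltage arrival
    time distributions to collision cross sections via the Mason-Schamp
    relation, deconvolves multimodal arrival time distributions into conformer
    families, disambiguates m/z-coincident oligomers ("aggromers") using
    isotope fine structure and collision-induced dissociation channel logic,
    screens charge states against the de la Mora Rayleigh limit, and provides
    structure-side metrics (radius of gyration, projection-approximation
    collision cross sections, Kabsch RMSD) that link atomistic models to
    mobility data. A synthetic drift-tube instrument module generates
    ground-truth-labelled data so every stage is testable without spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    pracma,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
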