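Package: colonyscreen
Title: FACS Matrix-Deposition Colony Screening: Simulation, Quantification
    and Spectral Variant Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for flow-sorter single-cell matrix
    deposition screens. Generates synthetic multi-filter bioluminescence
    images of colony plates printed on a known lattice (grid geometry,
    viability, doublets, minority spike-ins, density-dependent colony
    size, camera noise), detects and quantifies colonies on the grid,
    builds a normalised multi-point emission spectrum per colony, calls
    rare spectrally shifted clones and emits a pick map, analyses
    two-colour deposition coincidence and singlet purity, and models
    deposition scheduling and throughput for conventional single-stream
    printing versus a sort-stream multiplexer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    png,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
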