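Package: magassembly
Title: Agent-Based Simulation of Magnetically Guided Microtissue Bioassembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Overdamped discrete-element simulation of superparamagnetic
    nanoparticle (MNP) coated tissue spheroids assembling over a cylindrical
    permanent magnet, together with the downstream readouts used to
    characterise the process: area-coverage kinetics and assembly time,
    radial and vertical stress profiles, Fe3O4 mass accounting from SQUID
    hysteresis curves, and FFT-based fiber directionality analysis.
    Includes synthetic generators for spheroid populations, nanoparticle
    allocation, hysteresis curves and oriented-fiber images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    data.table,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
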