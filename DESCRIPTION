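Package: waterlogsy
Title: Ligand Epitope Mapping from WaterLOGSY and STD NMR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for ligand-observed NMR analysis in fragment-based lead
    discovery. Computes per-proton WaterLOGSY factors from free/bound signed
    intensity data, classifies protein-ligand pairs into the four canonical
    sign/intensity scenarios, calls per-proton solvent exposure, flags
    labile-proton artifacts from mixing-time series, compares factors with
    solvent-accessible surface areas computed from complex structures, and
    ships a Solomon-equation relaxation-matrix simulator that generates
    synthetic WaterLOGSY and STD data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
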