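Package: softspotter
Title: Soft-Spot Identification for Cyclic Peptides via 2PCA Derivatization LC-MS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automated identification of ring-opening hydrolysis sites
    ("soft spots") in cyclic peptides from LC-MS/MS data after derivatization
    of the newly formed N-terminus with 2-pyridinecarboxaldehyde (2PCA).
    Enumerates isomeric linearized candidates, computes the diagnostic
    imidazolidinone ions (the a1/b1-type doublet spaced by CO and the
    m/z 107.0609 marker ion), performs dynamic control-scan background
    subtraction of all-ion-fragmentation data against matrix-only controls,
    screens the marker-ion chromatogram, and scores ring-opening candidates
    against targeted MS/MS spectra with duplicate-residue disambiguation via
    the y-ion series. Includes a ground-truth synthetic run generator for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    mzR,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
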