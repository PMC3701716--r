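Package: lovtherm
Title: Thermostability Engineering Analysis for LOV-Domain Fluorescent Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for computational thermostability engineering of
    flavin-based fluorescent proteins (FbFPs) and other dimeric LOV-domain
    scaffolds. Implements Bennett acceptance-ratio (BAR) free-energy estimation
    from alchemical lambda-window energy-difference samples with block-based
    errors and autocorrelation diagnostics; thermodynamic-cycle assembly of
    mutational folding free-energy differences (ddG) through a pseudo-alanine
    intermediate with electrostatic/van der Waals decomposition; fitting of
    fluorescence thermal-denaturation curves with a concentration-dependent
    dimeric two-state model, nested-model F-tests and Monte-Carlo parameter
    errors; screening statistics comparing predicted and experimental ddG and
    melting temperatures; and per-site consensus frequency analysis of aligned
    homolog sets. Synthetic-data generators with closed-form ground truth make
    every stage testable without molecular-dynamics trajectories or
    spectrometer data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
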