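Package: paleoGDGT
Title: Branched GDGT Proxy Calculus and Neural-Network Precipitation
    Calibration for Loess Paleoclimate Records
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing paleoclimate from branched glycerol
    dialkyl glycerol tetraether (brGDGT) membrane lipids and leaf-wax
    n-alkanes in loess-paleosol sequences. Computes fractional abundances
    and the standard index suite (MBT', MBT'6ME, IR6ME, CBT'/pH and four
    temperature calibrations, CPI, ACL), calibrates lipid compositions to
    mean annual precipitation with a from-scratch deep feed-forward network
    trained by Adam on mean absolute error (with multiple-linear-regression
    and recurrent RNN/LSTM/GRU baselines and full regression diagnostics),
    builds magnetic-susceptibility-weighted age-depth models, compares
    reconstructions against reference series by Morlet cross-wavelet phase
    analysis, and simulates compositional calibration and downcore datasets
    with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Metabolomics, Lipidomics, Regression, TimeCourse
RoxygenNote: 7.3.3
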