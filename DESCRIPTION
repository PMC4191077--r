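Package: hemopk
Title: Pharmacokinetics of Hemoglobin and Hemoglobin-Haptoglobin Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for intravascular hemoglobin (Hb)
    and hemoglobin:haptoglobin (Hb:Hp) disposition studies. Provides a kinetic
    simulator of Hb infusion, irreversible Hp binding and complex clearance
    (first-order or saturable); multi-component spectral deconvolution of heme
    species from UV-visible absorbance; size-exclusion chromatogram peak
    integration and free/bound partitioning; non-compartmental pharmacokinetic
    analysis (Cmax, trapezoidal AUC, terminal slope, clearance, central volume,
    half-life) with mean +/- SEM group summaries; and per-cell quantification
    of Hb:Hp endocytosis from two-channel fluorescence images, including a
    synthetic image generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    EBImage,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
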