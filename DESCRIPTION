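Package: vitreomiR
Title: Efficiency-Aware qPCR Quantification and Ratio Biomarker Analysis of
    Ocular-Fluid microRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies microRNA expression from TaqMan qPCR threshold-cycle
    data using an efficiency-corrected delta-delta-Ct model with a
    weighted-mean endogenous reference, applies the quality-control
    exclusions used for vitreous-humour and plasma cohorts (40-cycle
    detection threshold, amplification-efficiency cutoff, hemolysis index,
    Grubbs outlier test), summarises per-miRNA fold changes with Student
    t-tests, and evaluates miRNA-ratio biomarkers by Mann-Whitney ROC
    analysis with Hanley-McNeil confidence intervals. Includes amplification
    curve modelling (threshold-cycle calling and window-of-linearity
    efficiency estimation from raw fluorescence), a phased filter of GWAS
    summary statistics against miRNA binding-site motifs with Bonferroni and
    Storey q-value adjustments, and a synthetic cohort generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
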