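Package: screenSurv
Title: Multiplexed siRNA Screen Analytics and Survival Biomarker Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed RNAi screens read out by both a
    fluorescence viability assay and image-derived cell counts, together with
    a downstream survival-biomarker scan. Provides per-plate z'-factor quality
    control from positive (siPLK1) and negative (siNC) control wells, per-plate
    log2 normalization of both readouts against the negative controls,
    replicate-level hit calling into common / cisplatin-sensitized categories,
    derived statistics (viability per cell, percent growth inhibition,
    additive-expectation synergy flagging, serial-treatment contrasts),
    Kaplan-Meier estimation and log-rank testing implemented from first
    principles, a 48-condition prognostic scan with best-p selection and
    favorable/unfavorable classification, mutation-set-stratified survival,
    and oncoprint matrix construction. Seeded synthetic-data generators emulate
    384-well screen plates and survival cohorts so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), survival, jsonlite, yaml, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
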