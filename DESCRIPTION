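Package: dermoct
Title: Skin OCT, Optical Coherence Elastography and OCT Angiography Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of multifunctional optical coherence
    tomography (OCT) imaging of skin: structural skin-thickness measurement
    from repeated B-scan volumes, elastic-wave group-velocity estimation from
    phase-sensitive M-B-mode optical coherence elastography (OCE) records,
    correlation-mapping OCT angiography (OCTA) with Hessian vessel
    enhancement and automated lumen-width measurement, and the accompanying
    nonparametric statistical layer (Wilcoxon signed-rank and Mann-Whitney U
    tests, Bonferroni correction, Hodges-Lehmann shift estimates with
    confidence intervals, Hedges' g, power and minimum-detectable-difference
    calculations). A synthetic phantom generator produces speckle-bearing
    layered volumes, propagating-wave phase records, decorrelating vessel
    stacks and longitudinal cohorts with known ground truth, so every stage
    of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
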