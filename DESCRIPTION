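Package: lcmstats
Title: Targeted LC-MS/MS Quantification and Integrative Metabolomics Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted liquid-chromatography tandem mass-spectrometry
    metabolomics: mzML input/output and synthetic-run generation, targeted
    peak detection and abundance quantification with signal-to-noise and
    relative-abundance summaries, abundance-matrix preprocessing (internal
    standard normalization, log transforms, Pareto scaling, rank-based
    inverse normal transformation), peak and sample quality control,
    per-feature ANCOVA association and NIPALS PLS/PLS-DA modelling with VIP
    scores and cross-validated Q2, integrative gene-plus-compound pathway
    analysis combining over-representation tests with a topology-aware
    perturbation statistic, accurate-mass compound identification against
    database snapshots, and weighted calibration curves with outlier
    rejection for concentration estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite
Config/testthat/edition: 3
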