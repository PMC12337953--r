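Package: ProteoDisorder
Title: Comparative Intrinsic Disorder and Phase-Separation Profiling of Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative profiling of intrinsic disorder and
    liquid-liquid phase separation (LLPS) propensity across protein sets.
    Provides per-residue disorder predictors (a windowed charge-hydropathy
    score and a disorder-propensity scale), ADS/PPDR aggregation with tiered
    classification, charge-hydropathy versus cumulative-distribution-function
    (CH-CDF) quadrant analysis with contingency statistics, sliding-window
    detection of phase-separating intrinsically disordered regions with
    cumulative-length and recall-AUC summaries, cross-proteome inference
    (ANOVA, Tukey HSD, pairwise t, Pearson chi-squared), overlap analysis,
    and a seeded synthetic proteome generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ProteoDisorder-package.R'
    'disorder.R'
    'chcdf.R'
    'classify.R'
    'llps.R'
    'proteome-io.R'
    'synthetic.R'
    'stats.R'
    'pipeline.R'
    'reference-data.R'
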