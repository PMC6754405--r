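Package: histurnover
Title: Histone PTM Abundance and Turnover from Metabolic-Labeling Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-proteoform histone post-translational modification
    (PTM) relative abundance and heavy-isotope labeling incorporation
    ("turnover") from bottom-up DIA and middle-down mass-spectrometry signals.
    Includes the mass chemistry of propionyl-derivatized histone peptides and
    SILAC-style labels, a media labeling-stoichiometry and replication-dilution
    model, fragment-ion resolution of positional isomers, intact-tail
    methyl-equivalent ladders, the statistical layer (heteroscedastic t-tests,
    Pearson correlations, fold-change and replicate-precision comparisons),
    BED-interval overlap metrics for sequencing-based validation, and seeded
    synthetic-data generators with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    pracma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
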