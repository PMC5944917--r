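Package: gsclines
Title: Selection on Genome Size and Repeat Content Along Altitudinal
    Clines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing natural selection on genome size and
    repeat abundance along environmental clines in structured plant
    populations. Provides a kinship-null linear mixed model fitted by
    restricted maximum likelihood via spectral decomposition, genotype
    quality control and centered identity-by-state kinship estimation,
    repeat-abundance estimation from low-coverage shotgun read
    assignments with repeat-library masking, a hierarchical Bayesian
    mediation model linking genome size to cell size and cell-production
    rate through leaf elongation, mixed-model re-analysis of shoot
    apical meristem cell counts and flowering time, and synthetic-data
    generators that reproduce the statistical structure assumed by each
    analysis so the whole pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    sandwich,
    stats,
    tools,
    utils
Suggests:
    coda,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
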